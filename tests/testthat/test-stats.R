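test_that("pooled z-scores have mean 0, SD 1 and are affine-invariant", {
  set.seed(101)
  x <- rnorm(60, 10, 3)
  z <- pooled_zscore(x)
  expect_equal(mean(z), 0, tolerance = 1e-12)
  expect_equal(sd(z), 1, tolerance = 1e-12)
  expect_equal(pooled_zscore(3.2 * x + 11), z, tolerance = 1e-12)
  expect_error(pooled_zscore(rep(5, 10), name = "ve"), "ve")
})

test_that("panel visit coefficient equals the mean within-subject z-difference", {
  for (seed in c(1, 2, 3)) {
    tab <- random_cohort_table(n = 25, seed = seed)
    sc <- standardized_change_panel(tab)
    for (p in sc$parameter) {
      z <- pooled_zscore(tab[[p]])
      dz <- z[tab$visit == "followup"] - z[tab$visit == "baseline"]
      expect_equal(sc$estimate[sc$parameter == p], mean(dz), tolerance = 1e-10)
    }
  }
})

test_that("raw mean change over pooled SD equals the panel coefficient", {
  tab <- random_cohort_table(n = 40, seed = 9)
  sc <- standardized_change_panel(tab)
  for (p in sc$parameter) {
    pooled_sd <- sd(tab[[p]])
    expect_equal(sc$raw_mean_change[sc$parameter == p] / pooled_sd,
                 sc$estimate[sc$parameter == p], tolerance = 1e-10)
  }
})

test_that("pooled and per-parameter panel modes give identical point estimates", {
  tab <- random_cohort_table(n = 20, seed = 4)
  sc1 <- standardized_change_panel(tab, mode = "pooled")
  sc2 <- standardized_change_panel(tab, mode = "per_parameter")
  expect_equal(sc1$estimate, sc2$estimate, tolerance = 1e-10)
})

test_that("panel estimates agree with an independent mixed-model fit", {
  skip_if_not_installed("lme4")
  tab <- random_cohort_table(n = 30, seed = 12)
  params <- c("volume_mm3", "re_late", "ktrans", "koos_pain")
  sc <- standardized_change_panel(tab, parameters = params)
  long <- do.call(rbind, lapply(params, function(p)
    data.frame(subject = tab$subject_id, visit = as.numeric(tab$visit == "followup"),
               type = p, y = pooled_zscore(tab[[p]]))))
  fit <- lme4::lmer(y ~ 0 + type + type:visit + (1 | subject), data = long,
                    control = lme4::lmerControl(check.conv.singular = "ignore"))
  fe <- lme4::fixef(fit)
  for (p in params)
    expect_equal(unname(fe[[paste0("type", p, ":visit")]]),
                 sc$estimate[sc$parameter == p], tolerance = 1e-6)
})

test_that("no change between visits yields zero standardized change", {
  n <- 15
  set.seed(6)
  vals <- rnorm(n, 5, 2)
  tab <- data.frame(subject_id = rep(sprintf("P%02d", 1:n), each = 2),
                    visit = rep(c("baseline", "followup"), n))
  for (v in c("volume_mm3", "rer", "re_late", "re_max", "ve", "ktrans", "koos_pain"))
    tab[[v]] <- rep(rnorm(n, 5, 2), each = 2)  # follow-up identical to baseline
  sc <- standardized_change_panel(tab)
  expect_true(all(abs(sc$estimate) < 1e-12))
})

test_that("standardized change is invariant to positive affine rescaling of a raw parameter", {
  tab <- random_cohort_table(n = 22, seed = 30)
  sc1 <- standardized_change_panel(tab)
  tab$ktrans <- 1000 * tab$ktrans + 3
  sc2 <- standardized_change_panel(tab)
  expect_equal(sc2$estimate, sc1$estimate, tolerance = 1e-10)
})

test_that("KOOS row is reported in both orientations", {
  tab <- random_cohort_table(n = 12, seed = 44)
  sc <- standardized_change_panel(tab)
  k <- sc$parameter == "koos_pain"
  expect_equal(sc$oriented_estimate[k], -sc$estimate[k])
  expect_equal(sc$orientation[k], "improvement-negative")
  expect_true(all(sc$oriented_estimate[!k] == sc$estimate[!k]))
  expect_true(all(sc$ci_low <= sc$estimate & sc$estimate <= sc$ci_high))
})

test_that("unbalanced panels are rejected", {
  tab <- random_cohort_table(n = 10, seed = 2)
  expect_error(standardized_change_panel(tab[-1, ]), "unbalanced")
})

test_that("paired mean change uses a t-interval and shrinks like 1/sqrt(n)", {
  expect_equal(mean_change(c(1, 2), c(1, 2))$mean_change, 0)
  expect_error(mean_change(1, 2), "at least 2")

  set.seed(55)
  base <- rnorm(800, 10, 2)
  diffs <- rnorm(800, -1, 1.5)
  widths <- vapply(c(50, 200, 800), function(n) {
    mc <- mean_change(base[1:n], base[1:n] + diffs[1:n])
    mc$ci_high - mc$ci_low
  }, numeric(1))
  # width ratio approximately 2 for a 4x sample-size step
  expect_equal(widths[1] / widths[2], 2, tolerance = 0.3)
  expect_equal(widths[2] / widths[3], 2, tolerance = 0.3)
})

test_that("association recovers exact linear relations and rejects degenerate input", {
  d <- c(-1.5, 0.2, 1.1, 2.4, -0.6)
  a <- suppressWarnings(association(d, 2 * d))  # lm warns on a perfect fit
  expect_equal(a$b, 2, tolerance = 1e-12)
  expect_equal(a$r, 1, tolerance = 1e-12)

  expect_error(association(rep(1, 10), rnorm(10)), "constant")
  expect_error(association(1:3, 1:3), "4 complete pairs")
})

test_that("independent changes show near-zero correlation at large n", {
  set.seed(77)
  a <- association(rnorm(5000), rnorm(5000))
  expect_lt(abs(a$r), 0.05)
  expect_true(a$r_ci_low <= a$r && a$r <= a$r_ci_high)
})

test_that("b and r always share a sign in cohorts with a true link", {
  for (seed in c(1, 5, 9)) {
    co <- simulate_cohort(120, seed = seed)
    bl <- co$truth[co$truth$visit == "baseline", ]
    fu <- co$truth[co$truth$visit == "followup", ]
    a <- association(fu$re_late - bl$re_late, fu$koos_pain - bl$koos_pain)
    expect_equal(sign(a$b), sign(a$r))
    expect_lt(a$r, 0)
  }
})

test_that("Fisher-z confidence intervals achieve nominal coverage on null cohorts", {
  set.seed(2026)
  n_rep <- 2000
  covered <- logical(n_rep)
  for (i in seq_len(n_rep)) {
    x <- rnorm(93); y <- rnorm(93)
    a <- association(x, y)
    covered[i] <- a$r_ci_low <= 0 && 0 <= a$r_ci_high
  }
  expect_gte(mean(covered), 0.93)
  expect_lte(mean(covered), 0.97)
})

test_that("association table reports volume per cm^3 and one row per parameter", {
  co <- simulate_cohort(60, seed = 13)
  at <- association_table(co$truth)
  expect_equal(at$parameter,
               c("volume_mm3", "rer", "re_late", "re_max", "ve", "ktrans"))
  # scaling mm^3 -> cm^3 multiplies the slope by 1000
  bl <- co$truth[co$truth$visit == "baseline", ]
  fu <- co$truth[co$truth$visit == "followup", ]
  raw <- association((fu$volume_mm3 - bl$volume_mm3),
                     fu$koos_pain - bl$koos_pain)
  expect_equal(at$b[1], raw$b * 1000, tolerance = 1e-9)
})
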