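test_that("no uptake and no noise gives a flat curve at s0", {
  ser <- simulate_signal_curve(tofts_params(0, 0.3, 0), pop_aif_std,
                               std_protocol, s0 = 120, gain = 5, noise_sd = 0)
  expect_equal(ser$signal, rep(120, 18))
})

test_that("noiseless curves are causal: pre-contrast frames equal s0", {
  for (pr in list(std_protocol, ltr_protocol)) {
    a <- make_population_aif(aif_params(), pr)
    ser <- simulate_signal_curve(tofts_params(0.1, 0.4, 0.05), a, pr,
                                 s0 = 100, noise_sd = 0)
    pre <- seq_len(pr$precontrast_frames)
    expect_equal(ser$signal[pre], rep(100, length(pre)))
    expect_true(all(ser$signal[-pre][-1] > 100))
  }
})

test_that("simulated RE_late equals the convolution-oracle prediction", {
  p <- tofts_params(0.07, 0.35, 0.03)
  gain <- 5
  ser <- simulate_signal_curve(p, pop_aif_std, std_protocol, s0 = 100,
                               gain = gain, noise_sd = 0)
  oracle_grid <- oracle_tofts_ct(p$ktrans, p$ve, p$vp, pop_aif_std$times, pop_aif_std$cp)
  t_s <- protocol_frame_times(std_protocol)
  ct_frames <- approx(pop_aif_std$times, oracle_grid, xout = t_s)$y
  expected <- 1 + gain * mean(tail(ct_frames, 4))
  expect_equal(re_late(ser, baseline_signal(ser)), expected, tolerance = 1e-10)
})

test_that("the same seed reproduces the same noisy curve", {
  p <- tofts_params(0.05, 0.3, 0.02)
  s1 <- simulate_signal_curve(p, pop_aif_std, std_protocol, noise_sd = 3, seed = 77)
  s2 <- simulate_signal_curve(p, pop_aif_std, std_protocol, noise_sd = 3, seed = 77)
  s3 <- simulate_signal_curve(p, pop_aif_std, std_protocol, noise_sd = 3, seed = 78)
  expect_identical(s1$signal, s2$signal)
  expect_false(identical(s1$signal, s3$signal))
})

test_that("doubling the gain doubles the enhancement above baseline", {
  p <- tofts_params(0.06, 0.3, 0.02)
  s1 <- simulate_signal_curve(p, pop_aif_std, std_protocol, gain = 4, noise_sd = 0)
  s2 <- simulate_signal_curve(p, pop_aif_std, std_protocol, gain = 8, noise_sd = 0)
  s0 <- 100
  expect_equal(re_max(s2, s0) - 1, 2 * (re_max(s1, s0) - 1), tolerance = 1e-12)
  expect_equal(re_late(s2, s0) - 1, 2 * (re_late(s1, s0) - 1), tolerance = 1e-12)
})

test_that("cohort truth table has the long two-visit shape", {
  co <- simulate_cohort(93, seed = 5)
  expect_equal(nrow(co$truth), 186)
  expect_equal(length(co$subjects), 93)
  expect_setequal(unique(co$truth$visit), c("baseline", "followup"))
  vars <- c("volume_mm3", "rer", "re_late", "re_max", "ktrans", "ve", "koos_pain")
  expect_true(all(vars %in% names(co$truth)))
  expect_true(all(co$truth$koos_pain >= 0 & co$truth$koos_pain <= 100))
  # treatment effect: follow-up Ktrans never exceeds baseline
  bl <- co$truth[co$truth$visit == "baseline", ]
  fu <- co$truth[co$truth$visit == "followup", ]
  expect_true(all(fu$ktrans <= bl$ktrans))
  # roughly 16/93 on the LTR protocol
  expect_gt(mean(bl$protocol == "ltr"), 0.05)
  expect_lt(mean(bl$protocol == "ltr"), 0.35)
})

test_that("cohorts are reproducible and subject draws are seed-stable under growth", {
  c1 <- simulate_cohort(20, seed = 3)
  c2 <- simulate_cohort(20, seed = 3)
  expect_equal(c1$truth, c2$truth)
  # growing the cohort leaves earlier subjects' draws untouched (the pain
  # link is cohort-calibrated, so compare the per-subject imaging truth)
  c3 <- simulate_cohort(25, seed = 3)
  img_vars <- c("subject_id", "visit", "protocol", "volume_mm3", "rer",
                "re_late", "re_max", "ktrans", "ve")
  expect_equal(c3$truth[1:40, img_vars], c1$truth[, img_vars],
               ignore_attr = TRUE)
})

test_that("null effect with zero pain slope gives standardized change near zero", {
  co <- simulate_cohort(500,
                        effect = cohort_effect(0, 0, 0, 0, heterogeneity_sd = 0),
                        pain_model = pain_link(mean_change = 0, r = 0),
                        seed = 17)
  sc <- standardized_change_panel(co$truth,
                                  parameters = c("volume_mm3", "ktrans", "ve", "koos_pain"))
  se <- (sc$ci_high - sc$ci_low) / (2 * qnorm(0.975))
  expect_true(all(abs(sc$estimate) < 3 * se))
})

test_that("a degenerate zero-variance effect with a correlation target is rejected", {
  expect_error(
    simulate_cohort(10, effect = cohort_effect(0, 0, 0, 0, heterogeneity_sd = 0),
                    pain_model = pain_link(r = -0.27), seed = 1),
    "degenerate")
})

test_that("exact-moment mode reproduces the requested per-visit moments to machine precision", {
  co <- simulate_cohort(93, seed = 23, moment_mode = "exact")
  m <- reference_visit_moments()
  for (v in seq_len(nrow(m))) {
    x_bl <- co$truth[[m$variable[v]]][co$truth$visit == "baseline"]
    x_fu <- co$truth[[m$variable[v]]][co$truth$visit == "followup"]
    expect_equal(mean(x_bl), m$mean_baseline[v], tolerance = 1e-12)
    expect_equal(sd(x_bl), m$sd_baseline[v], tolerance = 1e-12)
    expect_equal(mean(x_fu), m$mean_followup[v], tolerance = 1e-12)
    expect_equal(sd(x_fu), m$sd_followup[v], tolerance = 1e-12)
  }
})

test_that("the pain link hits its target correlation in a large cohort", {
  co <- simulate_cohort(5000, seed = 19)
  bl <- co$truth[co$truth$visit == "baseline", ]
  fu <- co$truth[co$truth$visit == "followup", ]
  r_hat <- cor(fu$re_late - bl$re_late, fu$koos_pain - bl$koos_pain)
  expect_lt(abs(r_hat - (-0.27)), 0.03)
})

test_that("rendered volumes carry curves in-mask, constant background, and round-trip", {
  co <- simulate_cohort(2, population = cohort_population(volume_mean = 70,
                                                          volume_sd = 10,
                                                          noise_sd = 0,
                                                          voxel_jitter_sd = 0),
                        seed = 4)
  s <- co$subjects[[1]]
  out <- withr::local_tempdir()
  r <- render_4d_volume(s, "baseline", grid_shape = c(16, 16, 4),
                        voxel_size = c(1.5, 1.5, 3.0), out_dir = out)
  nvox <- length(r$mask$indices)
  expect_equal(nvox, round(s$volume_mm3[["baseline"]] / 6.75))
  # exactly the in-mask voxels vary over time (noise-free render)
  flat <- apply(r$dyn, 1:3, function(ts) max(ts) - min(ts))
  expect_equal(sum(flat > 0), nvox)
  expect_true(all(which(flat > 0) %in% r$mask$indices))

  # a 100-voxel mask at 1.5 x 1.5 x 3 mm is 675 mm^3
  s100 <- s; s100$volume_mm3[["baseline"]] <- 675
  r100 <- render_4d_volume(s100, "baseline", grid_shape = c(16, 16, 4),
                           voxel_size = c(1.5, 1.5, 3.0))
  expect_equal(synovial_volume(r100$mask), 675)

  # files round-trip bit-identically
  dyn_back <- RNifti::readNifti(r$files[["dyn"]])
  msk_back <- RNifti::readNifti(r$files[["mask"]])
  expect_identical(as.numeric(dyn_back), as.numeric(r$dyn))
  expect_identical(which(as.integer(msk_back) == 1L), r$mask$indices)

  # mask that cannot fit the grid is rejected
  sbig <- s; sbig$volume_mm3[["baseline"]] <- 1e6
  expect_error(render_4d_volume(sbig, "baseline", grid_shape = c(8, 8, 2),
                                voxel_size = c(1.5, 1.5, 3.0)), "fit inside")
})

test_that("invalid generator arguments are rejected", {
  expect_error(simulate_cohort(1, seed = 1), "at least 2")
  expect_error(simulate_cohort(5, protocol_mix = 1.5, seed = 1), "protocol_mix")
  expect_error(ground_truth_subject("x", std_protocol,
                                    list(baseline = tofts_params(0.1, 0.3),
                                         followup = tofts_params(0.1, 0.3)),
                                    c(baseline = 100, followup = 90),
                                    koos_pain = c(baseline = 120, followup = 50)),
               "koos_pain")
})
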