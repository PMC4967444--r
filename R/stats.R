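# Responsiveness and association statistics: pooled z-scoring, random-effects
# panel estimation of standardized change, paired mean change, and bivariate
# association of imaging change with pain change.

#' Pooled two-visit z-score
#'
#' Standardizes one parameter's values using the mean and SD of the pooled
#' sample (baseline and follow-up observations combined). The pooled
#' convention makes the per-parameter standardized change equal to the raw
#' mean change divided by the pooled-sample SD.
#'
#' @param x numeric vector: all observations of one parameter across both
#'   visits (at least 4 values, i.e., 2 subjects).
#' @param name parameter name used in error messages.
#' @return `x` standardized to pooled mean 0 and SD 1 (SD with the `n-1`
#'   denominator).
#' @export
pooled_zscore <- function(x, name = "value") {
  x <- as.numeric(x)
  if (length(x) < 4L) stop("need at least two subjects at two visits")
  if (any(!is.finite(x))) stop("non-finite values in '", name, "'")
  s <- stats::sd(x)
  if (s == 0) stop("parameter '", name, "' has zero pooled variance; cannot standardize")
  (x - mean(x)) / s
}

# Feasible-GLS random-effects (error components) estimator for a balanced
# panel, Swamy-Arora variance components:
#   sigma2_e from the within (subject-demeaned) regression,
#   sigma2_u from the between (subject means) regression,
#   theta = 1 - sqrt(sigma2_e / (sigma2_e + T sigma2_u)),
# then OLS on quasi-demeaned data. Normal-theory CIs.
panel_re_fit <- function(y, subject, X, conf_level = 0.95) {
  subject <- as.factor(subject)
  n_obs <- length(y)
  stopifnot(nrow(X) == n_obs, length(subject) == n_obs)
  Tn <- table(subject)
  if (length(unique(Tn)) != 1L) stop("panel is unbalanced")
  T_per <- as.integer(Tn[1L])
  n_sub <- nlevels(subject)

  group_mean <- function(v) stats::ave(v, subject)
  y_bar <- group_mean(y)
  X_bar <- apply(X, 2L, group_mean)

  # within regression (subject-demeaned); intercept-like columns vanish
  y_w <- y - y_bar
  X_w <- X - X_bar
  qr_w <- qr(X_w)
  k_w <- qr_w$rank
  res_w <- stats::residuals(stats::lm.fit(X_w[, qr_w$pivot[seq_len(max(k_w, 1L))], drop = FALSE], y_w))
  if (k_w == 0L) res_w <- y_w
  df_w <- n_obs - n_sub - k_w
  sigma2_e <- sum(res_w^2) / max(df_w, 1L)

  # between regression on subject means (one row per subject)
  first <- !duplicated(subject)
  Xb <- X_bar[first, , drop = FALSE]
  yb <- y_bar[first]
  qr_b <- qr(Xb)
  k_b <- qr_b$rank
  res_b <- stats::residuals(stats::lm.fit(Xb[, qr_b$pivot[seq_len(max(k_b, 1L))], drop = FALSE], yb))
  df_b <- n_sub - k_b
  s2_between <- if (df_b > 0L) sum(res_b^2) / df_b else 0
  sigma2_u <- max(0, s2_between - sigma2_e / T_per)

  theta <- 1 - sqrt(sigma2_e / (sigma2_e + T_per * sigma2_u))
  if (!is.finite(theta)) theta <- 0
  theta <- min(theta, 1 - 1e-8)  # keep the quasi-demeaned design full rank
  y_star <- y - theta * y_bar
  X_star <- X - theta * X_bar
  fit <- stats::lm.fit(X_star, y_star)
  beta <- fit$coefficients
  XtX_inv <- chol2inv(chol(crossprod(X_star)))
  se <- sqrt(sigma2_e * diag(XtX_inv))
  names(se) <- colnames(X)
  zq <- stats::qnorm(1 - (1 - conf_level) / 2)
  list(coefficients = beta, se = se,
       ci_low = beta - zq * se, ci_high = beta + zq * se,
       sigma2_e = sigma2_e, sigma2_u = sigma2_u, theta = theta,
       n_subjects = n_sub, t_per_subject = T_per)
}

#' Standardized change at follow-up via random-effects panel regression
#'
#' Implements the responsiveness analysis: each parameter is pooled
#' z-scored over both visits, the z-scores of all parameters are stacked
#' into one long panel, and a random-effects (error-components) linear
#' panel regression
#'
#'   y_it = X_it1 b + X_it2 b + W_i + U_it
#'
#' is fitted, where `X_it1` are parameter-type dummies, `X_it2` the
#' parameter-type-by-visit interactions, and `W_i` a subject random effect.
#' The interaction coefficient for a parameter is its standardized change
#' at follow-up; in a balanced panel it equals the mean within-subject
#' z-score change exactly, whatever the variance components, because the
#' fixed-effect design is saturated in the (type, visit) cells. Unlike a
#' standardized response mean, the panel formulation yields confidence
#' intervals directly.
#'
#' The KOOS pain subscale runs from 100 (no pain) to 0 (extreme pain), so
#' improvement *raises* the score; `oriented_estimate` flips the sign of
#' the KOOS row (orientation `"improvement-negative"`) so that response to
#' treatment is negative for every parameter, while `estimate` keeps the
#' as-modelled sign.
#'
#' @param cohort a `cohort_table` (see [build_cohort_table()] or
#'   [simulate_cohort()]`$truth`): long format, one row per subject-visit.
#' @param parameters which columns to analyse (default the seven analysis
#'   variables).
#' @param mode `"pooled"` (one panel fit with all parameters sharing the
#'   subject random effect, the default) or `"per_parameter"` (a separate
#'   two-visit panel per parameter). Point estimates are identical; CIs
#'   differ slightly through the variance components.
#' @param conf_level confidence level (default 0.95).
#' @return `data.frame` of class `"standardized_change"`, one row per
#'   parameter: `parameter`, `estimate`, `ci_low`, `ci_high` (standardized
#'   units), `oriented_estimate`, `oriented_ci_low`, `oriented_ci_high`,
#'   `orientation`, plus the raw-scale `raw_mean_change`, `raw_ci_low`,
#'   `raw_ci_high`.
#' @export
standardized_change_panel <- function(cohort,
                                      parameters = c("volume_mm3", "rer", "re_late",
                                                     "re_max", "ve", "ktrans", "koos_pain"),
                                      mode = c("pooled", "per_parameter"),
                                      conf_level = 0.95) {
  mode <- match.arg(mode)
  stopifnot(is.data.frame(cohort))
  missing_cols <- setdiff(c("subject_id", "visit", parameters), names(cohort))
  if (length(missing_cols))
    stop("cohort table missing columns: ", paste(missing_cols, collapse = ", "))
  if (!all(cohort$visit %in% c("baseline", "followup")))
    stop("visit must be 'baseline' or 'followup'")
  cohort <- cohort[order(cohort$subject_id, cohort$visit), , drop = FALSE]
  cnt <- table(cohort$subject_id, cohort$visit)
  if (!all(cnt == 1L))
    stop("panel is unbalanced: every subject needs exactly one baseline and one followup row")
  for (p in parameters)
    if (any(!is.finite(cohort[[p]]))) stop("non-finite values in parameter '", p, "'")

  n_sub <- length(unique(cohort$subject_id))
  visit01 <- as.numeric(cohort$visit == "followup")

  z <- lapply(parameters, function(p) pooled_zscore(cohort[[p]], p))
  names(z) <- parameters

  extract_one <- function(fit, key) {
    est <- fit$coefficients[[key]]
    data.frame(estimate = est, ci_low = fit$ci_low[[key]], ci_high = fit$ci_high[[key]])
  }

  if (mode == "pooled") {
    np <- length(parameters)
    y <- unlist(z, use.names = FALSE)
    subj <- rep(cohort$subject_id, np)
    type <- rep(parameters, each = nrow(cohort))
    vis <- rep(visit01, np)
    X_type <- stats::model.matrix(~ 0 + factor(type, levels = parameters))
    colnames(X_type) <- parameters
    X_int <- X_type * vis
    colnames(X_int) <- paste0(parameters, ":visit")
    fit <- panel_re_fit(y, subj, cbind(X_type, X_int), conf_level)
    rows <- do.call(rbind, lapply(parameters, function(p)
      extract_one(fit, paste0(p, ":visit"))))
  } else {
    rows <- do.call(rbind, lapply(parameters, function(p) {
      X <- cbind(`(Intercept)` = 1, visit = visit01)
      fit <- panel_re_fit(z[[p]], cohort$subject_id, X, conf_level)
      extract_one(fit, "visit")
    }))
  }

  raw <- do.call(rbind, lapply(parameters, function(p) {
    b <- cohort[[p]][cohort$visit == "baseline"]
    f <- cohort[[p]][cohort$visit == "followup"]
    mc <- mean_change(b, f, conf_level)
    data.frame(raw_mean_change = mc$mean_change,
               raw_ci_low = mc$ci_low, raw_ci_high = mc$ci_high)
  }))

  flip <- parameters == "koos_pain"
  out <- data.frame(parameter = parameters, rows,
                    oriented_estimate = ifelse(flip, -rows$estimate, rows$estimate),
                    oriented_ci_low = ifelse(flip, -rows$ci_high, rows$ci_low),
                    oriented_ci_high = ifelse(flip, -rows$ci_low, rows$ci_high),
                    orientation = ifelse(flip, "improvement-negative", "as-modelled"),
                    raw, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "n_subjects") <- n_sub
  attr(out, "mode") <- mode
  class(out) <- c("standardized_change", "data.frame")
  out
}

#' Paired mean change with t-interval
#'
#' Mean within-subject difference (follow-up minus baseline) in the
#' original units, with a Student-t 95 percent confidence interval.
#'
#' @param baseline,followup numeric vectors paired by subject.
#' @param conf_level confidence level.
#' @return List with `mean_change`, `ci_low`, `ci_high`, `n`.
#' @export
mean_change <- function(baseline, followup, conf_level = 0.95) {
  stopifnot(length(baseline) == length(followup))
  d <- followup - baseline
  d <- d[is.finite(d)]
  n <- length(d)
  if (n < 2L) stop("need at least 2 complete pairs")
  m <- mean(d)
  se <- stats::sd(d) / sqrt(n)
  tq <- stats::qt(1 - (1 - conf_level) / 2, df = n - 1L)
  list(mean_change = m, ci_low = m - tq * se, ci_high = m + tq * se, n = n)
}

#' Percent reduction at follow-up
#'
#' Mean reduction expressed as a percentage of the baseline mean:
#' `-100 * mean_change / baseline_mean`.
#'
#' @param baseline,followup paired per-subject values.
#' @return Percentage (positive for a reduction).
#' @export
percent_reduction <- function(baseline, followup) {
  stopifnot(length(baseline) == length(followup))
  -100 * mean(followup - baseline) / mean(baseline)
}

#' Association between parameter change and pain change
#'
#' Bivariate ordinary least squares of KOOS pain change on the change in
#' one imaging parameter (unstandardized coefficient `b` with its
#' confidence interval and two-sided p-value), together with the Pearson
#' correlation `r` and its Fisher-z confidence interval.
#'
#' @param delta_param per-subject change in the imaging parameter.
#' @param delta_koos per-subject change in the KOOS pain subscale.
#' @param conf_level confidence level.
#' @return List of class `"association_result"`: `b`, `b_ci_low`,
#'   `b_ci_high`, `p`, `r`, `r_ci_low`, `r_ci_high`, `n`.
#' @export
association <- function(delta_param, delta_koos, conf_level = 0.95) {
  stopifnot(length(delta_param) == length(delta_koos))
  ok <- is.finite(delta_param) & is.finite(delta_koos)
  x <- delta_param[ok]; y <- delta_koos[ok]
  if (length(x) < 4L) stop("need at least 4 complete pairs")
  if (stats::sd(x) == 0) stop("predictor change is constant")
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  ci <- stats::confint(fit, level = conf_level)["x", ]
  ct <- stats::cor.test(x, y, method = "pearson", conf.level = conf_level)
  structure(list(b = unname(stats::coef(fit)[["x"]]),
                 b_ci_low = unname(ci[1L]), b_ci_high = unname(ci[2L]),
                 p = sm$coefficients["x", "Pr(>|t|)"],
                 r = unname(ct$estimate),
                 r_ci_low = unname(ct$conf.int[1L]),
                 r_ci_high = unname(ct$conf.int[2L]),
                 n = length(x)),
            class = "association_result")
}

#' Association table for a two-visit cohort
#'
#' Runs [association()] of KOOS pain change against the change in each
#' imaging parameter of a cohort table. Synovial volume is converted from
#' mm^3 to cm^3 before regression so its `b` coefficient is per cm^3.
#'
#' @param cohort a balanced two-visit `cohort_table`.
#' @param parameters imaging parameters to test.
#' @param conf_level confidence level.
#' @return `data.frame` with one row per parameter: `parameter`, `b`,
#'   `b_ci_low`, `b_ci_high`, `p`, `r`, `r_ci_low`, `r_ci_high`, `n`.
#' @export
association_table <- function(cohort,
                              parameters = c("volume_mm3", "rer", "re_late",
                                             "re_max", "ve", "ktrans"),
                              conf_level = 0.95) {
  stopifnot(is.data.frame(cohort))
  cohort <- cohort[order(cohort$subject_id, cohort$visit), , drop = FALSE]
  bl <- cohort[cohort$visit == "baseline", , drop = FALSE]
  fu <- cohort[cohort$visit == "followup", , drop = FALSE]
  if (!identical(bl$subject_id, fu$subject_id)) stop("panel is unbalanced")
  d_koos <- fu$koos_pain - bl$koos_pain
  rows <- lapply(parameters, function(p) {
    d <- fu[[p]] - bl[[p]]
    if (p == "volume_mm3") d <- d / 1000  # report volume slope per cm^3
    a <- association(d, d_koos, conf_level)
    data.frame(parameter = p, b = a$b, b_ci_low = a$b_ci_low,
               b_ci_high = a$b_ci_high, p = a$p, r = a$r,
               r_ci_low = a$r_ci_low, r_ci_high = a$r_ci_high, n = a$n,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
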