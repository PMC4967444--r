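# Seeded synthetic DCE-MRI cohorts with known ground truth.

# Run code under a temporary RNG state so generators are pure functions of
# (inputs, seed) and never disturb the caller's RNG.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

#' Per-subject child seed from a master seed
#'
#' Stable string hash of `(master_seed, subject_id)` into `[0, 2^31 - 2]`,
#' so that enlarging a cohort never perturbs the draws of earlier subjects.
#'
#' @param master_seed integer master seed.
#' @param subject_id subject identifier (coerced to character).
#' @return A single integer seed.
#' @export
subject_seed <- function(master_seed, subject_id) {
  h <- as.numeric(master_seed) %% 2147483647
  for (ch in utf8ToInt(paste0("s:", subject_id))) h <- (h * 31 + ch) %% 2147483647
  as.integer(h)
}

# lognormal parameters matching a target mean and SD
.lnorm_par <- function(m, s) {
  sigma2 <- log(1 + (s / m)^2)
  list(mu = log(m) - sigma2 / 2, sigma = sqrt(sigma2))
}

#' Baseline population of the synthetic cohort
#'
#' Distributional targets for the pre-treatment visit. Kinetic parameters
#' and synovial volume are lognormal (right-skewed, strictly positive, as
#' ROI medians of perfusion parameters are in practice); the KOOS pain score
#' is normal truncated to its 0-100 instrument range. Defaults emulate a
#' 93-patient knee osteoarthritis cohort imaged before and about 10 days
#' after intra-articular methylprednisolone.
#'
#' @param ktrans_mean,ktrans_sd volume transfer coefficient, per minute.
#' @param ve_mean,ve_sd fractional EES volume (draws clipped to `[0.02, 0.95]`).
#' @param vp_mean,vp_sd fractional plasma volume (clipped to `[0, 0.2]`).
#' @param volume_mean,volume_sd synovial tissue volume, mm^3.
#' @param koos_mean,koos_sd baseline KOOS pain subscale (0-100).
#' @param s0 pre-contrast signal level, scanner units.
#' @param gain signal units per unit concentration (shared with fitting).
#' @param noise_sd additive Gaussian signal noise, scanner units.
#' @param voxel_jitter_sd lognormal SD of voxel-level parameter jitter
#'   inside the ROI when volumes are rendered.
#' @return List of class `"cohort_population"`.
#' @export
cohort_population <- function(ktrans_mean = 0.045, ktrans_sd = 0.033,
                              ve_mean = 0.31, ve_sd = 0.22,
                              vp_mean = 0.02, vp_sd = 0.01,
                              volume_mean = 9601, volume_sd = 5251,
                              koos_mean = 46.75, koos_sd = 14.40,
                              s0 = 100, gain = 5, noise_sd = 2,
                              voxel_jitter_sd = 0.1) {
  stopifnot(ktrans_mean > 0, ve_mean > 0, volume_mean > 0, s0 > 0,
            gain > 0, noise_sd >= 0, voxel_jitter_sd >= 0)
  structure(as.list(environment()), class = "cohort_population")
}

#' Treatment effect of the synthetic cohort
#'
#' Multiplicative mean reductions applied at follow-up to the kinetic
#' parameters and to the ROI size, with subject-level lognormal
#' heterogeneity of the reduction multiplier (truncated so follow-up values
#' never exceed baseline). Defaults reproduce the mean reductions observed
#' after intra-articular steroid: Ktrans 0.045 to 0.029, ve 0.31 to 0.22,
#' synovial volume 9601 to 8119 mm^3.
#'
#' @param ktrans,ve,vp,volume mean fractional reductions in `[0, 1)`.
#' @param heterogeneity_sd lognormal SD of the subject-level multiplier on
#'   the reduction.
#' @return List of class `"cohort_effect"`.
#' @export
cohort_effect <- function(ktrans = 1 - 0.029 / 0.045,
                          ve = 1 - 0.22 / 0.31,
                          vp = 1 - 0.029 / 0.045,
                          volume = 1 - 8119 / 9601,
                          heterogeneity_sd = 0.25) {
  stopifnot(ktrans >= 0, ktrans < 1, ve >= 0, ve < 1, vp >= 0, vp < 1,
            volume >= 0, volume < 1, heterogeneity_sd >= 0)
  structure(list(ktrans = ktrans, ve = ve, vp = vp, volume = volume,
                 heterogeneity_sd = heterogeneity_sd), class = "cohort_effect")
}

#' Pain model linking enhancement change to KOOS change
#'
#' The simulated KOOS pain change is a linear function of the standardized
#' true change in late relative enhancement plus independent noise, with a
#' negative loading on the standardized baseline score (patients in more
#' pain improve more, which also keeps the follow-up score dispersion
#' realistic). `r` is the target correlation between KOOS change and
#' RE_late change; since KOOS rises with improvement while enhancement
#' falls, the target is negative.
#'
#' @param mean_change mean KOOS improvement at follow-up (default +22.93).
#' @param sd_change SD of the KOOS change (default 19.8).
#' Because the recorded score is truncated to the 0-100 instrument range,
#' a fixed latent loading would deliver a slightly attenuated recorded
#' correlation. With `calibrate = TRUE` (default) the generator therefore
#' solves for the loading that makes the recorded scores hit the target
#' correlation — the same philosophy as exact-moment mode, applied to the
#' correlation target; with `calibrate = FALSE` the loading is the target
#' itself, applied on the latent (unbounded) scale.
#'
#' @param r target Pearson correlation between KOOS change and true RE_late
#'   change, in `(-1, 1)`.
#' @param baseline_coupling correlation between KOOS change and baseline
#'   KOOS (negative default -0.42 keeps follow-up SD near 19).
#' @param calibrate solve for the loading on the recorded (bounded) scale.
#' @return List of class `"pain_link"`.
#' @export
pain_link <- function(mean_change = 22.93, sd_change = 19.8, r = -0.27,
                      baseline_coupling = -0.42, calibrate = TRUE) {
  stopifnot(sd_change >= 0, abs(r) < 1, abs(baseline_coupling) < 1,
            r^2 + baseline_coupling^2 < 1)
  structure(list(mean_change = mean_change, sd_change = sd_change, r = r,
                 baseline_coupling = baseline_coupling,
                 calibrate = isTRUE(calibrate)), class = "pain_link")
}

#' Per-visit moment targets of the emulated cohort
#'
#' Means and SDs of the seven analysis variables at each visit in the
#' 93-patient steroid-injection cohort the generator emulates. Used as
#' targets for exact-moment cohorts and as documentation of what the
#' sampled generator aims at.
#'
#' @return `data.frame` with columns `variable`, `mean_baseline`,
#'   `sd_baseline`, `mean_followup`, `sd_followup`.
#' @export
reference_visit_moments <- function() {
  data.frame(
    variable      = c("volume_mm3", "rer", "re_late", "re_max", "ve", "ktrans", "koos_pain"),
    mean_baseline = c(9601, 0.048, 3.10, 3.51, 0.31, 0.045, 46.75),
    sd_baseline   = c(5251, 0.030, 1.37, 1.46, 0.22, 0.033, 14.40),
    mean_followup = c(8119, 0.032, 2.35, 2.65, 0.22, 0.029, 69.68),
    sd_followup   = c(4353, 0.020, 1.12, 1.17, 0.23, 0.028, 18.99),
    stringsAsFactors = FALSE
  )
}

# affine rescale so that sample mean/SD (n-1 denominator) equal the targets
moment_match <- function(x, mean_target, sd_target) {
  s <- stats::sd(x)
  if (s == 0) stop("cannot moment-match a constant vector")
  mean_target + sd_target * (x - mean(x)) / s
}

#' Simulate one voxel's signal curve
#'
#' Forward-simulates the extended Tofts tissue curve for the given
#' parameters and AIF, then applies the linear signal model
#' `S_i = s0 * (1 + gain * Ct(t_i)) + e_i`, `e_i ~ N(0, noise_sd)`, at the
#' protocol's frame times.
#'
#' @param tofts a [tofts_params()] set.
#' @param aif the population [aif()].
#' @param protocol the [dce_protocol()].
#' @param s0 baseline signal, positive.
#' @param gain signal units per unit concentration, non-negative.
#' @param noise_sd additive Gaussian noise SD, signal units.
#' @param seed integer seed (ignored when `noise_sd = 0`).
#' @return A [signal_series()].
#' @export
simulate_signal_curve <- function(tofts, aif, protocol, s0 = 100, gain = 5,
                                  noise_sd = 0, seed = 1L) {
  stopifnot(inherits(tofts, "tofts_params"))
  if (!is.finite(s0) || s0 <= 0) stop("s0 must be positive")
  if (gain < 0) stop("gain must be non-negative")
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  t_min <- protocol_frame_times(protocol, "minutes")
  ct <- extended_tofts_forward(tofts, aif, t_min)$ct
  sig <- s0 * (1 + gain * ct)
  if (noise_sd > 0)
    sig <- sig + with_seed(seed, stats::rnorm(length(sig), 0, noise_sd))
  signal_series(sig, protocol)
}

# noiseless enhancement metrics for vectors of parameter sets (one column of
# tofts_ct_grid per subject), on a protocol's frame times
true_enhancement_metrics <- function(ktrans, ve, vp, aif_obj, protocol, gain) {
  t_s <- protocol_frame_times(protocol)
  ct <- tofts_ct_grid(ktrans, ve, vp, aif_obj)
  # sample the dense grid at the frame times (grids include the frame times
  # when dt divides the frame interval; interpolate to be safe)
  ctf <- apply(ct, 2L, function(col) stats::approx(aif_obj$times, col, xout = t_s)$y)
  ctf <- matrix(ctf, nrow = length(t_s))
  nfr <- nrow(ctf)
  dt_min <- diff(t_s) / 60
  re_late <- 1 + gain * colMeans(ctf[(nfr - 3L):nfr, , drop = FALSE])
  re_max <- 1 + gain * apply(ctf, 2L, max)
  rer <- gain * apply(ctf, 2L, function(col) max(diff(col) / dt_min))
  list(rer = rer, re_max = re_max, re_late = re_late)
}

#' Ground-truth description of one synthetic subject
#'
#' Bundles everything needed to render a subject's dynamic volumes and to
#' score parameter recovery: true kinetic parameters and ROI volume at each
#' visit, KOOS pain scores, acquisition protocol and signal model.
#'
#' @param subject_id identifier.
#' @param protocol a [dce_protocol()].
#' @param params list with `baseline` and `followup` [tofts_params()].
#' @param volume_mm3 named numeric, true synovial volume at `baseline` and
#'   `followup`.
#' @param koos_pain named numeric in `[0, 100]` at both visits.
#' @param s0_true,gain,noise_sd,voxel_jitter_sd signal model constants.
#' @param seed subject-level seed used for rendering.
#' @return List of class `"ground_truth_subject"`.
#' @export
ground_truth_subject <- function(subject_id, protocol, params, volume_mm3,
                                 koos_pain, s0_true = 100, gain = 5,
                                 noise_sd = 0, voxel_jitter_sd = 0,
                                 seed = 1L) {
  stopifnot(inherits(protocol, "dce_protocol"),
            inherits(params$baseline, "tofts_params"),
            inherits(params$followup, "tofts_params"))
  if (any(koos_pain < 0 | koos_pain > 100)) stop("koos_pain must lie in [0, 100]")
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  if (any(volume_mm3 < 0)) stop("volume must be non-negative")
  structure(list(subject_id = as.character(subject_id), protocol = protocol,
                 params = params, volume_mm3 = volume_mm3,
                 koos_pain = koos_pain, s0_true = s0_true, gain = gain,
                 noise_sd = noise_sd, voxel_jitter_sd = voxel_jitter_sd,
                 seed = as.integer(seed)),
            class = "ground_truth_subject")
}

#' Simulate a two-visit synthetic cohort with known truth
#'
#' Draws per-subject baseline kinetics, synovial volume and pain from the
#' population model, applies the multiplicative treatment effect at
#' follow-up, derives the true (noiseless) enhancement metrics from the
#' forward model, and links the pain change to the true RE_late change.
#' Every subject draw comes from its own child seed (see [subject_seed()]),
#' so the cohort is reproducible and extensible.
#'
#' In `moment_mode = "exact"` the seven variables of the returned truth
#' table are affine-rescaled per visit so their sample means and SDs equal
#' the `moments` targets to machine precision (ranks and cross-correlations
#' are preserved). Exact-moment cohorts are tabular: they are meant for the
#' statistics stage and are not guaranteed to respect instrument bounds or
#' the forward-model link between parameters and metrics.
#'
#' @param n_subjects number of subjects, at least 2.
#' @param effect a [cohort_effect()].
#' @param pain_model a [pain_link()].
#' @param population a [cohort_population()].
#' @param protocol_mix fraction of subjects on the LTR protocol (default
#'   16/93).
#' @param seed master seed.
#' @param moment_mode `"sampled"` (default) or `"exact"`.
#' @param moments per-visit targets for exact mode, as
#'   [reference_visit_moments()].
#' @return List of class `"dce_cohort"`: `subjects` (list of
#'   [ground_truth_subject()]), `truth` (a `cohort_table` of true values:
#'   `subject_id, visit, protocol, volume_mm3, rer, re_late, re_max,
#'   ktrans, ve, koos_pain`), and the generating configuration.
#' @export
simulate_cohort <- function(n_subjects,
                            effect = cohort_effect(),
                            pain_model = pain_link(),
                            population = cohort_population(),
                            protocol_mix = 16 / 93,
                            seed = 1L,
                            moment_mode = c("sampled", "exact"),
                            moments = reference_visit_moments()) {
  moment_mode <- match.arg(moment_mode)
  if (n_subjects < 2L) stop("n_subjects must be at least 2")
  if (protocol_mix < 0 || protocol_mix > 1) stop("protocol_mix must be in [0, 1]")
  zero_effect <- effect$ktrans == 0 && effect$ve == 0 && effect$vp == 0 &&
    effect$heterogeneity_sd == 0
  if (zero_effect && pain_model$r != 0)
    stop("degenerate effect: no enhancement change anywhere but correlation target is nonzero")

  kt_p <- .lnorm_par(population$ktrans_mean, population$ktrans_sd)
  ve_p <- .lnorm_par(population$ve_mean, population$ve_sd)
  vp_p <- .lnorm_par(population$vp_mean, population$vp_sd)
  vol_p <- .lnorm_par(population$volume_mean, population$volume_sd)
  het <- effect$heterogeneity_sd

  ids <- sprintf("S%03d", seq_len(n_subjects))
  n <- n_subjects
  kt_bl <- ve_bl <- vp_bl <- vol_bl <- koos_bl <- numeric(n)
  red <- matrix(0, n, 4L, dimnames = list(NULL, c("ktrans", "ve", "vp", "volume")))
  on_ltr <- logical(n)
  eps_pain <- numeric(n)
  for (i in seq_len(n)) {
    si <- subject_seed(seed, ids[i])
    draws <- with_seed(si, list(
      kt = stats::rlnorm(1, kt_p$mu, kt_p$sigma),
      ve = stats::rlnorm(1, ve_p$mu, ve_p$sigma),
      vp = stats::rlnorm(1, vp_p$mu, vp_p$sigma),
      vol = stats::rlnorm(1, vol_p$mu, vol_p$sigma),
      koos = stats::rnorm(1, population$koos_mean, population$koos_sd),
      mult = if (het > 0) stats::rlnorm(4, -het^2 / 2, het) else rep(1, 4),
      u_prot = stats::runif(1),
      eps = stats::rnorm(1)
    ))
    kt_bl[i] <- draws$kt
    ve_bl[i] <- min(max(draws$ve, 0.02), 0.95)
    vp_bl[i] <- min(draws$vp, 0.2)
    vol_bl[i] <- draws$vol
    koos_bl[i] <- min(max(draws$koos, 0), 100)
    red[i, ] <- pmin(pmax(c(effect$ktrans, effect$ve, effect$vp, effect$volume) *
                            draws$mult, 0), 1)
    on_ltr[i] <- draws$u_prot < protocol_mix
    eps_pain[i] <- draws$eps
  }
  vp_bl <- pmin(vp_bl, 1 - ve_bl)

  kt_fu <- kt_bl * (1 - red[, "ktrans"])
  ve_fu <- pmax(ve_bl * (1 - red[, "ve"]), 1e-3)
  vp_fu <- vp_bl * (1 - red[, "vp"])
  vol_fu <- vol_bl * (1 - red[, "volume"])

  protos <- list(standard = dce_protocol("standard"), ltr = dce_protocol("ltr"))
  aifs <- lapply(protos, function(p) make_population_aif(aif_params(), p))
  met <- list()
  for (visit in c("bl", "fu")) {
    kt <- if (visit == "bl") kt_bl else kt_fu
    vv <- if (visit == "bl") ve_bl else ve_fu
    pp <- if (visit == "bl") vp_bl else vp_fu
    m <- list(rer = numeric(n), re_max = numeric(n), re_late = numeric(n))
    for (pn in c("standard", "ltr")) {
      sel <- if (pn == "ltr") on_ltr else !on_ltr
      if (!any(sel)) next
      mm <- true_enhancement_metrics(kt[sel], vv[sel], pp[sel], aifs[[pn]],
                                     protos[[pn]], population$gain)
      m$rer[sel] <- mm$rer; m$re_max[sel] <- mm$re_max; m$re_late[sel] <- mm$re_late
    }
    met[[visit]] <- m
  }

  d_relate <- met$fu$re_late - met$bl$re_late
  if (stats::sd(d_relate) == 0 && pain_model$r != 0)
    stop("degenerate effect: RE_late change has zero variance but correlation target is nonzero")
  z_re <- if (stats::sd(d_relate) > 0) (d_relate - mean(d_relate)) / stats::sd(d_relate)
          else numeric(n)
  z_bl <- if (stats::sd(koos_bl) > 0) (koos_bl - mean(koos_bl)) / stats::sd(koos_bl)
          else numeric(n)
  c_b <- pain_model$baseline_coupling
  koos_from_loading <- function(lam) {
    c_res <- sqrt(max(1 - lam^2 - c_b^2, 0))
    d <- pain_model$mean_change + pain_model$sd_change *
      (lam * z_re + c_b * z_bl + c_res * eps_pain)
    pmin(pmax(koos_bl + d, 0), 100)
  }
  lam <- pain_model$r
  if (pain_model$calibrate && pain_model$r != 0 && stats::sd(d_relate) > 0) {
    lam_max <- sqrt(1 - c_b^2) - 1e-6
    gap <- function(l) stats::cor(koos_from_loading(l) - koos_bl, d_relate) - pain_model$r
    lam <- tryCatch(
      stats::uniroot(gap, lower = -lam_max, upper = lam_max, tol = 1e-8)$root,
      error = function(e) pain_model$r)  # target unreachable: fall back to latent loading
  }
  koos_fu <- koos_from_loading(lam)

  truth <- data.frame(
    subject_id = rep(ids, each = 2L),
    visit = rep(c("baseline", "followup"), n),
    protocol = rep(ifelse(on_ltr, "ltr", "standard"), each = 2L),
    volume_mm3 = as.vector(rbind(vol_bl, vol_fu)),
    rer = as.vector(rbind(met$bl$rer, met$fu$rer)),
    re_late = as.vector(rbind(met$bl$re_late, met$fu$re_late)),
    re_max = as.vector(rbind(met$bl$re_max, met$fu$re_max)),
    ktrans = as.vector(rbind(kt_bl, kt_fu)),
    ve = as.vector(rbind(ve_bl, ve_fu)),
    koos_pain = as.vector(rbind(koos_bl, koos_fu)),
    stringsAsFactors = FALSE
  )

  if (moment_mode == "exact") {
    for (v in seq_len(nrow(moments))) {
      var <- moments$variable[v]
      bl <- truth$visit == "baseline"
      truth[[var]][bl] <- moment_match(truth[[var]][bl],
                                       moments$mean_baseline[v], moments$sd_baseline[v])
      truth[[var]][!bl] <- moment_match(truth[[var]][!bl],
                                        moments$mean_followup[v], moments$sd_followup[v])
    }
  }
  class(truth) <- c("cohort_table", "data.frame")

  subjects <- vector("list", n)
  for (i in seq_len(n)) {
    pr <- protos[[if (on_ltr[i]) "ltr" else "standard"]]
    subjects[[i]] <- ground_truth_subject(
      subject_id = ids[i], protocol = pr,
      params = list(
        baseline = tofts_params(kt_bl[i], ve_bl[i], min(vp_bl[i], 1 - ve_bl[i])),
        followup = tofts_params(kt_fu[i], ve_fu[i], min(vp_fu[i], 1 - ve_fu[i]))),
      volume_mm3 = c(baseline = vol_bl[i], followup = vol_fu[i]),
      koos_pain = c(baseline = koos_bl[i], followup = koos_fu[i]),
      s0_true = population$s0, gain = population$gain,
      noise_sd = population$noise_sd,
      voxel_jitter_sd = population$voxel_jitter_sd,
      seed = subject_seed(seed, ids[i]))
  }

  structure(list(subjects = subjects, truth = truth,
                 config = list(n_subjects = n, effect = effect,
                               pain_model = pain_model, population = population,
                               protocol_mix = protocol_mix, seed = seed,
                               moment_mode = moment_mode)),
            class = "dce_cohort")
}

# deterministic compact mask: the n_vox voxels nearest the grid centre
.center_mask <- function(n_vox, grid_shape, voxel_size) {
  if (n_vox > prod(grid_shape)) stop("mask does not fit inside the grid")
  ctr <- (grid_shape + 1) / 2
  g <- expand.grid(i = seq_len(grid_shape[1L]), j = seq_len(grid_shape[2L]),
                   k = seq_len(grid_shape[3L]))
  d2 <- ((g$i - ctr[1L]) * voxel_size[1L])^2 +
        ((g$j - ctr[2L]) * voxel_size[2L])^2 +
        ((g$k - ctr[3L]) * voxel_size[3L])^2
  ord <- order(d2, g$k, g$j, g$i)
  idx <- as.matrix(g[ord[seq_len(n_vox)], , drop = FALSE])
  roi_mask(idx, voxel_size = voxel_size, dim = grid_shape)
}

#' Render a subject-visit as a 4D dynamic volume and ROI mask
#'
#' Voxels inside the synovium mask carry simulated enhancement curves
#' (subject truth parameters with optional voxel-level lognormal jitter);
#' background voxels carry a constant lower signal. Gaussian noise is added
#' everywhere when `noise_sd > 0`. The mask is a compact region around the
#' grid centre whose voxel count realizes the subject's true synovial
#' volume at that visit.
#'
#' @param subject a [ground_truth_subject()].
#' @param visit `"baseline"` or `"followup"`.
#' @param grid_shape voxel grid dimensions, length-3.
#' @param voxel_size voxel edge lengths in mm, length-3.
#' @param out_dir optional directory; when given, the dynamic series and
#'   mask are written as NIfTI files `{subject}_{visit}_dyn.nii.gz` and
#'   `{subject}_{visit}_mask.nii.gz`.
#' @param background_s0 background signal level, scanner units.
#' @return List with `dyn` (4D array), `mask` ([roi_mask()]), and `files`
#'   (character vector of written paths, or `NULL`).
#' @export
render_4d_volume <- function(subject, visit = c("baseline", "followup"),
                             grid_shape = c(24, 24, 6),
                             voxel_size = c(1.5, 1.5, 3.0),
                             out_dir = NULL, background_s0 = 40) {
  stopifnot(inherits(subject, "ground_truth_subject"))
  visit <- match.arg(visit)
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3L || any(grid_shape < 1L)) stop("grid_shape must be 3 positive integers")
  pr <- subject$protocol
  voxvol <- prod(voxel_size)
  n_vox <- max(1L, as.integer(round(subject$volume_mm3[[visit]] / voxvol)))
  mask <- .center_mask(n_vox, grid_shape, voxel_size)

  p <- subject$params[[visit]]
  vseed <- subject_seed(subject$seed, paste0(visit, ":render"))
  jit <- with_seed(vseed, {
    if (subject$voxel_jitter_sd > 0)
      matrix(stats::rlnorm(2L * n_vox, -subject$voxel_jitter_sd^2 / 2,
                           subject$voxel_jitter_sd), ncol = 2L)
    else matrix(1, n_vox, 2L)
  })
  kt <- p$ktrans * jit[, 1L]
  ve <- pmin(pmax(p$ve * jit[, 2L], 1e-3), 0.95)
  vp <- pmin(rep(p$vp, n_vox), 1 - ve)

  a <- make_population_aif(aif_params(), pr)
  t_s <- protocol_frame_times(pr)
  ct <- tofts_ct_grid(kt, ve, vp, a)
  ctf <- apply(ct, 2L, function(col) stats::approx(a$times, col, xout = t_s)$y)
  ctf <- matrix(ctf, nrow = length(t_s))
  curves <- subject$s0_true * (1 + subject$gain * ctf)  # frames x voxels

  dyn <- array(background_s0, dim = c(grid_shape, pr$n_frames))
  nxyz <- prod(grid_shape)
  for (f in seq_len(pr$n_frames)) {
    sl <- dyn[, , , f]
    sl[mask$indices] <- curves[f, ]
    dyn[, , , f] <- sl
  }
  if (subject$noise_sd > 0) {
    dyn <- dyn + with_seed(subject_seed(subject$seed, paste0(visit, ":noise")),
                           array(stats::rnorm(length(dyn), 0, subject$noise_sd),
                                 dim = dim(dyn)))
  }

  files <- NULL
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    dyn_file <- file.path(out_dir, sprintf("%s_%s_dyn.nii.gz", subject$subject_id, visit))
    mask_file <- file.path(out_dir, sprintf("%s_%s_mask.nii.gz", subject$subject_id, visit))
    im <- RNifti::asNifti(dyn)
    RNifti::pixdim(im) <- c(voxel_size, pr$frame_interval)
    RNifti::writeNifti(im, dyn_file, datatype = "double")
    mi <- RNifti::asNifti(array(as.integer(mask_array(mask)), dim = grid_shape))
    RNifti::pixdim(mi) <- voxel_size
    RNifti::writeNifti(mi, mask_file, datatype = "uint8")
    files <- c(dyn = dyn_file, mask = mask_file)
  }
  list(dyn = dyn, mask = mask, files = files)
}

#' Write a cohort's clinical and truth tables as CSV
#'
#' @param cohort a [simulate_cohort()] result.
#' @param out_dir output directory (created if needed).
#' @return Paths of the written files (`clinical.csv`, `truth.csv`),
#'   invisibly.
#' @export
write_cohort_tables <- function(cohort, out_dir) {
  stopifnot(inherits(cohort, "dce_cohort"))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  truth_file <- file.path(out_dir, "truth.csv")
  clin_file <- file.path(out_dir, "clinical.csv")
  utils::write.csv(cohort$truth, truth_file, row.names = FALSE)
  clin <- cohort$truth[c("subject_id", "visit", "protocol", "koos_pain")]
  utils::write.csv(clin, clin_file, row.names = FALSE)
  invisible(c(clinical = clin_file, truth = truth_file))
}
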