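#' Extended Tofts model parameters
#'
#' The extended Tofts two-compartment model describes contrast exchange
#' between blood plasma and the extravascular extracellular space (EES):
#'
#'   Ct(t) = vp * Cp(t) + Ktrans * integral_0^t Cp(u) exp(-(Ktrans/ve)(t-u)) du
#'
#' @param ktrans volume transfer coefficient, per minute; `ktrans >= 0`.
#' @param ve fractional EES volume into which contrast distributes;
#'   `0 < ve <= 1`.
#' @param vp fractional plasma volume (the "extended" term); `0 <= vp <= 1`
#'   and `ve + vp <= 1`.
#' @return Object of class `"tofts_params"`.
#' @export
tofts_params <- function(ktrans, ve, vp = 0) {
  stopifnot(is.finite(ktrans), is.finite(ve), is.finite(vp))
  if (ktrans < 0) stop("ktrans must be non-negative")
  if (ve <= 0 || ve > 1) stop("ve must be in (0, 1]")
  if (vp < 0 || vp > 1) stop("vp must be in [0, 1]")
  if (ve + vp > 1 + 1e-12) stop("ve + vp must not exceed 1")
  structure(list(ktrans = ktrans, ve = ve, vp = vp), class = "tofts_params")
}

# Tissue concentration on the AIF's own grid for vectors of parameters.
# Returns a length(times) x length(ktrans) matrix. The convolution uses an
# exponentially weighted trapezoidal recursion, exact for piecewise-linear
# weighting of Cp and O(dt^2) overall:
#   I_j = E * I_{j-1} + dt_j/2 * (Cp_j + E * Cp_{j-1}),  E = exp(-kep * dt_j)
# Rates are per minute; the grid is in seconds, hence the /60.
tofts_ct_grid <- function(ktrans, ve, vp, aif_obj) {
  stopifnot(inherits(aif_obj, "dce_aif"))
  p <- length(ktrans)
  stopifnot(length(ve) == p, length(vp) == p)
  tt <- aif_obj$times; cp <- aif_obj$cp
  m <- length(tt)
  kep_s <- (ktrans / ve) / 60
  ktrans_s <- ktrans / 60
  ct <- matrix(0, nrow = m, ncol = p)
  I <- numeric(p)
  ct[1L, ] <- vp * cp[1L]
  for (j in 2:m) {
    dtj <- tt[j] - tt[j - 1L]
    E <- exp(-kep_s * dtj)
    I <- E * I + (dtj / 2) * (cp[j] + E * cp[j - 1L])
    ct[j, ] <- vp * cp[j] + ktrans_s * I
  }
  ct
}

#' Extended Tofts forward model
#'
#' Evaluates the tissue concentration curve Ct(t) for one parameter set by
#' trapezoidal convolution of the AIF on its own dense grid, then samples at
#' the requested times by linear interpolation.
#'
#' @param params a [tofts_params()] set.
#' @param aif a [aif()]; its grid must cover all requested times.
#' @param times output sample times in **minutes**, monotone increasing.
#' @return Object of class `"concentration_curve"`: list with `times`
#'   (minutes) and `ct` (same units as the AIF's `cp`).
#' @examples
#' a <- make_population_aif(aif_params(), dce_protocol("standard"))
#' cc <- extended_tofts_forward(tofts_params(0.045, 0.31, 0.02), a,
#'                              protocol_frame_times(dce_protocol("standard"), "minutes"))
#' @export
extended_tofts_forward <- function(params, aif, times) {
  stopifnot(inherits(params, "tofts_params"), inherits(aif, "dce_aif"))
  times <- as.numeric(times)
  if (length(times) < 1L || any(diff(times) <= 0) && length(times) > 1L)
    stop("times must be monotone increasing")
  t_s <- times * 60
  if (min(t_s) < aif$times[1L] - 1e-9 || max(t_s) > aif$times[length(aif$times)] + 1e-9)
    stop("requested times fall outside the AIF's support")
  ct_grid <- tofts_ct_grid(params$ktrans, params$ve, params$vp, aif)[, 1L]
  ct <- stats::approx(aif$times, ct_grid, xout = t_s, rule = 2)$y
  structure(list(times = times, ct = ct), class = "concentration_curve")
}

#' Fit the extended Tofts model to one voxel's signal curve
#'
#' Converts the measured signal to relative enhancement `S/S0 - 1`, divides
#' by the configured signal gain to obtain tissue concentration in AIF units,
#' and fits the extended Tofts forward model by bounded Levenberg-Marquardt
#' least squares. Initialization is a coarse grid over the parameter box
#' (3 x 3 x 2 in Ktrans x ve x vp); the optimizer is started from the
#' best-scoring grid points and the lowest-residual solution is returned,
#' which makes the fit deterministic.
#'
#' Bolus arrival is fixed by the protocol (first post-contrast frame), not
#' estimated per voxel.
#'
#' @param series numeric signal vector of length `protocol$n_frames`, or a
#'   [signal_series()].
#' @param s0 pre-contrast baseline signal (see [baseline_signal()]); must be
#'   positive.
#' @param aif the population [aif()].
#' @param protocol the [dce_protocol()] the series was acquired with.
#' @param gain signal units per unit concentration; the linear
#'   signal-concentration convention `S = S0 (1 + gain * Ct)` shared with
#'   the synthetic generator.
#' @param bounds list with elements `ktrans`, `ve`, `vp`, each `c(lower,
#'   upper)`. Defaults cover the physiological range with margin.
#' @param fit_vp fit the plasma-volume term (three-parameter extended model,
#'   the default) or pin `vp = 0` (two-parameter standard model).
#' @param init_grid optional list with vectors `ktrans`, `ve`, `vp` giving
#'   the multi-start grid; defaults to a 3 x 3 x 2 grid inside the bounds.
#' @param n_polish number of best grid starts from which the full optimizer
#'   is run (default 3).
#' @return Object of class `"tofts_fit"`: list with `params`
#'   ([tofts_params()]), `residual_ss`, `converged`, `n_iterations`,
#'   and `error` (TRUE when the series was unusable and the returned
#'   parameters are the lower corner of the bounds).
#' @export
fit_extended_tofts <- function(series, s0, aif, protocol,
                               gain = 5,
                               bounds = list(ktrans = c(0, 5), ve = c(1e-3, 1), vp = c(0, 0.5)),
                               fit_vp = TRUE,
                               init_grid = NULL,
                               n_polish = 3L) {
  if (inherits(series, "signal_series")) series <- series$signal
  series <- as.numeric(series)
  stopifnot(inherits(aif, "dce_aif"), inherits(protocol, "dce_protocol"))
  if (length(series) != protocol$n_frames)
    stop("series length must equal protocol$n_frames")
  failed <- function() {
    structure(list(params = structure(list(ktrans = bounds$ktrans[1],
                                           ve = max(bounds$ve[1], 1e-3),
                                           vp = bounds$vp[1]), class = "tofts_params"),
                   residual_ss = NA_real_, converged = FALSE,
                   n_iterations = 0L, error = TRUE), class = "tofts_fit")
  }
  if (any(!is.finite(series)) || all(series == 0)) return(failed())
  if (!is.finite(s0) || s0 <= 0) return(failed())
  if (gain <= 0) stop("gain must be positive")

  t_s <- protocol_frame_times(protocol)
  ct_obs <- (series / s0 - 1) / gain

  # precompute interpolation of the dense grid onto the frame times
  grid_t <- aif$times
  frame_idx <- findInterval(t_s, grid_t, rightmost.closed = TRUE)
  frame_idx[frame_idx < 1L] <- 1L
  frame_idx[frame_idx >= length(grid_t)] <- length(grid_t) - 1L
  w <- (t_s - grid_t[frame_idx]) / (grid_t[frame_idx + 1L] - grid_t[frame_idx])
  w <- pmin(pmax(w, 0), 1)

  model_ct <- function(th) {
    ct <- tofts_ct_grid(th[1L], th[2L], if (fit_vp) th[3L] else 0, aif)[, 1L]
    ct[frame_idx] * (1 - w) + ct[frame_idx + 1L] * w
  }
  resid_fn <- function(th) model_ct(th) - ct_obs

  if (is.null(init_grid)) {
    init_grid <- list(
      ktrans = c(0.01, 0.1, 0.5),
      ve = c(0.1, 0.3, 0.6),
      vp = c(bounds$vp[1], min(0.05, bounds$vp[2]))
    )
    # keep starts strictly inside the box
    init_grid$ktrans <- pmin(pmax(init_grid$ktrans, bounds$ktrans[1] + 1e-4), bounds$ktrans[2])
    init_grid$ve <- pmin(pmax(init_grid$ve, bounds$ve[1]), bounds$ve[2])
    init_grid$vp <- pmin(pmax(init_grid$vp, bounds$vp[1]), bounds$vp[2])
  }
  starts <- expand.grid(ktrans = init_grid$ktrans, ve = init_grid$ve,
                        vp = if (fit_vp) init_grid$vp else 0)
  starts <- unique(starts)
  ss0 <- apply(starts, 1L, function(th) sum(resid_fn(as.numeric(th))^2))
  ord <- order(ss0)
  n_run <- min(as.integer(n_polish), nrow(starts))

  lower <- c(bounds$ktrans[1], bounds$ve[1], if (fit_vp) bounds$vp[1])
  upper <- c(bounds$ktrans[2], bounds$ve[2], if (fit_vp) bounds$vp[2])
  best <- NULL
  for (r in seq_len(n_run)) {
    th0 <- as.numeric(starts[ord[r], seq_along(lower)])
    fit <- tryCatch(
      minpack.lm::nls.lm(par = th0, lower = lower, upper = upper,
                         fn = resid_fn,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 200, ftol = 1e-8, ptol = 1e-8)),
      error = function(e) NULL)
    if (is.null(fit)) next
    ss <- sum(fit$fvec^2)
    if (is.null(best) || ss < best$ss - 1e-15) {
      best <- list(par = fit$par, ss = ss, info = fit$info, niter = fit$niter)
    }
  }
  if (is.null(best)) return(failed())
  th <- best$par
  ve_hat <- min(max(th[2L], 1e-3), 1)
  vp_hat <- if (fit_vp) min(th[3L], 1 - ve_hat) else 0
  structure(list(
    params = structure(list(ktrans = max(th[1L], 0), ve = ve_hat, vp = max(vp_hat, 0)),
                       class = "tofts_params"),
    residual_ss = best$ss,
    converged = best$info %in% 1:3,
    n_iterations = best$niter,
    error = FALSE), class = "tofts_fit")
}

#' @export
print.tofts_fit <- function(x, ...) {
  cat(sprintf("extended Tofts fit: Ktrans=%.4g /min, ve=%.3g, vp=%.3g (SS=%.3g, %s)\n",
              x$params$ktrans, x$params$ve, x$params$vp, x$residual_ss,
              if (isTRUE(x$converged)) "converged" else "not converged"))
  invisible(x)
}
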