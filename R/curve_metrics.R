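#' Signal time series for one voxel
#'
#' Raw scanner signal intensities S_i at the dynamic frame times of an
#' acquisition protocol.
#'
#' @param signal numeric vector of length `protocol$n_frames`, all finite.
#' @param protocol the [dce_protocol()] the series was acquired with.
#' @return Object of class `"signal_series"`: list with `signal`, `protocol`
#'   and `frame_times` (seconds).
#' @export
signal_series <- function(signal, protocol) {
  stopifnot(inherits(protocol, "dce_protocol"))
  signal <- as.numeric(signal)
  if (length(signal) != protocol$n_frames)
    stop("signal length must equal protocol$n_frames (", protocol$n_frames, ")")
  if (any(!is.finite(signal))) stop("signal values must be finite")
  structure(list(signal = signal, protocol = protocol,
                 frame_times = protocol_frame_times(protocol)),
            class = "signal_series")
}

.series_signal <- function(series) {
  if (inherits(series, "signal_series")) series$signal else as.numeric(series)
}

#' Pre-contrast baseline signal S0
#'
#' Enhancement parameters are expressed relative to the signal before
#' contrast arrival. S0 is the arithmetic mean of all pre-contrast frames
#' (3 frames for the standard protocol, 2 for the LTR protocol); averaging
#' reduces noise relative to using a single frame.
#'
#' @param series a [signal_series()].
#' @return The baseline signal, in scanner units. A non-positive or
#'   non-finite value marks the voxel non-evaluable downstream.
#' @export
baseline_signal <- function(series) {
  stopifnot(inherits(series, "signal_series"))
  k <- series$protocol$precontrast_frames
  if (k < 1L) stop("protocol has no pre-contrast frames")
  mean(series$signal[seq_len(k)])
}

#' Late relative enhancement RE_late
#'
#' The average of the last four points of the enhancement curve relative to
#' the baseline intensity: `(S_n + S_{n-1} + S_{n-2} + S_{n-3}) / (4 * S0)`.
#' A non-enhancing voxel has RE_late = 1.
#'
#' @param series a [signal_series()] or plain numeric signal vector with at
#'   least 4 frames.
#' @param s0 baseline signal, positive (see [baseline_signal()]).
#' @return Dimensionless ratio.
#' @export
re_late <- function(series, s0) {
  x <- .series_signal(series)
  if (length(x) < 4L) stop("RE_late needs at least 4 frames")
  if (!is.finite(s0) || s0 <= 0) stop("s0 must be positive")
  mean(x[(length(x) - 3L):length(x)]) / s0
}

#' Maximum relative enhancement RE_max
#'
#' The maximum point of the enhancement curve relative to the baseline
#' intensity: `max_i S_i / S0`.
#'
#' @inheritParams re_late
#' @return Dimensionless ratio; always `>= re_late` for the same curve.
#' @export
re_max <- function(series, s0) {
  x <- .series_signal(series)
  if (!is.finite(s0) || s0 <= 0) stop("s0 must be positive")
  max(x) / s0
}

#' Maximum relative enhancement rate RER
#'
#' The maximum slope of the enhancement curve relative to the baseline
#' intensity, estimated by consecutive-frame finite differences:
#' `max_i (S_{i+1} - S_i) / (dt_i * S0)` with `dt_i` in minutes. No
#' smoothing is applied; a 3-point centered slope is available via
#' `window = 3`. The result can be negative for monotone-decreasing curves.
#'
#' @inheritParams re_late
#' @param series a [signal_series()] (the protocol supplies the frame
#'   spacing).
#' @param window 2 (consecutive differences, default) or 3 (centered
#'   differences over two frame intervals).
#' @return Rate in per-minute units.
#' @export
rer <- function(series, s0, window = 2L) {
  stopifnot(inherits(series, "signal_series"))
  if (!is.finite(s0) || s0 <= 0) stop("s0 must be positive")
  x <- series$signal
  t_min <- series$frame_times / 60
  if (length(x) < 2L) stop("RER needs at least 2 frames")
  window <- as.integer(window)
  if (window == 2L) {
    slopes <- diff(x) / diff(t_min)
  } else if (window == 3L) {
    if (length(x) < 3L) stop("3-point RER needs at least 3 frames")
    n <- length(x)
    slopes <- (x[3:n] - x[1:(n - 2L)]) / (t_min[3:n] - t_min[1:(n - 2L)])
  } else stop("window must be 2 or 3")
  max(slopes) / s0
}

#' Voxelwise parameter maps over a region of interest
#'
#' Computes, for every voxel inside the mask, the three semi-quantitative
#' enhancement parameters (RER, RE_max, RE_late) and, when an AIF is
#' supplied, the extended Tofts fit (Ktrans, ve, vp). Voxels whose baseline
#' signal S0 is non-positive or non-finite are flagged non-evaluable: their
#' parameters are NA and they are excluded from ROI aggregation.
#'
#' @param volume 4D numeric array `[x, y, z, frame]` with
#'   `dim(volume)[4] == protocol$n_frames`.
#' @param mask a [roi_mask()] on the same spatial grid.
#' @param protocol the [dce_protocol()].
#' @param aif optional population [aif()]; when supplied the Tofts model is
#'   fitted at every evaluable voxel.
#' @param gain signal-per-concentration constant shared with the generator.
#' @param ... further arguments passed to [fit_extended_tofts()].
#' @return `data.frame` with one row per in-mask voxel: columns `i, j, k`
#'   (voxel indices), `s0`, `evaluable`, `rer`, `re_max`, `re_late`, and —
#'   when fitting — `ktrans`, `ve`, `vp`, `converged`. The number of
#'   non-evaluable voxels is reported via `message()`.
#' @export
voxelwise_maps <- function(volume, mask, protocol, aif = NULL, gain = 5, ...) {
  stopifnot(inherits(mask, "roi_mask"), inherits(protocol, "dce_protocol"))
  d <- dim(volume)
  if (length(d) != 4L) stop("volume must be a 4D array")
  if (!all(d[1:3] == mask$dim)) stop("mask and volume grids differ")
  if (d[4L] != protocol$n_frames) stop("4th dimension must equal protocol$n_frames")
  idx <- mask_voxel_indices(mask)
  if (nrow(idx) == 0L) stop("empty mask")

  fit <- !is.null(aif)
  n <- nrow(idx)
  out <- data.frame(i = idx[, 1L], j = idx[, 2L], k = idx[, 3L],
                    s0 = NA_real_, evaluable = FALSE,
                    rer = NA_real_, re_max = NA_real_, re_late = NA_real_)
  if (fit) {
    out$ktrans <- NA_real_; out$ve <- NA_real_; out$vp <- NA_real_
    out$converged <- NA
  }
  for (v in seq_len(n)) {
    sig <- volume[idx[v, 1L], idx[v, 2L], idx[v, 3L], ]
    if (any(!is.finite(sig))) next
    ser <- signal_series(sig, protocol)
    s0 <- baseline_signal(ser)
    out$s0[v] <- s0
    if (!is.finite(s0) || s0 <= 0) next
    out$evaluable[v] <- TRUE
    out$rer[v] <- rer(ser, s0)
    out$re_max[v] <- re_max(ser, s0)
    out$re_late[v] <- re_late(ser, s0)
    if (fit) {
      f <- fit_extended_tofts(ser, s0, aif, protocol, gain = gain, ...)
      if (!f$error) {
        out$ktrans[v] <- f$params$ktrans
        out$ve[v] <- f$params$ve
        out$vp[v] <- f$params$vp
        out$converged[v] <- f$converged
      } else out$evaluable[v] <- FALSE
    }
  }
  n_bad <- sum(!out$evaluable)
  if (n_bad > 0L)
    message(n_bad, " of ", n, " in-mask voxels non-evaluable (excluded from aggregation)")
  out
}
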