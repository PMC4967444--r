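#' Arterial input function container
#'
#' An AIF is the plasma contrast concentration over time in a feeding artery
#' (for the knee, the popliteal artery), and is the driving input of the
#' tracer-kinetic model. Stored as a dense sampled curve.
#'
#' @param times sample times in seconds, strictly increasing, starting at 0
#'   or later.
#' @param cp plasma concentration at `times` (mM in the synthetic data);
#'   must be non-negative and the same length as `times`.
#' @return Object of class `"dce_aif"`: list with `times` (s) and `cp`.
#' @export
aif <- function(times, cp) {
  times <- as.numeric(times); cp <- as.numeric(cp)
  if (length(times) != length(cp)) stop("times and cp must have equal length")
  if (length(times) < 2L) stop("an AIF needs at least two samples")
  if (any(!is.finite(times)) || any(!is.finite(cp))) stop("AIF values must be finite")
  if (any(diff(times) <= 0)) stop("AIF times must be strictly increasing")
  if (any(cp < 0)) stop("plasma concentration must be non-negative")
  structure(list(times = times, cp = cp), class = "dce_aif")
}

#' Parametric bolus parameters for the synthetic population AIF
#'
#' The synthetic AIF is a linear upslope to the bolus peak followed by a
#' biexponential washout: fast redistribution plus slow renal clearance.
#' Concentration is zero before the bolus delay (causality).
#'
#' @param a_fast,a_slow amplitudes (mM) of the fast and slow washout
#'   components; their sum is the peak plasma concentration.
#' @param t_rise upslope duration from bolus arrival to peak, seconds.
#' @param k_fast,k_slow washout rate constants, per second.
#' @return A list of class `"aif_params"`.
#' @export
aif_params <- function(a_fast = 4.2, a_slow = 1.8, t_rise = 10,
                       k_fast = 0.02, k_slow = 4e-4) {
  stopifnot(a_fast >= 0, a_slow >= 0, t_rise > 0, k_fast >= 0, k_slow >= 0)
  structure(list(a_fast = a_fast, a_slow = a_slow, t_rise = t_rise,
                 k_fast = k_fast, k_slow = k_slow), class = "aif_params")
}

#' Synthetic population arterial input function
#'
#' Evaluates the parametric bolus model on a dense regular grid covering the
#' full duration of the acquisition protocol. Used as the stand-in for a
#' measured population AIF (an average over subjects' popliteal-artery
#' curves, see [average_population_aif()]).
#'
#' @param model_params an [aif_params()] description.
#' @param protocol a [dce_protocol()]; the grid spans `[0, last frame time]`.
#' @param bolus_delay bolus arrival time in seconds; defaults to
#'   [protocol_bolus_delay()]. Must lie inside the scan window.
#' @param dt grid resolution in seconds (default 1 s).
#' @return A [aif()] object sampled at resolution `dt`.
#' @examples
#' a <- make_population_aif(aif_params(), dce_protocol("standard"))
#' max(a$cp)  # peak plasma concentration, mM
#' @export
make_population_aif <- function(model_params = aif_params(),
                                protocol = dce_protocol("standard"),
                                bolus_delay = NULL, dt = 1) {
  stopifnot(inherits(model_params, "aif_params"), inherits(protocol, "dce_protocol"))
  if (is.null(bolus_delay)) bolus_delay <- protocol_bolus_delay(protocol)
  t_end <- (protocol$n_frames - 1) * protocol$frame_interval
  if (!is.finite(bolus_delay) || bolus_delay < 0 || bolus_delay >= t_end)
    stop("bolus_delay must lie inside the scan window [0, ", t_end, ") s")
  if (dt <= 0) stop("dt must be positive")
  times <- seq(0, t_end, by = dt)
  if (times[length(times)] < t_end) times <- c(times, t_end)
  aif(times, eval_aif_model(model_params, times, bolus_delay))
}

# Closed-form evaluation of the bolus model at arbitrary times (seconds).
eval_aif_model <- function(p, times, bolus_delay) {
  peak <- p$a_fast + p$a_slow
  s <- times - bolus_delay
  cp <- numeric(length(times))
  up <- s > 0 & s < p$t_rise
  cp[up] <- peak * s[up] / p$t_rise
  down <- s >= p$t_rise
  sd2 <- s[down] - p$t_rise
  cp[down] <- p$a_fast * exp(-p$k_fast * sd2) + p$a_slow * exp(-p$k_slow * sd2)
  cp
}

#' Average a set of subject AIFs into a population AIF
#'
#' Pointwise arithmetic mean over subjects measured on a common time grid.
#' Grids must match exactly; no resampling is performed.
#'
#' @param subject_aifs list of [aif()] objects on identical time grids.
#' @return The population [aif()] on the shared grid.
#' @export
average_population_aif <- function(subject_aifs) {
  if (!is.list(subject_aifs) || length(subject_aifs) < 1L)
    stop("need at least one AIF")
  if (!all(vapply(subject_aifs, inherits, logical(1), "dce_aif")))
    stop("all elements must be 'dce_aif' objects")
  ref <- subject_aifs[[1L]]$times
  for (a in subject_aifs[-1L]) {
    if (length(a$times) != length(ref) || any(a$times != ref))
      stop("AIF time grids differ; averaging requires a common grid (no silent resampling)")
  }
  cp <- rowMeans(vapply(subject_aifs, `[[`, numeric(length(ref)), "cp"))
  aif(ref, cp)
}

#' Read / write an AIF as two-column delimited text
#'
#' The on-disk format is plain text with a header and two columns,
#' `time_s` and `cp`.
#'
#' @param x an [aif()] object.
#' @param path file path.
#' @return `read_aif` returns an [aif()]; `write_aif` returns `path`
#'   invisibly.
#' @export
write_aif <- function(x, path) {
  stopifnot(inherits(x, "dce_aif"))
  utils::write.table(data.frame(time_s = x$times, cp = x$cp), path,
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_aif
#' @export
read_aif <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t")
  if (!all(c("time_s", "cp") %in% names(d)))
    stop("AIF file must have columns 'time_s' and 'cp'")
  aif(d$time_s, d$cp)
}

#' @export
print.dce_aif <- function(x, ...) {
  cat(sprintf("AIF: %d samples over [%g, %g] s, peak %.3g\n",
              length(x$times), x$times[1], x$times[length(x$times)], max(x$cp)))
  invisible(x)
}
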