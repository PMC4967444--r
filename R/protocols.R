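#' Dynamic acquisition protocols
#'
#' Describes the temporal structure of a dynamic contrast-enhanced (DCE)
#' acquisition: how many 3D volumes are acquired, how far apart, and at which
#' frame the contrast bolus first appears. Two named protocols are built in:
#'
#' * `"standard"`: 18 frames at 22 s intervals, contrast injected between
#'   frames 3 and 4, so the first post-contrast frame is frame 4.
#' * `"ltr"` (lower temporal resolution, used for large knees that need a
#'   different coil): 12 frames at 39 s intervals, contrast injected between
#'   frames 2 and 3, first post-contrast frame 3.
#'
#' Frames are numbered 1-based; all frames before `contrast_arrival_frame`
#' are pre-contrast and are averaged to form the baseline signal S0.
#'
#' @param name `"standard"`, `"ltr"`, or `"custom"`. For `"custom"` all three
#'   numeric fields must be supplied.
#' @param n_frames total number of dynamic frames.
#' @param frame_interval spacing between consecutive frames, seconds.
#' @param contrast_arrival_frame 1-based index of the first post-contrast
#'   frame; must satisfy `2 <= contrast_arrival_frame <= n_frames`.
#' @return An object of class `"dce_protocol"`: a list with fields `name`,
#'   `n_frames`, `frame_interval`, `contrast_arrival_frame` and
#'   `precontrast_frames` (always `contrast_arrival_frame - 1`).
#' @examples
#' p <- dce_protocol("standard")
#' protocol_frame_times(p)   # 0, 22, 44, ... seconds
#' @export
dce_protocol <- function(name = c("standard", "ltr", "custom"),
                         n_frames = NULL, frame_interval = NULL,
                         contrast_arrival_frame = NULL) {
  name <- match.arg(name)
  defaults <- switch(name,
    standard = list(n_frames = 18L, frame_interval = 22, contrast_arrival_frame = 4L),
    ltr      = list(n_frames = 12L, frame_interval = 39, contrast_arrival_frame = 3L),
    custom   = list(n_frames = n_frames, frame_interval = frame_interval,
                    contrast_arrival_frame = contrast_arrival_frame)
  )
  if (!is.null(n_frames)) defaults$n_frames <- n_frames
  if (!is.null(frame_interval)) defaults$frame_interval <- frame_interval
  if (!is.null(contrast_arrival_frame)) defaults$contrast_arrival_frame <- contrast_arrival_frame
  n <- defaults$n_frames
  dt <- defaults$frame_interval
  arr <- defaults$contrast_arrival_frame
  if (is.null(n) || is.null(dt) || is.null(arr))
    stop("custom protocol requires n_frames, frame_interval and contrast_arrival_frame")
  n <- as.integer(n); arr <- as.integer(arr)
  if (!is.finite(dt) || dt <= 0) stop("frame_interval must be positive")
  if (arr < 2L) stop("contrast_arrival_frame must be >= 2 (at least one pre-contrast frame)")
  if (n < arr) stop("n_frames must be >= contrast_arrival_frame")
  structure(list(name = name, n_frames = n, frame_interval = dt,
                 contrast_arrival_frame = arr, precontrast_frames = arr - 1L),
            class = "dce_protocol")
}

#' Frame acquisition times of a protocol
#'
#' @param protocol a [dce_protocol()].
#' @param units `"seconds"` (default) or `"minutes"`.
#' @return Numeric vector of length `n_frames`; frame 1 is acquired at time 0.
#' @export
protocol_frame_times <- function(protocol, units = c("seconds", "minutes")) {
  stopifnot(inherits(protocol, "dce_protocol"))
  units <- match.arg(units)
  t <- (seq_len(protocol$n_frames) - 1) * protocol$frame_interval
  if (units == "minutes") t / 60 else t
}

#' Default bolus arrival time for a protocol
#'
#' Contrast is injected between the last pre-contrast frame and the first
#' post-contrast frame; the nominal arrival time is taken midway between them.
#'
#' @param protocol a [dce_protocol()].
#' @return Arrival time in seconds.
#' @export
protocol_bolus_delay <- function(protocol) {
  stopifnot(inherits(protocol, "dce_protocol"))
  (protocol$contrast_arrival_frame - 1.5) * protocol$frame_interval
}

#' @export
print.dce_protocol <- function(x, ...) {
  cat(sprintf("DCE protocol '%s': %d frames every %g s, first post-contrast frame %d\n",
              x$name, x$n_frames, x$frame_interval, x$contrast_arrival_frame))
  invisible(x)
}
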