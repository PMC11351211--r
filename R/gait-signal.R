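#' Single-channel gait signal
#'
#' Container for a uniformly sampled single-channel IMU time series, typically
#' the sagittal-plane tibial orientation (or angular-velocity) channel of a
#' shank-mounted sensor. Frames are 0-based throughout the package and
#' `time_s = frame / sample_rate_hz`.
#'
#' @param values Numeric vector of samples (degrees). Must be finite.
#' @param sample_rate_hz Positive sampling rate in Hz. Default 60, the usual
#'   rate of consumer IMUs used for gait capture.
#' @param start_frame Integer frame offset of `values[1]` (0-based).
#'
#' @return An object of class `gait_signal`: a list with elements `values`,
#'   `sample_rate_hz` and `start_frame`.
#' @examples
#' s <- gait_signal(sin(seq(0, 2 * pi, length.out = 120)) * 30)
#' length(s)
#' @export
gait_signal <- function(values, sample_rate_hz = 60, start_frame = 0L) {
  values <- as.numeric(values)
  if (length(values) == 0) stop("'values' must contain at least one sample")
  if (!all(is.finite(values))) {
    stop("'values' must be finite; first bad index: ",
         which(!is.finite(values))[1])
  }
  if (!is.numeric(sample_rate_hz) || length(sample_rate_hz) != 1 ||
      !is.finite(sample_rate_hz) || sample_rate_hz <= 0) {
    stop("'sample_rate_hz' must be a single positive number")
  }
  start_frame <- as.integer(start_frame)
  if (is.na(start_frame) || start_frame < 0) {
    stop("'start_frame' must be a non-negative integer")
  }
  structure(
    list(values = values, sample_rate_hz = as.numeric(sample_rate_hz),
         start_frame = start_frame),
    class = "gait_signal"
  )
}

#' @export
length.gait_signal <- function(x) length(x$values)

#' @export
print.gait_signal <- function(x, ...) {
  cat(sprintf("<gait_signal> %d samples @ %g Hz (%.2f s), frames %d..%d\n",
              length(x$values), x$sample_rate_hz,
              length(x$values) / x$sample_rate_hz,
              x$start_frame, x$start_frame + length(x$values) - 1L))
  invisible(x)
}

#' @export
as.data.frame.gait_signal <- function(x, ...) {
  frame <- seq_along(x$values) - 1L + x$start_frame
  data.frame(frame = frame, time_s = frame / x$sample_rate_hz,
             angle_deg = x$values)
}

as_gait_signal <- function(x, sample_rate_hz = 60) {
  if (inherits(x, "gait_signal")) x else gait_signal(x, sample_rate_hz)
}

#' First difference of a gait signal
#'
#' The per-frame change `dy[k] = y[k] - y[k-1]`, the instantaneous gait
#' dynamics on which the DGEI curves are built. Element `k` of the result
#' corresponds to 0-based signal frame `k` (the difference is defined from
#' the second sample onward).
#'
#' @param signal A [gait_signal] or numeric vector of length >= 2.
#' @return Numeric vector of length `length(signal) - 1`.
#' @examples
#' first_difference(c(0, 2, 5, 3))  # 2, 3, -2
#' @export
first_difference <- function(signal) {
  v <- if (inherits(signal, "gait_signal")) signal$values else as.numeric(signal)
  if (length(v) < 2) stop("signal must contain at least 2 samples")
  v[-1] - v[-length(v)]
}
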