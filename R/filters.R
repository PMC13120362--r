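#' Zero-shift Butterworth filtering
#'
#' Applies a Butterworth filter forward and backward ("zero-shift"), so the
#' output has no phase delay. The effective attenuation order is twice the
#' design order, the standard reading of zero-shift filtering in gait
#' analysis. The signal is odd-reflected at both ends before filtering to
#' suppress start/end transients; the padding is removed from the output.
#'
#' @param x numeric vector, uniformly sampled signal.
#' @param fs sampling rate in Hz.
#' @param cutoff cutoff frequency in Hz; a length-2 vector for `type = "pass"`.
#' @param type `"low"`, `"high"` or `"pass"`.
#' @param order filter design order (default 4, doubled in effect by the
#'   forward-backward pass).
#' @return filtered numeric vector, same length as `x`.
#' @export
#' @examples
#' fs <- 500
#' t <- seq(0, 2, by = 1 / fs)
#' x <- sin(2 * pi * 2 * t) + 0.2 * sin(2 * pi * 80 * t)
#' y <- butter_zero_shift(x, fs, 25, "low")
butter_zero_shift <- function(x, fs, cutoff, type = c("low", "high", "pass"),
                              order = 4L) {
  type <- match.arg(type)
  stopifnot(is.numeric(x), fs > 0, all(cutoff > 0), all(cutoff < fs / 2))
  n <- length(x)
  if (n < 10L) stop("signal too short to filter")
  bf <- signal::butter(order, cutoff / (fs / 2), type = type)
  np <- min(n - 1L, 30L * (order + 1L))
  pre <- 2 * x[1L] - x[(np + 1L):2L]
  post <- 2 * x[n] - x[(n - 1L):(n - np)]
  xp <- c(pre, x, post)
  yp <- as.numeric(signal::filter(bf, xp))
  yp <- rev(as.numeric(signal::filter(bf, rev(yp))))
  yp[(np + 1L):(np + n)]
}

#' Low-pass filter force-plate signals
#'
#' Force traces are low-pass filtered at 25 Hz with a 4th-order zero-shift
#' Butterworth filter, once, upstream of both event detection and stride
#' metrics (so nothing is double-smoothed).
#'
#' @param trial a `gait_trial` (see [generate_trial()]).
#' @param cutoff low-pass cutoff in Hz (default 25).
#' @return the trial with `$forces` columns `fz_L`, `fy_L`, `fz_R`, `fy_R`
#'   filtered; `$forces_filtered` is set to `TRUE` so a second call is a
#'   no-op.
#' @export
filter_forces <- function(trial, cutoff = 25) {
  stopifnot(inherits(trial, "gait_trial"))
  if (isTRUE(trial$forces_filtered)) return(trial)
  fs <- trial$meta$rates$force_hz
  for (col in c("fz_L", "fy_L", "fz_R", "fy_R")) {
    trial$forces[[col]] <- butter_zero_shift(trial$forces[[col]], fs, cutoff,
                                             "low")
  }
  trial$forces_filtered <- TRUE
  trial
}
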