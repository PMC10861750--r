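#' Uniformly sampled time series
#'
#' The universal signal carrier between the generative stages and the feature
#' pipeline: a real-valued vector sampled at a fixed rate, with a time origin
#' expressed relative to movement onset (so `t0 = -5` means the first sample
#' lies 5 s before the movement).
#'
#' @param samples Numeric vector of signal values (model units unless stated).
#' @param sampling_rate Sampling rate in Hz, `> 0`.
#' @param t0 Time of the first sample in seconds relative to movement onset.
#' @return An object of class `eeg_ts`.
#' @examples
#' ts <- time_series(sin(2 * pi * 10 * seq(0, 1, by = 1e-3)), 1000)
#' ts_times(ts)[1:3]
#' @export
time_series <- function(samples, sampling_rate, t0 = 0) {
  if (!is.numeric(samples) || length(samples) < 1L)
    stop("`samples` must be a numeric vector of length >= 1")
  if (!is.numeric(sampling_rate) || length(sampling_rate) != 1L ||
      !is.finite(sampling_rate) || sampling_rate <= 0)
    stop("`sampling_rate` must be a single positive number (Hz)")
  if (!is.numeric(t0) || length(t0) != 1L || !is.finite(t0))
    stop("`t0` must be a single finite number (seconds)")
  structure(
    list(samples = as.numeric(samples),
         sampling_rate = as.numeric(sampling_rate),
         t0 = as.numeric(t0)),
    class = "eeg_ts"
  )
}

#' @export
length.eeg_ts <- function(x) length(x$samples)

#' Sample times of a time series
#'
#' @param ts An [time_series()] object.
#' @return Numeric vector of sample times in seconds relative to movement
#'   onset.
#' @export
ts_times <- function(ts) {
  stopifnot(inherits(ts, "eeg_ts"))
  ts$t0 + (seq_along(ts$samples) - 1) / ts$sampling_rate
}

#' @export
print.eeg_ts <- function(x, ...) {
  dur <- length(x$samples) / x$sampling_rate
  cat(sprintf("<eeg_ts> %d samples @ %g Hz (%.3f s), t0 = %g s\n",
              length(x$samples), x$sampling_rate, dur, x$t0))
  invisible(x)
}

#' @export
as.data.frame.eeg_ts <- function(x, ...) {
  data.frame(time = ts_times(x), value = x$samples)
}

# internal: assert two series share length and rate
check_aligned <- function(a, b, what = "series") {
  stopifnot(inherits(a, "eeg_ts"), inherits(b, "eeg_ts"))
  if (length(a$samples) != length(b$samples))
    stop(sprintf("%s length mismatch: %d vs %d", what,
                 length(a$samples), length(b$samples)))
  if (abs(a$sampling_rate - b$sampling_rate) > 1e-9)
    stop(sprintf("%s sampling rate mismatch: %g vs %g Hz", what,
                 a$sampling_rate, b$sampling_rate))
  invisible(TRUE)
}

# internal: analytic signal via frequency-domain construction; used for
# instantaneous phase. Standard one-sided-spectrum method.
analytic_signal <- function(x) {
  n <- length(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  fft(fft(x) * h, inverse = TRUE) / n
}
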