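#' Van der Pol oscillator parameters
#'
#' A small oscillating neuronal assembly in the primary-processing stage is
#' modelled as a van der Pol oscillator
#' \deqn{\ddot Y - (\lambda - Y^2)\dot Y + p^2 Y = F(t),}
#' where `lam` is the bifurcation parameter, `p` the angular frequency in
#' rad/s and `F(t) = forcing_gain * forcing(t)` an additive external drive on
#' the acceleration equation. For `lam <= 0` the origin is stable and the
#' oscillation dies out; for `lam > 0` the system settles on a limit cycle
#' whose amplitude is approximately `2 * sqrt(lam)` for small-to-moderate
#' `lam` (exactly 2 at `lam = 1`).
#'
#' @param lam Bifurcation parameter (dimensionless).
#' @param p Angular frequency in rad/s, `> 0`. `p = 2*pi*f_hz` for a cycle
#'   frequency of `f_hz` Hz.
#' @param forcing_gain Dimensionless gain applied to the external forcing,
#'   `>= 0`. Default 1.
#' @return An object of class `oscillator_params`.
#' @export
oscillator_params <- function(lam = 1, p = 2 * pi * 10, forcing_gain = 1) {
  stopifnot(is.numeric(lam), length(lam) == 1L, is.finite(lam))
  if (!is.numeric(p) || length(p) != 1L || !is.finite(p) || p <= 0)
    stop("`p` must be a single positive angular frequency (rad/s)")
  if (!is.numeric(forcing_gain) || length(forcing_gain) != 1L ||
      !is.finite(forcing_gain) || forcing_gain < 0)
    stop("`forcing_gain` must be a single number >= 0")
  structure(list(lam = lam, p = p, forcing_gain = forcing_gain),
            class = "oscillator_params")
}

#' Van der Pol derivative field
#'
#' Exact algebraic evaluation of the oscillator equation rearranged for the
#' acceleration, with additive forcing:
#' `(dY, dYdot) = (Ydot, (lam - Y^2) * Ydot - p^2 * Y + forcing_gain * f)`.
#'
#' @param state Numeric vector `c(y, ydot)`.
#' @param params An [oscillator_params()] object.
#' @param forcing_value External forcing sample (model units). Default 0.
#' @return Numeric vector `c(dy, dydot)`.
#' @examples
#' vdp_derivatives(c(1, 0), oscillator_params(lam = 1, p = 1))  # c(0, -1)
#' @export
vdp_derivatives <- function(state, params, forcing_value = 0) {
  stopifnot(inherits(params, "oscillator_params"))
  if (!is.numeric(state) || length(state) != 2L || !all(is.finite(state)))
    stop("`state` must be two finite numbers c(y, ydot); non-finite state ",
         "signals numerical blow-up")
  if (!is.finite(forcing_value)) stop("`forcing_value` must be finite")
  y <- state[[1]]; v <- state[[2]]
  c(v,
    (params$lam - y^2) * v - params$p^2 * y +
      params$forcing_gain * forcing_value)
}

#' Simulate a van der Pol oscillator
#'
#' Fixed-step 4th-order Runge-Kutta integration of the oscillator, with
#' optional external forcing held constant over each step (zero-order hold).
#' The default initial state `(0.1, 0)` sits slightly off the origin so that
#' the trajectory escapes the unstable fixed point when `lam > 0`.
#'
#' @param params An [oscillator_params()] object.
#' @param duration Simulation length in seconds.
#' @param dt Integration step in seconds; default 1 ms, matching a 1,000 Hz
#'   sampling rate. Must give at least 10 steps per oscillator period.
#' @param init Initial state `c(y, ydot)`; default `c(0.1, 0)`.
#' @param forcing Optional [time_series()] of forcing values at the
#'   simulation rate with at least `duration / dt` samples, or `NULL`.
#' @param bound Magnitude guard: the simulation aborts with an error if
#'   `|Y|` exceeds this value. Default `1e6`.
#' @return A [time_series()] of the oscillator output `Y(t)` sampled at
#'   `1 / dt` Hz with `t0 = 0` (or the forcing's `t0` when forcing is given).
#' @examples
#' ts <- simulate_oscillator(oscillator_params(lam = 1), duration = 2)
#' measure_amplitude(ts)  # ~2
#' @export
simulate_oscillator <- function(params, duration, dt = 1e-3,
                                init = c(0.1, 0), forcing = NULL,
                                bound = 1e6) {
  stopifnot(inherits(params, "oscillator_params"))
  if (!is.numeric(duration) || duration <= 0) stop("`duration` must be > 0")
  period <- 2 * pi / params$p
  if (dt > period / 10)
    stop(sprintf("dt = %g s gives fewer than 10 steps per oscillator period (%g s)",
                 dt, period))
  if (!all(is.finite(init)) || length(init) != 2L)
    stop("`init` must be two finite numbers")
  n <- as.integer(round(duration / dt))
  t0 <- 0
  fvec <- numeric(0)
  if (!is.null(forcing)) {
    stopifnot(inherits(forcing, "eeg_ts"))
    if (abs(forcing$sampling_rate - 1 / dt) > 1e-6)
      stop("forcing sampling rate must equal 1/dt")
    if (length(forcing$samples) < n)
      stop("forcing is shorter than the simulation")
    fvec <- forcing$samples[seq_len(n)]
    t0 <- forcing$t0
  }
  y <- .vdp_rk4(params$lam, params$p, params$forcing_gain,
                as.numeric(init), n, dt, fvec, bound)
  time_series(y, sampling_rate = 1 / dt, t0 = t0)
}

#' Steady-state amplitude of a trajectory
#'
#' Estimates the steady-state oscillation amplitude as half the peak-to-peak
#' range over the retained tail of the signal, after discarding the leading
#' transient.
#'
#' @param ts A [time_series()].
#' @param discard_fraction Fraction of initial samples to discard in
#'   `[0, 1)`; default 0.5 (steady state defined as the final half).
#' @return Amplitude estimate (signal units).
#' @export
measure_amplitude <- function(ts, discard_fraction = 0.5) {
  stopifnot(inherits(ts, "eeg_ts"))
  if (!is.numeric(discard_fraction) || discard_fraction < 0 ||
      discard_fraction >= 1)
    stop("`discard_fraction` must be in [0, 1)")
  n <- length(ts$samples)
  keep <- ts$samples[(floor(n * discard_fraction) + 1L):n]
  if (length(keep) < 2L) stop("retained segment is empty or trivial")
  (max(keep) - min(keep)) / 2
}

#' Phase-locking value between two signals
#'
#' Quantifies entrainment: instantaneous phases are taken from the analytic
#' signal of each input and the index is the modulus of the mean phasor of
#' the phase difference. 1 means perfect phase locking, values near
#' `1/sqrt(n)` are expected for independent noise.
#'
#' @param ts,reference [time_series()] objects of equal length and rate.
#' @param tail_fraction Fraction of the final samples over which to evaluate
#'   the index (default 1, the whole signal). Entrainment claims are usually
#'   assessed on the tail, after phase convergence.
#' @return Phase-locking value in `[0, 1]`.
#' @export
phase_sync_index <- function(ts, reference, tail_fraction = 1) {
  check_aligned(ts, reference, "phase_sync_index inputs")
  stopifnot(tail_fraction > 0, tail_fraction <= 1)
  ph1 <- Arg(analytic_signal(ts$samples - mean(ts$samples)))
  ph2 <- Arg(analytic_signal(reference$samples - mean(reference$samples)))
  n <- length(ph1)
  idx <- (n - floor(n * tail_fraction) + 1L):n
  Mod(mean(exp(1i * (ph1[idx] - ph2[idx]))))
}

#' Dominant frequency of a signal
#'
#' Frequency of the largest FFT magnitude over the positive-frequency bins
#' (excluding DC), used to verify that a limit-cycle trajectory oscillates
#' at its design frequency.
#'
#' @param ts A [time_series()].
#' @param discard_fraction Leading fraction to discard before the FFT.
#' @return Frequency in Hz.
#' @export
dominant_frequency <- function(ts, discard_fraction = 0.5) {
  stopifnot(inherits(ts, "eeg_ts"))
  n <- length(ts$samples)
  x <- ts$samples[(floor(n * discard_fraction) + 1L):n]
  x <- x - mean(x)
  m <- length(x)
  spec <- Mod(fft(x))[2:floor(m / 2)]
  (which.max(spec)) * ts$sampling_rate / m
}
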