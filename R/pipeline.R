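#' Default virtual-reality connectivity overrides
#'
#' The induction scenario is modelled as a strengthening of the
#' excitatory-to-pyramidal coupling (attention engagement of the motor
#' control circuitry): `C12` raised by 20% over its default of 108. The
#' override is applied from the stimulus onset onward (an evoked, not
#' tonic, change), so baseline-referenced features are affected only after
#' induction begins.
#'
#' @return Named list of [nmm_params()] overrides.
#' @export
vr_default_overrides <- function() {
  list(C12 = 108 * 1.2)
}

#' Condition specification
#'
#' Generative configuration of one experimental condition. The `"normal"`
#' condition has no stimulus and no connectivity overrides; the `"vr"`
#' condition superimposes a sinusoidal visual stimulus on the visual input
#' channel from `stim_onset` onward and applies the connectivity overrides
#' from the same moment.
#'
#' @param label `"normal"` or `"vr"`.
#' @param stim_freq Stimulus frequency in Hz (alpha-band default, 10 Hz).
#' @param stim_amplitude Stimulus amplitude in model input units; must be 0
#'   for `"normal"`. Default 0.5 for `"vr"`.
#' @param stim_onset Stimulus onset in seconds relative to movement onset;
#'   default -2 s (the pre-movement intention window).
#' @param connectivity_overrides Named list of [nmm_params()] overrides;
#'   must be empty for `"normal"`. Default [vr_default_overrides()] for
#'   `"vr"`.
#' @param visual_weight,pain_weight Dimensionless salience scales applied
#'   to the unit-RMS primary-processing outputs of the visual and pain
#'   channels.
#' @param input_range Half-width `a` of the uniform background input
#'   `U(-a, a)`. Default 0.5.
#' @return An object of class `condition_spec`.
#' @export
condition_spec <- function(label = c("normal", "vr"),
                           stim_freq = 10,
                           stim_amplitude = if (label == "vr") 0.5 else 0,
                           stim_onset = -2,
                           connectivity_overrides =
                             if (label == "vr") vr_default_overrides()
                             else list(),
                           visual_weight = 1, pain_weight = 1,
                           input_range = 0.5) {
  label <- match.arg(label)
  force(stim_amplitude); force(connectivity_overrides)
  stopifnot(stim_freq > 0, stim_amplitude >= 0,
            visual_weight >= 0, pain_weight >= 0, input_range > 0)
  if (label == "normal") {
    if (stim_amplitude != 0)
      stop("the normal condition must have stim_amplitude = 0")
    if (length(connectivity_overrides) > 0)
      stop("the normal condition must have empty connectivity_overrides")
  }
  structure(list(label = label, stim_freq = stim_freq,
                 stim_amplitude = stim_amplitude, stim_onset = stim_onset,
                 connectivity_overrides = connectivity_overrides,
                 visual_weight = visual_weight, pain_weight = pain_weight,
                 input_range = input_range),
            class = "condition_spec")
}

#' Trial protocol specification
#'
#' Timing and count structure of the recording protocol: each trial is
#' `pre_still` seconds of stillness, up to `movement` seconds of movement,
#' then `rest` seconds of rest; a session holds `trials_per_session`
#' trials. The defaults follow the experimental protocol: 5 sessions of 10
#' trials, 5 s stillness, 4 s movement, 1,000 Hz sampling, and epochs cut
#' from 5 s before to 2 s after movement onset. The 4.5 s rest makes one
#' 10-trial session 135 s long.
#'
#' @param n_sessions Number of sessions, `>= 1`.
#' @param trials_per_session Trials per session, `>= 1`.
#' @param pre_still Stillness before movement onset (s).
#' @param movement Movement duration (s).
#' @param rest Inter-trial rest (s).
#' @param sampling_rate Sampling rate (Hz).
#' @param epoch_window Epoch window `c(start, end)` in seconds around
#'   movement onset; start must be negative, end positive.
#' @return An object of class `protocol_spec`.
#' @export
protocol_spec <- function(n_sessions = 5, trials_per_session = 10,
                          pre_still = 5, movement = 4, rest = 4.5,
                          sampling_rate = 1000,
                          epoch_window = c(-5, 2)) {
  stopifnot(n_sessions >= 1, trials_per_session >= 1,
            pre_still > 0, movement > 0, rest >= 0, sampling_rate > 0,
            length(epoch_window) == 2L,
            epoch_window[1] < 0, epoch_window[2] > 0)
  structure(list(n_sessions = as.integer(n_sessions),
                 trials_per_session = as.integer(trials_per_session),
                 pre_still = pre_still, movement = movement, rest = rest,
                 sampling_rate = sampling_rate,
                 epoch_window = epoch_window),
            class = "protocol_spec")
}

# internal: deterministic per-trial seed below 2^31
trial_seed <- function(seed, trial_index) {
  (as.numeric(seed) * 10007 + as.numeric(trial_index) * 7919) %% 2147483647
}

#' Build the external inputs for one trial
#'
#' Draws the three external drives of one trial, reproducibly from
#' `(seed, trial_index)`:
#' * `u_ev` — uniformly distributed background on `[-a, a]` feeding the
#'   visual channel, plus the condition's sinusoid
#'   `stim_amplitude * sin(2*pi*stim_freq*(t - stim_onset))` from
#'   `stim_onset` onward when the label is `"vr"`;
#' * `u_ip` — independent uniform background for the pain channel, scaled
#'   by `pain_weight`;
#' * `u4` — white Gaussian noise with mean 0 and variance 5 driving the
#'   fast-inhibitory auxiliary branch.
#'
#' The series cover the burn-in period as well as the trial proper, with
#' `t0 = -(burn_in + pre_still)` so that `t = 0` is movement onset.
#'
#' @param cond A [condition_spec()].
#' @param proto A [protocol_spec()].
#' @param trial_index Trial number within the ensemble (1-based).
#' @param seed Master seed (integer).
#' @param burn_in Extra leading seconds later discarded by
#'   [simulate_trial()]. Default 2.
#' @param u4_variance Variance of the Gaussian drive. Default 5.
#' @return List with [time_series()] elements `u_ev`, `u_ip`, `u4`.
#' @export
build_inputs <- function(cond, proto, trial_index = 1, seed = 1,
                         burn_in = 2, u4_variance = 5) {
  stopifnot(inherits(cond, "condition_spec"),
            inherits(proto, "protocol_spec"))
  fs <- proto$sampling_rate
  t0 <- -(burn_in + proto$pre_still)
  dur <- burn_in + proto$pre_still + proto$movement + proto$rest
  n <- as.integer(round(dur * fs))
  t <- t0 + (seq_len(n) - 1) / fs

  set.seed(trial_seed(seed, trial_index))
  a <- cond$input_range
  ev <- runif(n, -a, a)
  if (cond$label == "vr" && cond$stim_amplitude > 0) {
    on <- t >= cond$stim_onset
    ev[on] <- ev[on] + cond$stim_amplitude *
      sin(2 * pi * cond$stim_freq * (t[on] - cond$stim_onset))
  }
  ip <- runif(n, -a, a) * cond$pain_weight
  g <- rnorm(n, mean = 0, sd = sqrt(u4_variance))
  list(u_ev = time_series(ev, fs, t0),
       u_ip = time_series(ip, fs, t0),
       u4 = time_series(g, fs, t0))
}

#' Combine the primary-processing outputs
#'
#' The pyramidal input is the difference of the processed visual (promote)
#' and pain (prevent) channels: `u1(t) = u_ev(t) - u_ip(t)`, elementwise.
#'
#' @param u_ev,u_ip [time_series()] of equal length and rate.
#' @return A [time_series()] `u1`.
#' @export
combine_primary <- function(u_ev, u_ip) {
  check_aligned(u_ev, u_ip, "primary outputs")
  time_series(u_ev$samples - u_ip$samples, u_ev$sampling_rate, u_ev$t0)
}

#' Simulate one movement-intention trial
#'
#' Runs the full generative cascade for one trial: external inputs are
#' built, each sensory channel is passed through its own van der Pol
#' primary-processing oscillator (forced by the channel input, with a
#' random initial phase drawn from the trial seed), each oscillator output
#' is normalised to unit RMS and scaled by the channel's salience weight,
#' the two channels are combined into the pyramidal drive, and the neural
#' mass model is integrated. For the `"vr"` condition the connectivity
#' overrides take effect at the stimulus onset. The leading burn-in is
#' discarded and the returned simulated EEG `v1(t)` is aligned so that
#' `t = 0` is movement onset.
#'
#' @inheritParams build_inputs
#' @param osc An [oscillator_params()] object for the primary-processing
#'   oscillators (default: `lam = 1`, 10 Hz).
#' @param nmm Base [nmm_params()]; default [default_params()]`("normal")`.
#' @return A [time_series()] of the simulated EEG, `t0 = -pre_still`.
#' @export
simulate_trial <- function(cond, proto, trial_index = 1, seed = 1,
                           burn_in = 2,
                           osc = oscillator_params(lam = 1, p = 2 * pi * 10),
                           nmm = default_params("normal")) {
  stopifnot(inherits(cond, "condition_spec"),
            inherits(proto, "protocol_spec"))
  inputs <- build_inputs(cond, proto, trial_index, seed, burn_in)
  fs <- proto$sampling_rate
  dur <- length(inputs$u_ev$samples) / fs

  # random initial phases for the two assemblies, drawn after the inputs
  # from the same trial stream
  amp0 <- 2 * sqrt(max(osc$lam, 0.01))
  ph <- runif(2, 0, 2 * pi)
  init_ev <- c(amp0 * cos(ph[1]), -amp0 * osc$p * sin(ph[1]))
  init_ip <- c(amp0 * cos(ph[2]), -amp0 * osc$p * sin(ph[2]))

  y_ev <- simulate_oscillator(osc, dur, dt = 1 / fs, init = init_ev,
                              forcing = inputs$u_ev)
  y_ip <- simulate_oscillator(osc, dur, dt = 1 / fs, init = init_ip,
                              forcing = inputs$u_ip)

  unit_rms <- function(x) {
    s <- sqrt(mean(x^2))
    if (s == 0) x else x / s
  }
  u_ev <- time_series(unit_rms(y_ev$samples) * cond$visual_weight,
                      fs, y_ev$t0)
  u_ip <- time_series(unit_rms(y_ip$samples) * cond$pain_weight,
                      fs, y_ip$t0)
  u1 <- combine_primary(u_ev, u_ip)

  if (length(cond$connectivity_overrides) > 0) {
    post <- do.call(nmm_params,
                    modifyList(unclass(nmm),
                               as.list(cond$connectivity_overrides)))
    v1 <- simulate_nmm(nmm, u1, inputs$u4, params_post = post,
                       switch_time = cond$stim_onset)
  } else {
    v1 <- simulate_nmm(nmm, u1, inputs$u4)
  }
  keep <- ts_times(v1) >= -proto$pre_still - 1e-9
  time_series(v1$samples[keep], fs, t0 = -proto$pre_still)
}

#' Generate a full trial ensemble for one condition
#'
#' Simulates `n_sessions * trials_per_session` trials with per-trial seeds
#' derived deterministically from the master seed, so the ensemble is a
#' pure function of `(cond, proto, seed)`.
#'
#' @inheritParams simulate_trial
#' @return An object of class `trial_ensemble`: list with `trials` (list of
#'   [time_series()]), `condition`, `protocol`, `seed`.
#' @export
generate_dataset <- function(cond, proto, seed = 1, burn_in = 2,
                             osc = oscillator_params(lam = 1, p = 2 * pi * 10),
                             nmm = default_params("normal")) {
  stopifnot(inherits(cond, "condition_spec"),
            inherits(proto, "protocol_spec"))
  n_trials <- proto$n_sessions * proto$trials_per_session
  trials <- lapply(seq_len(n_trials), function(i)
    simulate_trial(cond, proto, trial_index = i, seed = seed,
                   burn_in = burn_in, osc = osc, nmm = nmm))
  structure(list(trials = trials, condition = cond, protocol = proto,
                 seed = seed),
            class = "trial_ensemble")
}

#' @export
print.trial_ensemble <- function(x, ...) {
  cat(sprintf("<trial_ensemble> %d trials, condition '%s', seed %s\n",
              length(x$trials), x$condition$label, format(x$seed)))
  invisible(x)
}
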