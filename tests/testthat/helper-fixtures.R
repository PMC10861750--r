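# Fixtures built in code at test time.

fs_default <- 1000

# a sine wave carried as eeg_ts
sine_ts <- function(freq, dur = 1, amp = 1, fs = fs_default, t0 = 0,
                    phase = 0) {
  tt <- t0 + (0:(round(dur * fs) - 1)) / fs
  time_series(amp * sin(2 * pi * freq * (tt - t0) + phase), fs, t0)
}

# single-trial epochs over [-5, 2) holding a 10 Hz tone whose amplitude
# switches from 1 to `resid` at time t_drop
tone_drop_epochs <- function(t_drop, resid = 0.01, freq = 10,
                             fs = fs_default) {
  tt <- seq(-5, 2 - 1 / fs, by = 1 / fs)
  amp <- ifelse(tt >= t_drop, resid, 1)
  epoch_signal(time_series(amp * sin(2 * pi * freq * (tt + 5)), fs, t0 = -5))
}

# noisy trials with a planted negative Gaussian bump
bump_trials <- function(n_trials = 20, centre = -0.1, depth = -5,
                        width = 0.3, noise_sd = 1, fs = fs_default,
                        seed = 7) {
  set.seed(seed)
  tt <- seq(-5, 2 - 1 / fs, by = 1 / fs)
  lapply(seq_len(n_trials), function(i) {
    bump <- depth * exp(-((tt - centre)^2) / (2 * width^2))
    time_series(bump + rnorm(length(tt), 0, noise_sd), fs, -5)
  })
}

# small protocol for fast pipeline tests
small_protocol <- function(n_trials = 3) {
  protocol_spec(n_sessions = 1, trials_per_session = n_trials)
}

# hand-built time-frequency map
manual_tf_map <- function(values, times, freqs, baseline_end = -2) {
  structure(list(times = times, freqs = freqs, values = values,
                 baseline_window = c(-5, baseline_end)),
            class = "tf_map")
}
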