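test_that("band-pass keeps the passband and rejects the stopband", {
  s10 <- sine_ts(10, dur = 7)
  f <- bandpass_butterworth(s10, 8, 30)
  core <- f$samples[2000:5000]  # trim filter edges
  expect_equal(max(abs(core)), 1, tolerance = 0.05)

  s2 <- sine_ts(2, dur = 7)
  f2 <- bandpass_butterworth(s2, 8, 30)
  expect_lt(max(abs(f2$samples[2000:5000])), 0.1)

  # low-frequency band used for slow cortical potentials
  s5 <- sine_ts(5, dur = 7)
  f5 <- bandpass_butterworth(s5, 0.1, 10)
  expect_equal(max(abs(f5$samples[2000:5000])), 1, tolerance = 0.05)

  expect_error(bandpass_butterworth(s10, 30, 8), "invalid band")
  expect_error(bandpass_butterworth(s10, 8, 600), "invalid band")
})

test_that("epoching produces half-open windows of the exact sample count", {
  fs <- 1000
  rec <- time_series(rnorm(12 * fs), fs, t0 = -6)
  e1 <- epoch_signal(rec, window = c(-1, 1), baseline_window = c(-1, -0.5))
  expect_equal(ncol(e1$data), 2000)
  e2 <- epoch_signal(rec, window = c(-5, 2))
  expect_equal(ncol(e2$data), 7000)
  expect_equal(e2$times[1], -5)
  # t = 0 column holds the onset sample
  i0 <- which(e2$times == 0)
  expect_equal(e2$data[1, i0], rec$samples[floor((0 - rec$t0) * fs) + 1])
  # onset too close to the recording edge
  expect_error(epoch_signal(time_series(rnorm(100), fs, t0 = -0.05),
                            window = c(-1, 1),
                            baseline_window = c(-1, -0.5)),
               "trial 1")
})

test_that("desynchronization percentage follows the power-ratio identities", {
  expect_equal(erd_percent(1, 1), 0)
  expect_equal(erd_percent(0.5, 1), -50)
  expect_equal(erd_percent(2, 1), 100)
  expect_error(erd_percent(1, 0), "baseline")

  # brute-force oracle on random epochs: loop over samples and epochs
  set.seed(21)
  for (rep in 1:5) {
    n <- sample(5:40, 1); m <- sample(2:6, 1)
    epoch <- rnorm(n)
    baseline <- matrix(rnorm(n * m), nrow = m)
    e <- 0
    for (k in seq_len(n)) e <- e + epoch[k]^2
    e <- e / n
    eb <- 0
    for (j in seq_len(m)) {
      ej <- 0
      for (k in seq_len(n)) ej <- ej + baseline[j, k]^2
      eb <- eb + ej / n
    }
    eb <- eb / m
    oracle <- (e - eb) / eb * 100
    expect_equal(erd_percent(epoch_power(epoch),
                             apply(baseline, 1, epoch_power)),
                 oracle)
  }
})

test_that("spectral perturbation map self-baselines, scales and calibrates", {
  fs <- 1000
  set.seed(31)
  noise_trials <- lapply(1:50, function(i)
    time_series(rnorm(7 * fs), fs, t0 = -5))
  ep <- epoch_signal(noise_trials)
  tf <- stft_ersp(ep)
  base_cols <- tf$times - 0.5 >= -5 - 1e-9 & tf$times + 0.5 <= -2 + 1e-9
  expect_lt(abs(mean(tf$values[, base_cols])), 0.5)

  # amplitude scale invariance: dB map unchanged under a global gain
  scaled <- lapply(noise_trials, function(tr)
    time_series(tr$samples * 10, fs, tr$t0))
  tf2 <- stft_ersp(epoch_signal(scaled))
  expect_equal(tf2$values, tf$values, tolerance = 1e-8)

  # half-amplitude tone drop: -6.02 dB at the tone frequency after onset
  tt <- seq(-5, 2 - 1 / fs, by = 1 / fs)
  amp <- ifelse(tt >= 0, 0.5, 1)
  tf3 <- stft_ersp(epoch_signal(
    time_series(amp * sin(2 * pi * 10 * (tt + 5)), fs, -5)))
  i10 <- which(tf3$freqs == 10)
  post <- tf3$times > 0.6
  expect_lt(abs(mean(tf3$values[i10, post]) - 10 * log10(0.25)), 1)
})

test_that("onset detection finds the threshold crossing or reports missing", {
  times <- seq(-2, 2, by = 0.5)
  freqs <- 8:12
  flat <- manual_tf_map(matrix(0, 5, 9), times, freqs)
  expect_true(is.na(erd_onset(flat)))
  expect_equal(erd_peak(flat), 0)

  one <- flat
  one$values[freqs == 10, times == -1.5] <- -25
  expect_equal(erd_onset(one), -1.5)
  expect_equal(erd_peak(one), -25)

  # planted 99 % amplitude suppression from -1.5 s: onset within one hop,
  # peak at 20*log10(residual)
  ep <- tone_drop_epochs(-1.5, resid = 0.01)
  tf <- stft_ersp(ep, window_sec = 0.2, hop_sec = 0.1)
  expect_lt(abs(erd_onset(tf) - (-1.5)), 0.1 + 1e-9)
  expect_lt(abs(erd_peak(tf) - 20 * log10(0.01)), 1)
})

test_that("deepening the suppression never delays the detected onset", {
  onsets <- sapply(c(0.05, 0.02, 0.01, 0.002), function(res) {
    tf <- stft_ersp(tone_drop_epochs(-1.5, resid = res),
                    window_sec = 0.2, hop_sec = 0.1)
    erd_onset(tf)
  })
  expect_true(all(diff(onsets) <= 1e-9))
})

test_that("the power curve localises the suppressed frequency", {
  times <- seq(-3, 2, by = 0.5)
  const <- manual_tf_map(matrix(-3, 4, length(times)), times, 8:11)
  cv <- frequency_power_curve(const)
  expect_equal(cv$power_db, rep(-3, 4))

  tf <- stft_ersp(tone_drop_epochs(-1.5), window_sec = 1, hop_sec = 0.05)
  cv2 <- frequency_power_curve(tf)
  expect_equal(cv2$freqs[which.min(cv2$power_db)], 10)
})

test_that("characteristic frequency is the in-band argmin with low-tie rule", {
  curve <- list(freqs = 8:25, power_db = rep(0, 18))
  curve$power_db[curve$freqs == 11] <- -4
  curve$power_db[curve$freqs == 19] <- -6
  expect_equal(characteristic_frequency(curve, c(8, 13))$freq, 11)
  expect_equal(characteristic_frequency(curve, c(14, 25))$freq, 19)
  # monotone curve: argmin at the band edge
  mono <- list(freqs = 8:25, power_db = seq(-1, -18))
  expect_equal(characteristic_frequency(mono, c(8, 13))$freq, 13)
  # ties break to the lowest frequency
  expect_equal(characteristic_frequency(
    list(freqs = 8:13, power_db = rep(-2, 6)), c(8, 13))$freq, 8)
  expect_error(characteristic_frequency(curve, c(30, 40)), "band")
  # in-band guarantee on a real map
  tf <- stft_ersp(tone_drop_epochs(-1.5))
  cf <- characteristic_frequency(frequency_power_curve(tf), c(8, 13))
  expect_true(cf$freq >= 8 && cf$freq <= 13)
})

test_that("slow-potential extraction recovers planted deflections linearly", {
  fs <- 1000
  zeros <- lapply(1:3, function(i)
    time_series(rep(0, 7 * fs), fs, -5))
  mz <- mrcp_extract(epoch_signal(zeros))
  expect_equal(mz$peak, 0)
  expect_equal(mz$peak_time, -3)  # documented tie rule: first window sample

  ep <- epoch_signal(bump_trials(centre = -0.1, depth = -5))
  mr <- mrcp_extract(ep)
  expect_lt(abs(mr$peak_time - (-0.1)), 0.05)
  expect_lt(mr$peak, -3)

  # linearity under ensemble scaling
  scaled <- epoch_signal(lapply(bump_trials(centre = -0.1, depth = -5),
                                function(tr)
                                  time_series(3 * tr$samples, fs, tr$t0)))
  ms <- mrcp_extract(scaled)
  expect_equal(ms$peak, 3 * mr$peak, tolerance = 1e-4)
  expect_equal(ms$peak_time, mr$peak_time)
})

test_that("resting-state band power matches closed forms", {
  fs <- 1000
  zero_ep <- epoch_signal(time_series(rep(0, 7 * fs), fs, -5))
  expect_equal(baseline_power(zero_ep), 0)

  tone <- sine_ts(10, dur = 7, fs = fs, t0 = -5)
  ep <- epoch_signal(tone)
  expect_equal(baseline_power(ep), 0.5, tolerance = 0.05)
  ep2 <- epoch_signal(time_series(2 * tone$samples, fs, -5))
  expect_equal(baseline_power(ep2), 4 * baseline_power(ep),
               tolerance = 1e-10)
})

test_that("the feature table reports every per-dataset feature", {
  ft <- feature_table(tone_drop_epochs(-1.5))
  expect_named(ft, c("erd_onset_time", "erd_peak", "char_freq_alpha",
                     "char_freq_beta", "alpha_peak_power",
                     "beta_peak_power", "mrcp_peak", "mrcp_peak_time",
                     "baseline_power"))
  expect_true(ft$char_freq_alpha >= 8 && ft$char_freq_alpha <= 13)
  expect_true(ft$char_freq_beta >= 14 && ft$char_freq_beta <= 25)
  expect_lt(ft$erd_peak, -20)
})
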