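test_that("derivative field evaluates the oscillator equation exactly", {
  # origin is an equilibrium of the unforced system
  expect_equal(vdp_derivatives(c(0, 0), oscillator_params(lam = 1, p = 2 * pi)),
               c(0, 0))
  # only the p^2 Y restoring term acts at (1, 0)
  expect_equal(vdp_derivatives(c(1, 0), oscillator_params(lam = 1, p = 1)),
               c(0, -1))
  # hand evaluation: (0.8 - 0.25) * 0.2 - 4 * 0.5 = -1.89
  expect_equal(vdp_derivatives(c(0.5, 0.2), oscillator_params(lam = 0.8, p = 2)),
               c(0.2, -1.89))
  # additive forcing scaled by the gain
  expect_equal(
    vdp_derivatives(c(0, 0), oscillator_params(lam = 1, p = 1,
                                               forcing_gain = 2), 3),
    c(0, 6))
  expect_error(vdp_derivatives(c(NaN, 0), oscillator_params()), "finite")
})

test_that("subcritical trajectories decay and supercritical ones reach 2*sqrt(lambda)", {
  # lam <= 0: no oscillation; envelope decays like exp(lam * t / 2),
  # so 20 s at lam = -0.5 brings a unit start below 0.01
  dead <- simulate_oscillator(oscillator_params(lam = -0.5, p = 2 * pi * 10),
                              duration = 20, init = c(1, 0))
  expect_lt(measure_amplitude(dead, discard_fraction = 0.9), 0.01)

  # amplitude law 2*sqrt(lambda) within 5 %, frequency within one FFT bin;
  # start near the cycle so the lam/2 convergence rate has settled in time
  for (lam in c(0.25, 0.5, 1)) {
    ts <- simulate_oscillator(oscillator_params(lam = lam, p = 2 * pi * 10),
                              duration = 20, init = c(1, 0))
    expect_equal(measure_amplitude(ts), 2 * sqrt(lam),
                 tolerance = 0.05)
    bin <- 1 / (0.5 * 20)  # FFT resolution of the retained tail
    expect_lt(abs(dominant_frequency(ts) - 10), bin + 1e-9)
  }
})

test_that("trajectories stay bounded for moderate lambda and bounded forcing", {
  f <- sine_ts(10, dur = 10)
  for (lam in c(0.5, 1, 2)) {
    ts <- simulate_oscillator(oscillator_params(lam = lam, p = 2 * pi * 10),
                              duration = 10, forcing = f)
    expect_true(all(is.finite(ts$samples)))
    expect_lt(max(abs(ts$samples)), 10)
  }
})

test_that("RK4 trajectory matches an adaptive independent integrator", {
  skip_if_not_installed("deSolve")
  p <- oscillator_params(lam = 1, p = 2 * pi * 10)
  mine <- simulate_oscillator(p, 2, init = c(0.1, 0))
  rhs <- function(t, y, parms)
    list(c(y[2], (p$lam - y[1]^2) * y[2] - p$p^2 * y[1]))
  ref <- deSolve::ode(c(0.1, 0), seq(0, 2, by = 1e-3), rhs, NULL,
                      method = "lsoda", rtol = 1e-10, atol = 1e-12)
  rel_rms <- sqrt(mean((mine$samples - ref[seq_len(2000), 2])^2)) /
    sd(ref[seq_len(2000), 2])
  expect_lt(rel_rms, 1e-3)
})

test_that("simulation guards reject invalid steps and blow-ups", {
  expect_error(simulate_oscillator(oscillator_params(p = 2 * pi * 100),
                                   duration = 1, dt = 1e-2),
               "steps per oscillator period")
  expect_error(simulate_oscillator(oscillator_params(lam = 1, p = 2 * pi),
                                   duration = 1, dt = 1e-3,
                                   init = c(1, 0), bound = 0.5),
               "magnitude bound")
})

test_that("amplitude measurement is exact on known signals", {
  expect_equal(measure_amplitude(time_series(rep(0, 100), 100)), 0)
  s <- sine_ts(10, dur = 2, amp = 2)
  expect_equal(measure_amplitude(s), 2, tolerance = 1e-3)
  expect_error(measure_amplitude(time_series(1:2, 10), 0.99), "empty")
})

test_that("phase-locking index is 1 for identical sines and small for noise", {
  s <- sine_ts(10, dur = 1)
  expect_equal(phase_sync_index(s, s), 1, tolerance = 1e-6)
  set.seed(42)
  a <- time_series(rnorm(1e4), 1000)
  b <- time_series(rnorm(1e4), 1000)
  expect_lt(phase_sync_index(a, b), 0.1)
  expect_error(phase_sync_index(s, time_series(1:5, 1000)), "mismatch")
})

test_that("same-frequency forcing entrains the oscillator from any initial phase", {
  # 20 periods at 1 Hz; tail phase difference must converge to the same
  # forced equilibrium from every initial offset, unlike the unforced case
  fs <- 200; dur <- 20
  tail_phase <- function(gain, ph0) {
    f <- sine_ts(1, dur = dur, fs = fs)
    y <- simulate_oscillator(
      oscillator_params(lam = 1, p = 2 * pi, forcing_gain = gain),
      dur, dt = 1 / fs,
      init = c(2 * cos(ph0), -2 * 2 * pi * sin(ph0)), forcing = f)
    ph1 <- Arg(mieeg:::analytic_signal(y$samples - mean(y$samples)))
    ph2 <- Arg(mieeg:::analytic_signal(f$samples - mean(f$samples)))
    idx <- (0.8 * dur * fs):(dur * fs)
    c(diff = Arg(mean(exp(1i * (ph1[idx] - ph2[idx])))),
      plv = phase_sync_index(y, f, tail_fraction = 0.2))
  }
  offsets <- c(0, pi / 2, pi, 4.5)
  forced <- sapply(offsets, function(p0) tail_phase(10, p0))
  free <- sapply(offsets, function(p0) tail_phase(0, p0))
  expect_true(all(forced["plv", ] > 0.9))
  expect_lt(diff(range(forced["diff", ])), 0.3)   # converged phases
  expect_gt(diff(range(free["diff", ])), 2)       # memory of initial phase
})
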