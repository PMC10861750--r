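test_that("firing-rate sigmoid is centred, saturating, odd and rescalable", {
  expect_identical(nmm_sigmoid(0), 0)
  expect_equal(nmm_sigmoid(1e6), 2.5)
  expect_equal(nmm_sigmoid(-1e6), -2.5)
  # direct high-precision evaluation at v = 1
  expect_equal(nmm_sigmoid(1), 2 * 2.5 / (1 + exp(-0.56)) - 2.5,
               tolerance = 1e-12)
  expect_equal(round(nmm_sigmoid(1), 4), 0.6823)
  v <- seq(-20, 20, by = 0.25)
  expect_equal(nmm_sigmoid(-v), -nmm_sigmoid(v))          # odd
  expect_true(all(diff(nmm_sigmoid(v)) > 0))              # increasing
  # doubling r halves the potential needed for a given rate
  expect_equal(nmm_sigmoid(v, r = 0.56), nmm_sigmoid(2 * v, r = 0.28))
})

test_that("derivative field matches hand evaluation of the population equations", {
  p <- nmm_params()
  zero <- rep(0, 10)
  expect_equal(unname(nmm_derivatives(zero, p, 0, 0)), rep(0, 10))

  # u4 drives only the primed self-loop branch, with excitatory kinetics
  d <- nmm_derivatives(zero, p, u1 = 0, u4 = 1)
  expect_equal(unname(d[10]), p$G2 * p$w2)
  expect_equal(unname(d[-10]), rep(0, 9))

  # with y1 = 1 the membrane potentials are the outgoing connectivities
  s <- zero; s[1] <- 1
  d <- nmm_derivatives(s, p, 0, 0)
  expect_equal(unname(d[4]), p$G2 * p$w2 * nmm_sigmoid(p$C21))
  expect_equal(unname(d[6]),
               p$G3 * p$w3 * nmm_sigmoid(p$C31) - p$w3^2 * 0)
  expect_equal(unname(d[8]), p$G4 * p$w4 * nmm_sigmoid(p$C41))
  expect_equal(unname(d[2]), -p$w2^2 * 1)  # v1 = 0, damping only

  expect_error(nmm_derivatives(zero, nmm_params(C12 = 0), u1 = 1), "C12")
})

test_that("the all-zero state with zero input is an exact fixed point", {
  n <- 1e5
  u0 <- time_series(rep(0, n), 1000)
  v1 <- simulate_nmm(nmm_params(), u0, u0, keep_states = TRUE)
  expect_identical(max(abs(v1$samples)), 0)
  expect_identical(max(abs(attr(v1, "states"))), 0)
})

test_that("each second-order branch reproduces the analytic impulse response", {
  # an impulse is an instantaneous jump of the rate variable to G*w;
  # with all couplings zeroed every branch is an isolated critically
  # damped linear filter with response G * w * t * exp(-w * t)
  p0 <- nmm_params(C12 = 0, C21 = 0, C13 = 0, C31 = 0,
                   C14 = 0, C41 = 0, C43 = 0, C44 = 0)
  branches <- list(y1 = list(x = 2, y = 1, G = p0$G2, w = p0$w2),
                   y2 = list(x = 4, y = 3, G = p0$G2, w = p0$w2),
                   y3 = list(x = 6, y = 5, G = p0$G3, w = p0$w3),
                   y4 = list(x = 8, y = 7, G = p0$G4, w = p0$w4),
                   y4p = list(x = 10, y = 9, G = p0$G2, w = p0$w2))
  fs <- 1000
  for (br in branches) {
    dur <- 8 / br$w
    n <- max(50, round(dur * fs))
    u0 <- time_series(rep(0, n), fs)
    init <- rep(0, 10); init[br$x] <- br$G * br$w
    out <- simulate_nmm(p0, u0, u0, init = init, keep_states = TRUE)
    y <- attr(out, "states")[, br$y]
    tt <- (seq_len(n) - 1) / fs
    h <- br$G * br$w * tt * exp(-br$w * tt)
    expect_lt(sqrt(mean((y - h)^2)) / sqrt(mean(h^2)), 0.01)
  }
})

test_that("autonomous trajectory matches an adaptive independent integrator", {
  skip_if_not_installed("deSolve")
  prm <- nmm_params()
  init <- c(0.05, 0, 0.02, 0, 0, 0, 0, 0, 0, 0)
  n <- 1000
  u0 <- time_series(rep(0, n), 1000)
  mine <- simulate_nmm(prm, u0, u0, init = init)
  rhs <- function(t, s, q) list(unname(nmm_derivatives(s, prm, 0, 0)))
  ref <- deSolve::ode(init, seq(0, (n - 1) / 1000, by = 1e-3), rhs, NULL,
                      method = "lsoda", rtol = 1e-10, atol = 1e-12)
  v1_ref <- prm$C12 * ref[, 4] - prm$C13 * ref[, 6] - prm$C14 * ref[, 8]
  expect_lt(sqrt(mean((mine$samples - v1_ref)^2)) / sd(v1_ref), 1e-3)
})

test_that("default-input simulation stays bounded over a long run", {
  set.seed(3)
  n <- 60 * 1000
  u1 <- time_series(runif(n, -0.5, 0.5), 1000)
  u4 <- time_series(rnorm(n, 0, sqrt(5)), 1000)
  v1 <- simulate_nmm(nmm_params(), u1, u4)   # errors if the guard trips
  expect_true(all(is.finite(v1$samples)))
  expect_gt(sd(v1$samples), 0)               # nonconstant, irregular output
})

test_that("condition parameter sets differ in exactly the override set", {
  a <- default_params("normal")
  b <- default_params("vr")
  expect_equal(a$e0, 2.5)
  expect_equal(a$r, 0.56)
  ov <- vr_default_overrides()
  for (k in names(unclass(a))) {
    if (k %in% names(ov)) expect_equal(b[[k]], ov[[k]])
    else expect_identical(b[[k]], a[[k]])
  }
  expect_error(default_params("vr", overrides = list(bogus = 1)), "unknown")
})

test_that("step-size guard rejects too-large dt for the fastest synapse", {
  u <- time_series(rep(0, 10), 500)  # dt = 2 ms, w4 = 500 -> dt*w = 1
  expect_error(simulate_nmm(nmm_params(), u, u), "step too large")
})
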