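#' Neural mass model parameters
#'
#' Constants of the four-population neural mass model (pyramidal cells,
#' excitatory interneurons, slow inhibitory interneurons and fast inhibitory
#' interneurons with a self-inhibition loop and an auxiliary excitatory
#' input branch). `Cij` is the synaptic connectivity constant from
#' population `j` to population `i` (dimensionless), `G` the synaptic gain
#' in mV and `w` the reciprocal synaptic time constant in 1/s. `e0` (1/s)
#' and `r` (1/mV) parameterise the zero-centred firing-rate sigmoid.
#'
#' Defaults are the Wendling-family constants for this model class:
#' excitatory kinetics `G2 = 3.25` mV, `w2 = 100` 1/s; slow inhibitory
#' `G3 = 22` mV, `w3 = 50` 1/s; fast inhibitory `G4 = 10` mV,
#' `w4 = 500` 1/s; connectivity `C21 = 135`, `C12 = 108`,
#' `C31 = C13 = 33.75`, `C41 = 40.5`, `C14 = C43 = C44 = 13.5`; sigmoid
#' `e0 = 2.5` 1/s, `r = 0.56` 1/mV.
#'
#' @param C12,C21,C13,C31,C14,C41,C43,C44 Connectivity constants, `>= 0`.
#' @param G2,G3,G4 Synaptic gains (mV).
#' @param w2,w3,w4 Reciprocal time constants (1/s), `> 0`.
#' @param e0 Sigmoid saturation (1/s), `> 0`.
#' @param r Sigmoid steepness (1/mV), `> 0`.
#' @return An object of class `nmm_params`.
#' @export
nmm_params <- function(C12 = 108, C21 = 135, C13 = 33.75, C31 = 33.75,
                       C14 = 13.5, C41 = 40.5, C43 = 13.5, C44 = 13.5,
                       G2 = 3.25, G3 = 22, G4 = 10,
                       w2 = 100, w3 = 50, w4 = 500,
                       e0 = 2.5, r = 0.56) {
  p <- list(C12 = C12, C21 = C21, C13 = C13, C31 = C31,
            C14 = C14, C41 = C41, C43 = C43, C44 = C44,
            G2 = G2, G3 = G3, G4 = G4, w2 = w2, w3 = w3, w4 = w4,
            e0 = e0, r = r)
  if (!all(vapply(p, function(v) is.numeric(v) && length(v) == 1L &&
                    is.finite(v), logical(1))))
    stop("all neural mass parameters must be single finite numbers")
  if (any(unlist(p[c("w2", "w3", "w4", "e0", "r")]) <= 0))
    stop("w2, w3, w4, e0 and r must be > 0")
  if (any(unlist(p[grep("^C", names(p))]) < 0))
    stop("connectivity constants must be >= 0")
  structure(p, class = "nmm_params")
}

# internal: fixed-order parameter vector matching the C++ layout
nmm_param_vector <- function(p) {
  unlist(p[c("C12", "C21", "C13", "C31", "C14", "C41", "C43", "C44",
             "G2", "G3", "G4", "w2", "w3", "w4", "e0", "r")],
         use.names = FALSE)
}

nmm_state_names <- c("y1", "x1", "y2", "x2", "y3", "x3",
                     "y4", "x4", "y4p", "x4p")

#' Population firing-rate sigmoid
#'
#' Converts an average membrane potential into a firing-rate-like quantity:
#' `z(v) = 2 * e0 / (1 + exp(-r * v)) - e0`. The function is centred on 0
#' (so `z(0) = 0`), strictly increasing, odd, and saturates at `+/- e0`.
#' Negative values are meaningful in this formulation and are not clipped.
#'
#' @param v Membrane potential (mV); vectorised.
#' @param e0 Saturation (1/s). Default 2.5.
#' @param r Steepness (1/mV). Default 0.56.
#' @return Firing-rate-like value(s) in `(-e0, e0)`.
#' @examples
#' nmm_sigmoid(0)        # 0
#' nmm_sigmoid(1e6)      # 2.5
#' @export
nmm_sigmoid <- function(v, e0 = 2.5, r = 0.56) {
  stopifnot(is.numeric(v), e0 > 0, r > 0)
  2 * e0 / (1 + exp(-r * v)) - e0
}

#' Neural mass model derivative field
#'
#' Exact evaluation of the ten coupled first-order equations. The state is
#' ordered `(y1, x1, y2, x2, y3, x3, y4, x4, y4p, x4p)` where `y` are
#' postsynaptic potentials, `x` their derivatives, and the primed pair is
#' the auxiliary branch of the fast-inhibitory population driven by the
#' external input `u4`. Membrane potentials are
#' `v1 = C12*y2 - C13*y3 - C14*y4`, `v2 = C21*y1`, `v3 = C31*y1`,
#' `v4 = C41*y1 - C43*y3 - C44*y4 + y4p`. The external drive to the
#' excitatory interneurons enters as `z2 + u1 / C12`, and the primed branch
#' is driven by `u4` with excitatory kinetics `G2 * w2` — both as the model
#' equations state them.
#'
#' @param state Numeric vector of length 10 (order above).
#' @param params An [nmm_params()] object.
#' @param u1 External input to the excitatory-interneuron pathway.
#' @param u4 External input to the fast-inhibitory auxiliary branch.
#' @return Named numeric vector of length 10: the state derivative.
#' @export
nmm_derivatives <- function(state, params, u1 = 0, u4 = 0) {
  stopifnot(inherits(params, "nmm_params"))
  if (length(state) != 10L || !all(is.finite(state)))
    stop("`state` must be 10 finite numbers")
  if (!is.finite(u1) || !is.finite(u4)) stop("inputs must be finite")
  if (params$C12 == 0 && u1 != 0)
    stop("C12 = 0 with nonzero u1: the excitatory drive divides u1 by C12")
  p <- params
  y1 <- state[[1]]; x1 <- state[[2]]; y2 <- state[[3]]; x2 <- state[[4]]
  y3 <- state[[5]]; x3 <- state[[6]]; y4 <- state[[7]]; x4 <- state[[8]]
  y4p <- state[[9]]; x4p <- state[[10]]

  v1 <- p$C12 * y2 - p$C13 * y3 - p$C14 * y4
  v2 <- p$C21 * y1
  v3 <- p$C31 * y1
  v4 <- p$C41 * y1 - p$C43 * y3 - p$C44 * y4 + y4p

  z1 <- nmm_sigmoid(v1, p$e0, p$r)
  z2 <- nmm_sigmoid(v2, p$e0, p$r)
  z3 <- nmm_sigmoid(v3, p$e0, p$r)
  z4 <- nmm_sigmoid(v4, p$e0, p$r)

  u1c <- if (p$C12 == 0) 0 else u1 / p$C12
  d <- c(x1, p$G2 * p$w2 * z1 - 2 * p$w2 * x1 - p$w2^2 * y1,
         x2, p$G2 * p$w2 * (z2 + u1c) - 2 * p$w2 * x2 - p$w2^2 * y2,
         x3, p$G3 * p$w3 * z3 - 2 * p$w3 * x3 - p$w3^2 * y3,
         x4, p$G4 * p$w4 * z4 - 2 * p$w4 * x4 - p$w4^2 * y4,
         x4p, p$G2 * p$w2 * u4 - 2 * p$w2 * x4p - p$w2^2 * y4p)
  names(d) <- nmm_state_names
  d
}

#' Simulate the neural mass model
#'
#' Fixed-step RK4 integration of the ten-state model driven by the external
#' inputs `u1` (pyramidal/excitatory pathway) and `u4` (fast-inhibitory
#' auxiliary branch), both sampled by zero-order hold. The simulated EEG is
#' the pyramidal membrane potential `v1(t)`, returned at the input sampling
#' rate.
#'
#' An evoked connectivity change can be modelled by supplying
#' `params_post` and `switch_time`: integration uses `params` before the
#' switch and `params_post` from the switch onward.
#'
#' @param params An [nmm_params()] object.
#' @param u1,u4 [time_series()] inputs with equal length and sampling rate.
#' @param init Initial state (length 10); default all zero.
#' @param params_post Optional [nmm_params()] used from `switch_time` on.
#' @param switch_time Time (seconds, on the `u1` time axis) at which
#'   `params_post` takes over. Required when `params_post` is given.
#' @param keep_states If `TRUE`, attach the full state trajectory as
#'   attribute `"states"` (an `n x 10` matrix).
#' @param bound Blow-up guard on any state component. Default `1e7`.
#' @return A [time_series()] of `v1(t)` with the input rate and `t0`.
#' @export
simulate_nmm <- function(params, u1, u4, init = rep(0, 10),
                         params_post = NULL, switch_time = NULL,
                         keep_states = FALSE, bound = 1e7) {
  stopifnot(inherits(params, "nmm_params"))
  check_aligned(u1, u4, "nmm inputs")
  if (length(init) != 10L || !all(is.finite(init)))
    stop("`init` must be 10 finite numbers")
  dt <- 1 / u1$sampling_rate
  wmax <- max(params$w2, params$w3, params$w4)
  if (dt * wmax > 0.5)
    stop(sprintf("dt * max(w) = %g > 0.5: step too large for the fastest synapse",
                 dt * wmax))
  if (params$C12 == 0 && any(u1$samples != 0))
    stop("C12 = 0 with nonzero u1: the excitatory drive divides u1 by C12")
  n <- length(u1$samples)
  if (is.null(params_post)) {
    p2 <- params
    sw <- n + 1L
  } else {
    stopifnot(inherits(params_post, "nmm_params"))
    if (is.null(switch_time))
      stop("`switch_time` must be given with `params_post`")
    sw <- floor((switch_time - u1$t0) * u1$sampling_rate)
    sw <- max(0L, min(n, as.integer(sw)))
    p2 <- params_post
  }
  out <- .nmm_rk4(nmm_param_vector(params), nmm_param_vector(p2), sw,
                  as.numeric(init), u1$samples, u4$samples, dt, bound)
  v1 <- time_series(out[, 11], sampling_rate = u1$sampling_rate, t0 = u1$t0)
  if (keep_states) {
    states <- out[, 1:10, drop = FALSE]
    colnames(states) <- nmm_state_names
    attr(v1, "states") <- states
  }
  v1
}

#' Default parameter sets per experimental condition
#'
#' Returns the documented default neural mass parameters for the `"normal"`
#' condition, or the same set with the virtual-reality connectivity
#' overrides applied for `"vr"`. The two sets differ in exactly the
#' override entries.
#'
#' @param condition `"normal"` or `"vr"`.
#' @param overrides Named list of parameter overrides applied for `"vr"`;
#'   default [vr_default_overrides()].
#' @return An [nmm_params()] object.
#' @examples
#' default_params("normal")$e0  # 2.5
#' @export
default_params <- function(condition = c("normal", "vr"),
                           overrides = vr_default_overrides()) {
  condition <- match.arg(condition)
  base <- nmm_params()
  if (condition == "normal") return(base)
  if (length(overrides) &&
      !all(names(overrides) %in% names(unclass(base))))
    stop("unknown parameter name in overrides: ",
         paste(setdiff(names(overrides), names(unclass(base))),
               collapse = ", "))
  do.call(nmm_params, modifyList(unclass(base), as.list(overrides)))
}
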