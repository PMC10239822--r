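#' @useDynLib pumpneuron, .registration = TRUE
NULL

.gating_names <- c("mNaT", "hNaT", "mNaP", "mKf", "hKf1", "hKf2", "nKs")
.state_names <- c("V", .gating_names, "Na")

#' Steady states and time constants of the gating variables
#'
#' Evaluates the voltage dependence of the seven gating variables: the
#' Boltzmann steady-state curves x_inf(V) and the sigmoid time constants
#' tau(V), in ms. The persistent-sodium activation has a fixed 1 ms time
#' constant and the second fast-K inactivation component a fixed 116 ms
#' time constant.
#'
#' @param V membrane potential (mV), may be a vector
#' @return a list with matrices (rows follow `V`) `x_inf` and `tau`, each
#'   with one column per gating variable in the order mNaT, hNaT, mNaP,
#'   mKf, hKf1, hKf2, nKs
#' @export
gating_kinetics <- function(V) {
  if (!is.numeric(V) || any(!is.finite(V)))
    stop("V must be finite")
  boltz <- function(half, slope) 1 / (1 + exp((V + half) / slope))
  x_inf <- cbind(mNaT = boltz(29.13, -8.922),
                 hNaT = boltz(40.0, 6.048),
                 mNaP = boltz(48.77, -3.68),
                 mKf  = boltz(17.55, -7.27),
                 hKf1 = boltz(45.0, 6.0),
                 hKf2 = boltz(44.2, 1.5),
                 nKs  = boltz(12.85, -19.91))
  tau <- cbind(mNaT = 3.861 - 3.434 / (1 + exp((V + 51.35) / -5.98)),
               hNaT = 2.834 - 2.371 / (1 + exp((V + 2.19) / -2.641)),
               mNaP = rep(1.0, length(V)),
               mKf  = 1.94 + 2.66 / (1 + exp((V - 8.12) / 7.96)),
               hKf1 = 1.79 + 515.8 / (1 + exp((V + 147.4) / -28.66)),
               hKf2 = rep(116.0, length(V)),
               nKs  = 2.03 + 1.96 / (1 + exp((V - 29.83) / 3.32)))
  list(x_inf = x_inf, tau = tau)
}

#' Gating steady state at a holding potential
#'
#' Convenience wrapper returning the x_inf values at a single voltage as a
#' named vector, used to initialise cold starts.
#'
#' @param V membrane potential (mV), scalar
#' @return named numeric vector of the seven gating variables
#' @export
resting_gating <- function(V) {
  stopifnot(length(V) == 1L)
  gating_kinetics(V)$x_inf[1, ]
}

#' Na/K pump current
#'
#' Instantaneous sigmoid dependence of the electrogenic pump current on
#' intracellular sodium; there is no explicit activation time constant, the
#' pump follows concentration changes immediately. Strictly increasing in
#' `Na_in` and bounded in (0, Ipumpmax).
#'
#' @param Na_in intracellular sodium (mM), may be a vector
#' @param pump a [pump_parameters()] object
#' @return pump current (pA)
#' @export
pump_current <- function(Na_in, pump = pump_parameters()) {
  if (!is.numeric(Na_in) || any(!is.finite(Na_in)) || any(Na_in <= 0))
    stop("Na_in must be positive and finite")
  pump$Ipumpmax / (1 + exp((pump$NaH - Na_in) / pump$NaS))
}

#' Sodium Nernst potential
#'
#' `E_Na = (RT/F) ln(Na_out / Na_in)` with the natural logarithm and the
#' thermal voltage of the environment (about 25.69 mV at 25 degrees C).
#' Strictly decreasing in `Na_in`.
#'
#' @param Na_in intracellular sodium (mM), may be a vector
#' @param env a [sodium_environment()] object
#' @return reversal potential (mV)
#' @export
nernst_sodium <- function(Na_in, env = sodium_environment()) {
  if (!is.numeric(Na_in) || any(!is.finite(Na_in)) || any(Na_in <= 0))
    stop("Na_in must be positive and finite")
  env$RTF * log(env$Na_out / Na_in)
}

#' Construct a model state
#'
#' @param V membrane potential (mV)
#' @param gating named vector of the seven gating variables, each in
#'   \[0, 1\]; defaults to the steady state at `V`
#' @param Na_in intracellular sodium (mM)
#' @return named numeric state vector of length 9 (class `neuron_state`)
#' @export
neuron_state <- function(V, gating = resting_gating(V), Na_in = 40.08) {
  stopifnot(is.numeric(V), length(V) == 1L, is.finite(V))
  if (is.null(names(gating))) names(gating) <- .gating_names
  if (!setequal(names(gating), .gating_names))
    stop("gating must contain exactly: ", paste(.gating_names, collapse = ", "))
  gating <- gating[.gating_names]
  if (any(gating < 0 | gating > 1))
    stop("gating variables must lie in [0, 1]")
  if (!is.finite(Na_in) || Na_in <= 0)
    stop("Na_in must be positive")
  structure(c(V = V, gating, Na = Na_in), class = "neuron_state")
}

#' Instantaneous membrane currents
#'
#' Evaluates every membrane current and the pump current at a state, with
#' outward currents positive (sodium currents are negative at rest). The
#' effective sodium reversal is the frozen resting value unless the
#' variant's `ena_dynamic` switch is on, in which case it is the Nernst
#' potential of the momentary sodium concentration.
#'
#' @param state a [neuron_state()] (or named length-9 numeric vector)
#' @param model a [neuron_model()]
#' @return list with `INaT`, `INaP`, `INaleak`, `IKf`, `IKs`, `IKleak`,
#'   `Ipump` (pA) and `ENa_effective` (mV)
#' @export
membrane_currents <- function(state, model = neuron_model()) {
  s <- .as_state(state)
  mem <- model$membrane
  ENa <- if (model$variant$ena_dynamic)
    nernst_sodium(s[["Na"]], model$env) else model$env$ENa_rest
  V <- s[["V"]]
  list(
    INaT = mem$gNaT * s[["mNaT"]]^3 * s[["hNaT"]] * (V - ENa),
    INaP = mem$gNaP * s[["mNaP"]] * (V - ENa),
    INaleak = mem$gNaleak * (V - ENa),
    IKf = mem$gKf * s[["mKf"]]^4 *
      (0.95 * s[["hKf1"]] + 0.05 * s[["hKf2"]]) * (V - mem$EK),
    IKs = mem$gKs * s[["nKs"]]^4 * (V - mem$EK),
    IKleak = mem$gKleak * (V - mem$EK),
    Ipump = pump_current(s[["Na"]], model$pump),
    ENa_effective = ENa
  )
}

#' Time derivative of the full state
#'
#' The voltage obeys `dV/dt = -(sum of membrane and pump currents - Iinj)/C`
#' in mV/ms; each gating variable relaxes to its steady state with its
#' voltage-dependent time constant; intracellular sodium changes with the
#' sodium currents and three times the pump current (three sodium ions are
#' extruded per elementary charge), scaled by 1/(F*Vol) - or not at all
#' when the concentration is frozen.
#'
#' This is the reference R implementation; the integrator uses an
#' identical compiled version, and the two are cross-checked in the test
#' suite.
#'
#' @param t time (ms); the autonomous system ignores it, it is accepted for
#'   solver compatibility
#' @param state a [neuron_state()] (or named length-9 numeric vector)
#' @param I_inj injected current (pA)
#' @param model a [neuron_model()]
#' @return named numeric vector of the nine state derivatives (per ms)
#' @export
state_derivative <- function(t = 0, state, I_inj = 0, model = neuron_model()) {
  stopifnot(is.finite(I_inj))
  s <- .as_state(state)
  cur <- membrane_currents(s, model)
  gk <- gating_kinetics(s[["V"]])
  I_mem <- cur$INaT + cur$INaP + cur$INaleak + cur$IKf + cur$IKs +
    cur$IKleak + cur$Ipump
  dV <- -(I_mem - I_inj) / model$membrane$C
  dgating <- (gk$x_inf[1, ] - s[.gating_names]) / gk$tau[1, ]
  dNa <- if (model$variant$na_dynamic)
    -(cur$INaT + cur$INaP + cur$INaleak + 3 * cur$Ipump) * model$env$kNa
  else 0
  out <- c(dV, dgating, dNa)
  names(out) <- .state_names
  out
}

.as_state <- function(state) {
  s <- unclass(state)
  if (!is.numeric(s) || length(s) != 9L)
    stop("state must be a numeric vector of length 9")
  if (is.null(names(s))) names(s) <- .state_names
  if (!setequal(names(s), .state_names))
    stop("state must be named: ", paste(.state_names, collapse = ", "))
  s[.state_names]
}

# compiled-RHS evaluation used by find_rest polishing and the R-vs-C test
.state_derivative_c <- function(t, state, model, stim_parms = .null_stim()) {
  p <- .model_parms_vector(model, stim_parms)
  out <- .Call(C_pumpneuron_derivs, as.double(t),
               as.double(.as_state(state)), p)
  d <- out[1:9]
  names(d) <- .state_names
  list(derivative = d, ENa = out[10], Ipump = out[11], Iinj = out[12])
}
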