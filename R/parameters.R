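#' Membrane parameters of the motoneuron model
#'
#' Capacitance, maximal conductances and the potassium reversal potential of
#' the single-compartment model. Defaults are the published values for the
#' larval motoneuron: six membrane currents (transient and persistent sodium,
#' fast and slow potassium, and sodium/potassium leaks).
#'
#' @param C membrane capacitance (pF)
#' @param gNaT maximal transient sodium conductance (nS)
#' @param gNaP maximal persistent sodium conductance (nS)
#' @param gNaleak sodium leak conductance (nS)
#' @param gKf maximal fast potassium conductance (nS)
#' @param gKs maximal slow potassium conductance (nS)
#' @param gKleak potassium leak conductance (nS)
#' @param EK potassium reversal potential (mV)
#' @return an object of class `membrane_parameters`
#' @export
membrane_parameters <- function(C = 4.0, gNaT = 100.0, gNaP = 0.80,
                                gNaleak = 1.2, gKf = 15.1, gKs = 50.0,
                                gKleak = 3.75, EK = -80.0) {
  p <- list(C = C, gNaT = gNaT, gNaP = gNaP, gNaleak = gNaleak,
            gKf = gKf, gKs = gKs, gKleak = gKleak, EK = EK)
  for (nm in names(p)) {
    if (!is.numeric(p[[nm]]) || length(p[[nm]]) != 1L || !is.finite(p[[nm]]))
      stop("membrane parameter '", nm, "' must be a finite scalar")
  }
  if (C <= 0) stop("capacitance C must be positive")
  g <- unlist(p[c("gNaT", "gNaP", "gNaleak", "gKf", "gKs", "gKleak")])
  if (any(g < 0)) stop("conductances must be non-negative")
  structure(p, class = "membrane_parameters")
}

#' Na/K pump parameters
#'
#' The pump current is an instantaneous sigmoid function of intracellular
#' sodium: `Ipump = Ipumpmax / (1 + exp((NaH - Na) / NaS))`. `NaH` is the
#' sodium concentration of half activation and `NaS` sets the steepness of
#' the sodium dependence.
#'
#' @param Ipumpmax maximal pump current (pA)
#' @param NaH half-activation sodium concentration (mM)
#' @param NaS activation slope factor (mM)
#' @return an object of class `pump_parameters`
#' @export
pump_parameters <- function(Ipumpmax = 75, NaH = 40, NaS = 10) {
  p <- list(Ipumpmax = Ipumpmax, NaH = NaH, NaS = NaS)
  for (nm in names(p)) {
    if (!is.numeric(p[[nm]]) || length(p[[nm]]) != 1L || !is.finite(p[[nm]]))
      stop("pump parameter '", nm, "' must be a finite scalar")
    if (p[[nm]] <= 0)
      stop("pump parameter '", nm, "' must be positive")
  }
  structure(p, class = "pump_parameters")
}

#' Ionic environment for the sodium balance
#'
#' Fixed extracellular sodium, the volume of the sub-membrane shell whose
#' concentration the sodium currents change, the temperature entering the
#' Nernst equation, and the reference resting concentration/reversal used
#' when the respective dynamics are frozen.
#'
#' The thermal voltage RT/F is derived from `temperature` (about 25.69 mV at
#' 25 degrees C), and the flux conversion constant 1/(F*Vol) (about
#' 1.888e-5 mM per pA*ms at the default shell volume) is derived from `Vol`.
#'
#' @param Na_out extracellular sodium concentration (mM)
#' @param Vol sub-membrane shell volume (pL)
#' @param temperature absolute temperature (K)
#' @param Na_rest reference resting intracellular sodium (mM)
#' @param ENa_rest reference resting sodium reversal potential (mV); must be
#'   consistent with the Nernst potential of `Na_rest` to within 0.05 mV
#' @return an object of class `sodium_environment`
#' @export
sodium_environment <- function(Na_out = 135, Vol = 0.549,
                               temperature = 298.15, Na_rest = 40.08,
                               ENa_rest = 31.2) {
  if (Na_out <= 0 || Vol <= 0 || temperature <= 0 || Na_rest <= 0)
    stop("Na_out, Vol, temperature and Na_rest must be positive")
  RTF <- 1000 * 8.314462618 * temperature / 96485.332   # mV
  kNa <- 1 / (96485.332 * Vol)                          # mM / (pA ms)
  env <- structure(list(Na_out = Na_out, Vol = Vol,
                        temperature = temperature, Na_rest = Na_rest,
                        ENa_rest = ENa_rest, RTF = RTF, kNa = kNa),
                   class = "sodium_environment")
  nernst <- RTF * log(Na_out / Na_rest)
  if (abs(nernst - ENa_rest) > 0.05)
    stop(sprintf(paste0("ENa_rest = %.3f mV is inconsistent with the Nernst",
                        " potential of Na_rest (%.3f mV)"),
                 ENa_rest, nernst))
  env
}

#' Variant switches: which sodium quantities are dynamic
#'
#' Two switches define the model variants: `na_dynamic` lets intracellular
#' sodium evolve with the membrane sodium fluxes and the pump (otherwise it
#' is frozen at `Na_rest`), and `ena_dynamic` lets the sodium reversal
#' potential follow the Nernst equation of the momentary concentration
#' (otherwise it is frozen at `ENa_rest`). A dynamic reversal without a
#' dynamic concentration is meaningless and is rejected.
#'
#' Named presets: `ConCon` = (FALSE, FALSE), `DynCon` = (TRUE, FALSE),
#' `DynDyn` = (TRUE, TRUE).
#'
#' @param na_dynamic logical; intracellular sodium evolves dynamically
#' @param ena_dynamic logical; sodium reversal follows the Nernst equation
#' @return an object of class `variant_switches`
#' @export
variant_switches <- function(na_dynamic, ena_dynamic) {
  stopifnot(is.logical(na_dynamic), length(na_dynamic) == 1L,
            is.logical(ena_dynamic), length(ena_dynamic) == 1L,
            !is.na(na_dynamic), !is.na(ena_dynamic))
  if (ena_dynamic && !na_dynamic)
    stop("ena_dynamic = TRUE requires na_dynamic = TRUE: ",
         "the reversal potential cannot vary while the concentration is frozen")
  name <- if (!na_dynamic) "ConCon" else if (!ena_dynamic) "DynCon" else "DynDyn"
  structure(list(na_dynamic = na_dynamic, ena_dynamic = ena_dynamic,
                 name = name),
            class = "variant_switches")
}

#' @rdname variant_switches
#' @param name one of `"ConCon"`, `"DynCon"`, `"DynDyn"`
#' @export
variant_preset <- function(name = c("DynDyn", "DynCon", "ConCon")) {
  name <- match.arg(name)
  switch(name,
         ConCon = variant_switches(FALSE, FALSE),
         DynCon = variant_switches(TRUE, FALSE),
         DynDyn = variant_switches(TRUE, TRUE))
}

#' Assemble a complete model configuration
#'
#' Bundles membrane, pump and environment parameters with the variant
#' switches into one object consumed by [state_derivative()],
#' [integrate_model()] and the experiment drivers.
#'
#' @param variant a [variant_switches()] object or a preset name
#' @param membrane a [membrane_parameters()] object
#' @param pump a [pump_parameters()] object
#' @param env a [sodium_environment()] object
#' @return an object of class `neuron_model`
#' @examples
#' m <- neuron_model("DynDyn")
#' m$pump$Ipumpmax
#' @export
neuron_model <- function(variant = "DynDyn",
                         membrane = membrane_parameters(),
                         pump = pump_parameters(),
                         env = sodium_environment()) {
  if (is.character(variant)) variant <- variant_preset(variant)
  stopifnot(inherits(variant, "variant_switches"),
            inherits(membrane, "membrane_parameters"),
            inherits(pump, "pump_parameters"),
            inherits(env, "sodium_environment"))
  structure(list(variant = variant, membrane = membrane, pump = pump,
                 env = env),
            class = "neuron_model")
}

#' @export
print.neuron_model <- function(x, ...) {
  cat("<neuron_model> variant", x$variant$name, "\n")
  cat(sprintf("  membrane: C=%g pF, gNaT=%g, gNaP=%g, gNaleak=%g, gKf=%g, gKs=%g, gKleak=%g nS, EK=%g mV\n",
              x$membrane$C, x$membrane$gNaT, x$membrane$gNaP,
              x$membrane$gNaleak, x$membrane$gKf, x$membrane$gKs,
              x$membrane$gKleak, x$membrane$EK))
  cat(sprintf("  pump: Ipumpmax=%g pA, NaH=%g mM, NaS=%g mM\n",
              x$pump$Ipumpmax, x$pump$NaH, x$pump$NaS))
  cat(sprintf("  environment: Na_out=%g mM, Vol=%g pL, T=%g K, Na_rest=%g mM, ENa_rest=%g mV\n",
              x$env$Na_out, x$env$Vol, x$env$temperature, x$env$Na_rest,
              x$env$ENa_rest))
  invisible(x)
}

#' Numerical integration options
#'
#' Defaults follow the reference implementation of the model: absolute
#' tolerance 1.49012e-8, relative tolerance 1e-10, trace sampling every
#' 0.05 ms. `max_step` caps the internal step of the adaptive solver so
#' that narrow spikes are never stepped over.
#'
#' @param abs_tol absolute solver tolerance
#' @param rel_tol relative solver tolerance
#' @param max_step maximal internal solver step (ms)
#' @param output_dt trace sampling interval (ms); sampling only, the
#'   solution itself does not depend on it
#' @return an object of class `solver_options`
#' @export
solver_options <- function(abs_tol = 1.49012e-8, rel_tol = 1e-10,
                           max_step = 1.0, output_dt = 0.05) {
  stopifnot(abs_tol > 0, rel_tol > 0, max_step > 0, output_dt > 0)
  structure(list(abs_tol = abs_tol, rel_tol = rel_tol,
                 max_step = max_step, output_dt = output_dt),
            class = "solver_options")
}
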