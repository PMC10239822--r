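# Stimulus protocols.
#
# A stimulus is a list of non-overlapping segments on the time axis (ms);
# outside every segment the injected current is 0 pA. Segment windows are
# half-open [t0, t1): the sample at the offset carries 0 pA, which makes
# charge accounting unambiguous. Each segment is one of
#   const  : I = amp
#   linear : I = a + b (t - t0)
#   zap    : exponential chirp, deceleration half = exact time mirror
# The segment boundaries are the protocol's breakpoints, and the integrator
# restarts the solver at each of them so that discontinuities are not
# smeared.

.stimulus <- function(segments, duration) {
  if (nrow(segments) > 1) {
    o <- order(segments$t0)
    segments <- segments[o, , drop = FALSE]
    if (any(segments$t1[-nrow(segments)] > segments$t0[-1] + 1e-9))
      stop("stimulus segments overlap")
  }
  bp <- sort(unique(c(0, segments$t0, segments$t1, duration)))
  bp <- bp[bp >= 0 & bp <= duration]
  structure(list(segments = segments, breakpoints = bp, duration = duration),
            class = "stimulus")
}

.segment_row <- function(t0, t1, type, p1 = 0, p2 = 0, p3 = 0, p4 = 0) {
  data.frame(t0 = t0, t1 = t1, type = type, p1 = p1, p2 = p2, p3 = p3,
             p4 = p4)
}

#' Rectangular step current
#'
#' `amplitude` pA on the half-open window \[onset, onset + duration); 0 pA
#' elsewhere.
#'
#' @param amplitude step amplitude (pA)
#' @param onset step onset (ms)
#' @param duration step duration (ms)
#' @param total total protocol duration (ms); defaults to the step offset
#' @return a `stimulus` object
#' @export
step_stimulus <- function(amplitude, onset = 0, duration = 5000,
                          total = onset + duration) {
  stopifnot(is.finite(amplitude), duration > 0, onset >= 0,
            total >= onset + duration)
  .stimulus(.segment_row(onset, onset + duration, 0L, p1 = amplitude), total)
}

#' Bidirectional ramp current
#'
#' Piecewise-linear 0 -> `peak` -> 0, continuous everywhere.
#'
#' @param peak peak current (pA)
#' @param up_duration rising-phase duration (ms)
#' @param down_duration falling-phase duration (ms)
#' @param onset ramp onset (ms)
#' @param total total protocol duration (ms)
#' @return a `stimulus` object
#' @export
ramp_stimulus <- function(peak, up_duration, down_duration, onset = 0,
                          total = onset + up_duration + down_duration) {
  stopifnot(is.finite(peak), up_duration > 0, down_duration > 0, onset >= 0)
  t_peak <- onset + up_duration
  segs <- rbind(
    .segment_row(onset, t_peak, 1L, p1 = 0, p2 = peak / up_duration),
    .segment_row(t_peak, t_peak + down_duration, 1L, p1 = peak,
                 p2 = -peak / down_duration))
  .stimulus(segs, total)
}

#' Zap (chirp) stimulus parameters
#'
#' A sinusoidal current whose frequency sweeps exponentially from `f0` to
#' `fmax` over the acceleration half of duration `tau_half`, then back as
#' the exact time mirror. The rising factor is
#' `lambda = ln(fmax/f0)/tau_half`.
#'
#' @param Izapmax maximal current amplitude (pA)
#' @param f0 minimal zap frequency (Hz)
#' @param fmax maximal zap frequency (Hz)
#' @param tau_half half duration of the sweep (s)
#' @return an object of class `zap_parameters`
#' @export
zap_parameters <- function(Izapmax, f0 = 0.1, fmax = 5.0, tau_half = 20) {
  stopifnot(is.finite(Izapmax), f0 > 0, fmax > f0, tau_half > 0)
  structure(list(Izapmax = Izapmax, f0 = f0, fmax = fmax,
                 tau_half = tau_half,
                 lambda = log(fmax / f0) / tau_half),
            class = "zap_parameters")
}

#' Momentary zap frequency on the acceleration half
#'
#' `f_zap(t) = f0 (exp(lambda t) - 1)/(lambda t)` with the removable
#' singularity `f_zap(0) = f0`. This is the phase-average frequency whose
#' accumulated phase `2 pi f_zap t` equals the integrated phase of the
#' instantaneous exponential sweep `f0 exp(lambda t)`, which reaches `fmax`
#' exactly at `tau_half`.
#'
#' @param t time since the start of the acceleration half (s); vectorised
#' @param zap a [zap_parameters()] object
#' @return frequency (Hz)
#' @export
zap_frequency <- function(t, zap) {
  stopifnot(inherits(zap, "zap_parameters"))
  if (any(t < 0 | t > zap$tau_half))
    stop("t must lie in [0, tau_half]")
  x <- zap$lambda * t
  ifelse(x == 0, zap$f0, zap$f0 * expm1(x) / x)
}

#' Zap current waveform
#'
#' `Izap(t) = Izapmax (0.5 + 0.5 cos(2 pi f_zap t + pi))` on the
#' acceleration half; the deceleration half is the time mirror of the
#' acceleration waveform, so the full waveform satisfies
#' `I(t) = I(2 tau_half - t)`. `I(0) = 0` by the pi phase offset, and
#' `0 <= I <= Izapmax` everywhere.
#'
#' @param t time since zap onset (s); vectorised, in \[0, 2 tau_half\]
#' @param zap a [zap_parameters()] object
#' @return current (pA)
#' @export
zap_current <- function(t, zap) {
  stopifnot(inherits(zap, "zap_parameters"))
  if (any(t < 0 | t > 2 * zap$tau_half))
    stop("t must lie in [0, 2*tau_half]")
  ta <- ifelse(t <= zap$tau_half, t, 2 * zap$tau_half - t)
  phase <- 2 * pi * zap$f0 / zap$lambda * expm1(zap$lambda * ta)
  zap$Izapmax * (0.5 + 0.5 * cos(phase + pi))
}

#' Zap stimulus protocol
#'
#' @param Izapmax maximal current amplitude (pA)
#' @param f0,fmax,tau_half see [zap_parameters()]
#' @param onset zap onset (ms)
#' @param total total protocol duration (ms)
#' @return a `stimulus` object carrying the zap as one segment (the
#'   half-way point is an additional breakpoint)
#' @export
zap_stimulus <- function(Izapmax, f0 = 0.1, fmax = 5.0, tau_half = 20,
                         onset = 0, total = onset + 2000 * tau_half) {
  z <- zap_parameters(Izapmax, f0, fmax, tau_half)
  seg <- .segment_row(onset, onset + 2000 * tau_half, 2L, p1 = z$Izapmax,
                      p2 = z$f0, p3 = z$lambda, p4 = z$tau_half)
  s <- .stimulus(seg, total)
  s$breakpoints <- sort(unique(c(s$breakpoints, onset + 1000 * tau_half)))
  s$zap <- z
  s
}

#' Test-pulse memory protocol
#'
#' A short test pulse probing baseline excitability, a gap, the main
#' stimulus, a post-stimulus gap of length `delay`, and the identical test
#' pulse again. The pre-stimulus pulse ends `pre_gap` ms before the main
#' stimulus onset.
#'
#' @param test_amp test-pulse amplitude (pA)
#' @param test_dur test-pulse duration (ms)
#' @param main_amp main-stimulus amplitude (pA)
#' @param main_dur main-stimulus duration (ms)
#' @param delay gap between main-stimulus offset and the second test pulse
#'   (s)
#' @param pre_gap gap between the first test pulse offset and the main
#'   stimulus onset (ms)
#' @param tail recording tail after the second test pulse (ms)
#' @return a `stimulus` object; attributes `test1_onset`, `main_onset`,
#'   `main_offset`, `test2_onset` give the protocol landmarks (ms)
#' @export
memory_stimulus <- function(test_amp = 22, test_dur = 200, main_amp = 50,
                            main_dur = 5000, delay = 1, pre_gap = 5000,
                            tail = 800) {
  stopifnot(delay > 0, test_dur > 0, main_dur > 0, pre_gap > 0)
  t1_on <- 0
  main_on <- t1_on + test_dur + pre_gap
  main_off <- main_on + main_dur
  t2_on <- main_off + 1000 * delay
  segs <- rbind(
    .segment_row(t1_on, t1_on + test_dur, 0L, p1 = test_amp),
    .segment_row(main_on, main_off, 0L, p1 = main_amp),
    .segment_row(t2_on, t2_on + test_dur, 0L, p1 = test_amp))
  s <- .stimulus(segs, t2_on + test_dur + tail)
  s$landmarks <- c(test1_onset = t1_on, main_onset = main_on,
                   main_offset = main_off, test2_onset = t2_on,
                   test_dur = test_dur)
  s
}

#' Evaluate a stimulus protocol
#'
#' Pure-R evaluation of the injected current; the integrator uses an
#' identical compiled evaluator, and the two are cross-checked in the test
#' suite. Outside the protocol window the current is 0.
#'
#' @param stim a `stimulus` object
#' @param t times (ms), vectorised
#' @return injected current (pA)
#' @export
eval_stimulus <- function(stim, t) {
  stopifnot(inherits(stim, "stimulus"))
  out <- numeric(length(t))
  for (i in seq_len(nrow(stim$segments))) {
    seg <- stim$segments[i, ]
    sel <- t >= seg$t0 & t < seg$t1
    if (!any(sel)) next
    out[sel] <- switch(as.character(seg$type),
      "0" = seg$p1,
      "1" = seg$p1 + seg$p2 * (t[sel] - seg$t0),
      "2" = {
        z <- zap_parameters(seg$p1, seg$p2,
                            seg$p2 * exp(seg$p3 * seg$p4), seg$p4)
        zap_current((t[sel] - seg$t0) / 1000, z)
      },
      stop("unknown segment type"))
  }
  out
}

#' Breakpoints of a stimulus protocol
#'
#' Times (ms) at which the protocol definition changes; the integrator
#' restarts the solver there.
#'
#' @param stim a `stimulus` object
#' @return numeric vector of times (ms)
#' @export
stimulus_breakpoints <- function(stim) {
  stopifnot(inherits(stim, "stimulus"))
  stim$breakpoints
}

#' @export
print.stimulus <- function(x, ...) {
  type_names <- c("0" = "step", "1" = "ramp piece", "2" = "zap")
  cat("<stimulus>", nrow(x$segments), "segment(s), duration",
      x$duration, "ms\n")
  for (i in seq_len(nrow(x$segments))) {
    s <- x$segments[i, ]
    cat(sprintf("  [%g, %g) ms: %s", s$t0, s$t1, type_names[[as.character(s$type)]]))
    if (s$type == 0L) cat(sprintf(" %g pA", s$p1))
    if (s$type == 2L) cat(sprintf(" Izapmax=%g pA, f0=%g Hz, lambda=%g /s",
                                  s$p1, s$p2, s$p3))
    cat("\n")
  }
  invisible(x)
}

# zero-stimulus placeholder for the compiled parameter vector
.null_stim <- function() c(type = 0, p1 = 0, p2 = 0, p3 = 0, p4 = 0,
                           t0 = 0, t1 = -1)
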