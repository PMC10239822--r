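# Scripted in-silico experiments. Every driver is a pure function of its
# configuration: identical inputs produce identical tables.

#' Run one step-current response from rest
#'
#' Relaxes the model to rest, applies a rectangular step and records the
#' response plus a post-stimulus tail, returning the trace together with
#' the step descriptors.
#'
#' @param model a [neuron_model()]
#' @param amplitude step amplitude (pA)
#' @param duration step duration (ms)
#' @param tail post-stimulus tail (ms); AHP half-durations need several
#'   tens of seconds
#' @param onset step onset (ms)
#' @param rest optional pre-computed [find_rest()] result
#' @param options a [solver_options()]
#' @param ahp compute AHP metrics
#' @return list with `trace`, `metrics` (a [step_response_metrics()]) and
#'   `rest`
#' @export
run_step_response <- function(model, amplitude, duration = 5000,
                              tail = 60000, onset = 0, rest = NULL,
                              options = solver_options(), ahp = TRUE) {
  if (is.null(rest)) rest <- find_rest(model, options = options)
  if (!rest$converged)
    stop("no stable resting state for this parameter set")
  stim <- step_stimulus(amplitude, onset = onset, duration = duration,
                        total = onset + duration + tail)
  tr <- integrate_model(model, stim, onset + duration + tail,
                        init = rest$state, options = options)
  m <- step_response_metrics(tr, onset, onset + duration, ahp = ahp)
  list(trace = tr, metrics = m, rest = rest)
}

#' FI curve: step responses over a range of currents
#'
#' For each injected current, computes IFR_ini, IFR_fin, adaptation slope,
#' spike count, response classification and (optionally) the AHP metrics.
#' Subthreshold and depolarization-block rows are flagged in
#' `classification` rather than dropped.
#'
#' @param model a [neuron_model()] (or a preset name)
#' @param currents injected currents (pA)
#' @param duration step duration (ms)
#' @param tail post-stimulus tail (ms)
#' @param ahp compute AHP metrics (set `FALSE` with a short tail when only
#'   the spiking descriptors are needed)
#' @param options a [solver_options()]
#' @return data frame, one row per current, with columns `variant`,
#'   `current`, `n_spikes`, `IFR_ini`, `IFR_fin`, `s_adapt`,
#'   `classification` (+ `AHPamp`, `T_half` when `ahp`)
#' @export
run_fi_curve <- function(model, currents, duration = 5000,
                         tail = if (ahp) 60000 else 1000, ahp = FALSE,
                         options = solver_options()) {
  model <- .as_model(model)
  rest <- find_rest(model, options = options)
  if (!rest$converged) stop("no stable resting state")
  rows <- lapply(currents, function(a) {
    r <- tryCatch(
      run_step_response(model, a, duration, tail, rest = rest,
                        options = options, ahp = ahp),
      error = function(e) e)
    if (inherits(r, "error"))
      return(data.frame(variant = model$variant$name, current = a,
                        n_spikes = NA_integer_, IFR_ini = NA_real_,
                        IFR_fin = NA_real_, s_adapt = NA_real_,
                        classification = NA_character_,
                        status = conditionMessage(r)))
    m <- r$metrics
    out <- data.frame(variant = model$variant$name, current = a,
                      n_spikes = m$n_spikes, IFR_ini = m$IFR_ini,
                      IFR_fin = m$IFR_fin, s_adapt = as.numeric(m$s_adapt),
                      classification = m$classification, status = "ok")
    if (ahp) {
      out$AHPamp <- m$AHPamp
      out$T_half <- m$T_half
    }
    out
  })
  do.call(rbind, rows)
}

#' Smallest current sustaining spiking through the full step
#'
#' Scans integer currents and returns the smallest amplitude classified as
#' `sustained` such that all larger scanned amplitudes are also sustained
#' (premature termination occurs below it).
#'
#' @param model a [neuron_model()] or preset name
#' @param currents integer currents to scan (pA)
#' @param duration step duration (ms)
#' @param options a [solver_options()]
#' @return list with `threshold` (pA, `NA` if no sustained current) and the
#'   scan `table`
#' @export
sustained_spiking_threshold <- function(model, currents = 20:50,
                                        duration = 5000,
                                        options = solver_options()) {
  fi <- run_fi_curve(model, currents, duration, tail = 1000, ahp = FALSE,
                     options = options)
  sust <- fi$classification == "sustained"
  thr <- NA_real_
  for (i in seq_along(currents)) {
    if (all(sust[i:length(sust)])) { thr <- currents[i]; break }
  }
  list(threshold = thr, table = fi)
}

#' Bidirectional current ramps and rate hysteresis
#'
#' Simulates 0 -> `peak` -> 0 pA ramps of several total durations and
#' relates the IFR to the momentary injected current on the up and down
#' phases. The hysteresis metric is the mean difference (up minus down) of
#' the IFR, interpolated onto a common current grid over the overlapping
#' current range.
#'
#' @param model a [neuron_model()] or preset name
#' @param peak ramp peak (pA)
#' @param total_durations total ramp durations (s)
#' @param options a [solver_options()]
#' @return list with `summary` (data frame: variant, total_duration_s,
#'   hysteresis_hz, n_spikes) and `details` (per duration: the IFR-current
#'   tables for both phases)
#' @export
run_ramp_suite <- function(model, peak = 70, total_durations = c(2, 10, 40),
                           options = solver_options()) {
  model <- .as_model(model)
  rest <- find_rest(model, options = options)
  if (!rest$converged) stop("no stable resting state")
  details <- list()
  rows <- lapply(total_durations, function(td) {
    half <- 1000 * td / 2
    stim <- ramp_stimulus(peak, half, half)
    tr <- integrate_model(model, stim, 1000 * td, init = rest$state,
                          options = options)
    train <- detect_spikes(tr)
    ifr <- ifr_series(train)
    cur <- eval_stimulus(stim, ifr$t)
    up <- ifr$t <= half
    h <- .ifr_hysteresis(cur[up], ifr$ifr[up], cur[!up], ifr$ifr[!up])
    details[[as.character(td)]] <<- list(
      up = data.frame(current = cur[up], ifr = ifr$ifr[up]),
      down = data.frame(current = cur[!up], ifr = ifr$ifr[!up]))
    data.frame(variant = model$variant$name, total_duration_s = td,
               hysteresis_hz = h, n_spikes = length(train$times))
  })
  list(summary = do.call(rbind, rows), details = details)
}

.ifr_hysteresis <- function(cur_up, ifr_up, cur_down, ifr_down) {
  if (length(cur_up) < 2 || length(cur_down) < 2) return(NA_real_)
  lo <- max(min(cur_up), min(cur_down))
  hi <- min(max(cur_up), max(cur_down))
  if (hi <= lo) return(NA_real_)
  grid <- seq(lo, hi, length.out = 101)
  up_i <- stats::approx(cur_up, ifr_up, xout = grid, ties = mean)$y
  dn_i <- stats::approx(cur_down, ifr_down, xout = grid, ties = mean)$y
  mean(up_i - dn_i, na.rm = TRUE)
}

#' Zap-current experiment
#'
#' Applies a symmetric exponential chirp and summarises the response per
#' zap cycle: spike counts, the voltage peak of the first and last cycle,
#' and a symmetry score (mean absolute spike-count difference between
#' mirrored cycles).
#'
#' @param model a [neuron_model()] or preset name
#' @param amplitude `Izapmax` (pA)
#' @param f0,fmax,tau_half zap parameters (Hz, Hz, s)
#' @param tail post-zap tail (ms)
#' @param options a [solver_options()]
#' @return list with `per_cycle` (data frame: cycle, t_start, t_end,
#'   n_spikes, V_peak), `first_peak_V`, `last_peak_V`, `symmetry_score`,
#'   `n_spikes`, and the `trace`
#' @export
run_zap <- function(model, amplitude, f0 = 0.1, fmax = 5.0, tau_half = 20,
                    tail = 1000, options = solver_options()) {
  model <- .as_model(model)
  rest <- find_rest(model, options = options)
  if (!rest$converged) stop("no stable resting state")
  stim <- zap_stimulus(amplitude, f0, fmax, tau_half,
                       total = 2000 * tau_half + tail)
  tr <- integrate_model(model, stim, 2000 * tau_half + tail,
                        init = rest$state, options = options)
  z <- stim$zap
  # cycle boundaries: accumulated phase multiples of 2 pi on the
  # acceleration half, mirrored on the deceleration half
  k_max <- floor((z$fmax - z$f0) / z$lambda)
  tb_acc <- log(1 + seq_len(k_max) * z$lambda / z$f0) / z$lambda  # s
  bounds <- sort(unique(c(0, tb_acc, 2 * z$tau_half - tb_acc,
                          z$tau_half, 2 * z$tau_half))) * 1000    # ms
  train <- detect_spikes(tr)
  per_cycle <- data.frame(cycle = seq_len(length(bounds) - 1L),
                          t_start = bounds[-length(bounds)],
                          t_end = bounds[-1L])
  per_cycle$n_spikes <- vapply(seq_len(nrow(per_cycle)), function(i) {
    sum(train$times >= per_cycle$t_start[i] & train$times < per_cycle$t_end[i])
  }, integer(1))
  per_cycle$V_peak <- vapply(seq_len(nrow(per_cycle)), function(i) {
    sel <- tr$t >= per_cycle$t_start[i] & tr$t < per_cycle$t_end[i]
    if (any(sel)) max(tr$V[sel]) else NA_real_
  }, numeric(1))
  n_c <- nrow(per_cycle)
  mirrored <- per_cycle$n_spikes[seq_len(n_c %/% 2)] -
    rev(per_cycle$n_spikes)[seq_len(n_c %/% 2)]
  list(per_cycle = per_cycle,
       first_peak_V = per_cycle$V_peak[1L],
       last_peak_V = per_cycle$V_peak[n_c],
       symmetry_score = mean(abs(mirrored)),
       n_spikes = length(train$times),
       trace = tr)
}

#' Test-pulse memory experiment
#'
#' Probes excitability with a short test pulse before and at chosen delays
#' after a spike-inducing main stimulus. Each delay is an independent
#' simulation from the same rest state. The baseline row reports the
#' pre-stimulus test-pulse response; an isolated-pulse control (test pulse
#' with the main stimulus omitted) can be added for comparison.
#'
#' @param model a [neuron_model()] or preset name
#' @param delays delays between main-stimulus offset and the second test
#'   pulse (s)
#' @param test_amp,test_dur test pulse (pA, ms)
#' @param main_amp,main_dur main stimulus (pA, ms)
#' @param isolated_control also run an isolated late test pulse with no
#'   main stimulus
#' @param options a [solver_options()]
#' @return data frame: one row per condition (`baseline`, one per delay,
#'   optionally `isolated`), with `n_spikes` and `T1_ms` of the test-pulse
#'   response
#' @export
run_memory_protocol <- function(model, delays = c(1, 35, 36, 51, 52),
                                test_amp = 22, test_dur = 200,
                                main_amp = 50, main_dur = 5000,
                                isolated_control = TRUE,
                                options = solver_options()) {
  model <- .as_model(model)
  rest <- find_rest(model, options = options)
  if (!rest$converged) stop("no stable resting state")

  pulse_response <- function(train, onset) {
    in_pulse <- train$times[train$times >= onset &
                              train$times < onset + test_dur]
    t1 <- time_to_first_spike(train, onset, window = test_dur)
    c(n = length(in_pulse), t1 = as.numeric(t1))
  }

  rows <- list()
  for (d in delays) {
    stim <- memory_stimulus(test_amp, test_dur, main_amp, main_dur,
                            delay = d)
    tr <- integrate_model(model, stim, stim$duration, init = rest$state,
                          options = options)
    train <- detect_spikes(tr)
    lm <- stim$landmarks
    if (d == delays[1L]) {
      b <- pulse_response(train, lm[["test1_onset"]])
      rows[["baseline"]] <- data.frame(condition = "baseline",
                                       delay_s = NA_real_,
                                       n_spikes = b[["n"]],
                                       T1_ms = b[["t1"]])
    }
    p <- pulse_response(train, lm[["test2_onset"]])
    rows[[as.character(d)]] <- data.frame(condition = "post",
                                          delay_s = d,
                                          n_spikes = p[["n"]],
                                          T1_ms = p[["t1"]])
  }
  if (isolated_control) {
    d_iso <- max(delays)
    onset_iso <- 200 + 5000 + main_dur + 1000 * d_iso
    stim <- step_stimulus(test_amp, onset = onset_iso, duration = test_dur,
                          total = onset_iso + test_dur + 800)
    tr <- integrate_model(model, stim, stim$duration, init = rest$state,
                          options = options)
    p <- pulse_response(detect_spikes(tr), onset_iso)
    rows[["isolated"]] <- data.frame(condition = "isolated",
                                     delay_s = d_iso,
                                     n_spikes = p[["n"]], T1_ms = p[["t1"]])
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Pump-parameter sweep
#'
#' Varies one pump parameter over a range while the other two stay at
#' their defaults, re-derives the rest state for every value (rest shifts
#' with the pump), and reports the step descriptors of a 50 pA, 5 s
#' injection. Values without a stable rest are flagged, not dropped.
#'
#' @param parameter one of `"Ipumpmax"`, `"NaH"`, `"NaS"`
#' @param values parameter values to scan
#' @param model base [neuron_model()] or preset name
#' @param amplitude,duration,tail step stimulus (pA, ms, ms)
#' @param options a [solver_options()]
#' @return data frame, one row per value, with the step metrics and a
#'   `status` column (`"ok"` or `"no stable rest"`)
#' @export
run_pump_sweep <- function(parameter = c("Ipumpmax", "NaH", "NaS"),
                           values, model = "DynDyn", amplitude = 50,
                           duration = 5000, tail = 60000,
                           options = solver_options()) {
  parameter <- match.arg(parameter)
  base <- .as_model(model)
  rows <- lapply(values, function(v) {
    pump <- base$pump
    pump[[parameter]] <- v
    m <- neuron_model(base$variant,
                      membrane = base$membrane,
                      pump = pump_parameters(pump$Ipumpmax, pump$NaH,
                                             pump$NaS),
                      env = base$env)
    rest <- find_rest(m, options = options)
    if (!rest$converged)
      return(data.frame(parameter = parameter, value = v,
                        V_rest = NA_real_, n_spikes = NA_integer_,
                        IFR_ini = NA_real_, IFR_fin = NA_real_,
                        s_adapt = NA_real_, AHPamp = NA_real_,
                        T_half = NA_real_, status = "no stable rest"))
    r <- run_step_response(m, amplitude, duration, tail, rest = rest,
                           options = options)
    met <- r$metrics
    data.frame(parameter = parameter, value = v,
               V_rest = rest$state[["V"]], n_spikes = met$n_spikes,
               IFR_ini = met$IFR_ini, IFR_fin = met$IFR_fin,
               s_adapt = as.numeric(met$s_adapt), AHPamp = met$AHPamp,
               T_half = met$T_half, status = "ok")
  })
  do.call(rbind, rows)
}

#' Bursting survey over pump-parameter sets
#'
#' For each `(Ipumpmax, NaH, NaS, Iinj)` set, runs a long constant
#' injection and classifies the activity as `silent`, `tonic`, `bursting`
#' or `premature_then_silent`, with burst statistics where bursting.
#' Parameter sets without a stable rest are started from the cold-start
#' state instead (they are typically endogenous bursters).
#'
#' @param param_sets data frame with columns `Ipumpmax`, `NaH`, `NaS`,
#'   `Iinj`
#' @param duration record duration (s)
#' @param model base [neuron_model()] or preset name
#' @param options a [solver_options()]
#' @return data frame with the classification and burst metrics per set
#' @export
run_burst_survey <- function(param_sets, duration = 50, model = "DynDyn",
                             options = solver_options()) {
  base <- .as_model(model)
  dur_ms <- 1000 * duration
  rows <- lapply(seq_len(nrow(param_sets)), function(i) {
    ps <- param_sets[i, ]
    m <- neuron_model(base$variant, membrane = base$membrane,
                      pump = pump_parameters(ps$Ipumpmax, ps$NaH, ps$NaS),
                      env = base$env)
    rest <- find_rest(m, options = options)
    init <- if (rest$converged) rest$state else
      neuron_state(-60, Na_in = m$env$Na_rest)
    stim <- step_stimulus(ps$Iinj, 0, dur_ms)
    tr <- integrate_model(m, stim, dur_ms, init = init, options = options)
    train <- detect_spikes(tr)
    b <- burst_segmentation(train, dur_ms)
    cls <- if (b$bursting) "bursting"
      else if (length(train$times) == 0) "silent"
      else if (max(train$times) < 0.8 * dur_ms) "premature_then_silent"
      else "tonic"
    data.frame(Ipumpmax = ps$Ipumpmax, NaH = ps$NaH, NaS = ps$NaS,
               Iinj = ps$Iinj, stable_rest = rest$converged,
               classification = cls, n_spikes = length(train$times),
               period_s = b$period, burst_duration_s = b$burst_duration,
               duty_cycle = b$duty_cycle)
  })
  do.call(rbind, rows)
}

.as_model <- function(model) {
  if (is.character(model)) neuron_model(model) else model
}
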