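# Spike detection and the excitability / AHP / bursting descriptors.

#' Detect spikes in a voltage trace
#'
#' A spike time is the linearly interpolated upward crossing of `threshold`.
#' Crossings closer together than the refractory period are merged (the
#' first one is kept). Model spikes overshoot about 0 mV while subthreshold
#' dynamics stay below about -40 mV, so counts are insensitive to the
#' threshold over a wide band.
#'
#' @param trace a `simulation_trace`, or any data frame with columns `t`
#'   (ms) and `V` (mV)
#' @param threshold detection threshold (mV)
#' @param refractory minimal inter-spike separation (ms)
#' @return an object of class `spike_train`: list with `times` (ms,
#'   strictly increasing; possibly empty), `threshold`, `refractory`
#' @export
detect_spikes <- function(trace, threshold = -20, refractory = 2) {
  stopifnot(is.data.frame(trace), nrow(trace) > 0,
            all(c("t", "V") %in% names(trace)))
  t <- trace$t; V <- trace$V
  i <- which(V[-length(V)] < threshold & V[-1L] >= threshold)
  times <- t[i] + (threshold - V[i]) / (V[i + 1L] - V[i]) * (t[i + 1L] - t[i])
  if (length(times) > 1) {
    keep <- c(TRUE, diff(times) > refractory)
    # merge chains: re-scan until stable (rarely more than one pass)
    while (any(!keep)) {
      times <- times[keep]
      keep <- c(TRUE, diff(times) > refractory)
    }
  }
  spike_train(times, threshold = threshold, refractory = refractory)
}

#' Construct a spike train
#'
#' @param times spike times (ms), strictly increasing
#' @param threshold,refractory detection settings used (recorded only)
#' @return an object of class `spike_train`
#' @export
spike_train <- function(times, threshold = NA_real_, refractory = 0) {
  times <- as.numeric(times)
  if (is.unsorted(times, strictly = TRUE))
    stop("spike times must be strictly increasing")
  if (length(times) > 1 && refractory > 0 &&
      any(diff(times) <= refractory))
    stop("inter-spike intervals must exceed the refractory period")
  structure(list(times = times, threshold = threshold,
                 refractory = refractory),
            class = "spike_train")
}

#' @export
print.spike_train <- function(x, ...) {
  cat("<spike_train>", length(x$times), "spikes")
  if (length(x$times) > 0)
    cat(sprintf(", t in [%.3f, %.3f] ms", min(x$times), max(x$times)))
  cat("\n")
  invisible(x)
}

#' Instantaneous firing rate series
#'
#' One IFR value per inter-spike interval: `IFR_k = 1000 / ISI_k` Hz,
#' timestamped at the later spike of the pair (the causal reading used for
#' IFR-vs-time plots and the adaptation slope).
#'
#' @param train a [spike_train()] or numeric vector of spike times (ms)
#' @return data frame with columns `t` (ms) and `ifr` (Hz); zero rows if
#'   fewer than two spikes
#' @export
ifr_series <- function(train) {
  times <- .spike_times(train)
  if (length(times) < 2)
    return(data.frame(t = numeric(0), ifr = numeric(0)))
  data.frame(t = times[-1L], ifr = 1000 / diff(times))
}

#' Spike-rate adaptation slope
#'
#' The late-time slope of the IFR profile: take the last 19 IFR values,
#' drop the very last (its final spike may be truncated by the stimulus
#' offset), split the remaining 18 into two consecutive groups of 9, and
#' divide the difference of the group means by the time between the middle
#' (5th) spikes of each group. Units Hz/s. Invariant under uniform time
#' translation of the train.
#'
#' @param ifr an IFR series from [ifr_series()], a [spike_train()], or a
#'   numeric vector of spike times (ms)
#' @return slope in Hz/s, or `NA` with attribute `status = "undefined"`
#'   when fewer than 19 IFR values (20 spikes) are available
#' @export
adaptation_slope <- function(ifr) {
  if (!is.data.frame(ifr)) ifr <- ifr_series(ifr)
  n <- nrow(ifr)
  if (n < 19)
    return(structure(NA_real_, status = "undefined"))
  f <- ifr$ifr[(n - 18):n]
  tt <- ifr$t[(n - 18):n]
  g1 <- f[1:9]; g2 <- f[10:18]          # the 19th value is left off
  dt_s <- (tt[14] - tt[5]) / 1000        # middle spikes of each group
  (mean(g2) - mean(g1)) / dt_s
}

#' Afterhyperpolarization amplitude and half duration
#'
#' `AHPamp` is the minimum voltage after the end of the injection minus the
#' pre-injection baseline voltage (negative for a genuine AHP). `T_half` is
#' the time from the injection end to the first post-trough instant at
#' which the voltage has recovered to half the AHP amplitude. Both depend
#' only on voltage differences, so they are invariant under a constant
#' offset of the whole trace.
#'
#' @param trace a `simulation_trace` (or data frame with `t`, `V`)
#' @param injection_end stimulus offset time (ms)
#' @param baseline_V pre-injection voltage (mV); defaults to the first
#'   sample of the trace
#' @param min_amp minimal depth (mV) below baseline for a deflection to
#'   count as an AHP
#' @return list with `AHPamp` (mV, `NA` if no AHP), `T_half` (s, `NA` if no
#'   AHP or unrecovered), and `status` (`"ok"`, `"no AHP"`, or
#'   `"unrecovered"`)
#' @export
ahp_metrics <- function(trace, injection_end, baseline_V = trace$V[1L],
                        min_amp = 0.05) {
  stopifnot(is.data.frame(trace), all(c("t", "V") %in% names(trace)))
  post <- trace$t > injection_end
  if (!any(post)) stop("trace does not extend past injection_end")
  tp <- trace$t[post]; Vp <- trace$V[post]
  i_min <- which.min(Vp)
  amp <- Vp[i_min] - baseline_V
  if (amp >= -min_amp)
    return(list(AHPamp = NA_real_, T_half = NA_real_, status = "no AHP"))
  rec <- which(Vp[i_min:length(Vp)] >= baseline_V + amp / 2)
  if (length(rec) == 0) {
    warning("AHP has not recovered to half amplitude within the trace")
    return(list(AHPamp = amp, T_half = NA_real_, status = "unrecovered"))
  }
  list(AHPamp = amp,
       T_half = (tp[i_min + rec[1L] - 1L] - injection_end) / 1000,
       status = "ok")
}

#' Classify a step-current response
#'
#' `subthreshold` if no spikes occur in the injection window;
#' `depolarization_block` if the voltage stays above `block_V` without
#' spiking for more than `block_ms` contiguous milliseconds during the
#' injection; `premature_termination` if the gap from the last spike to the
#' injection end exceeds `max(500 ms, 3 x last ISI)`; otherwise
#' `sustained`.
#'
#' @param train a [spike_train()] (spikes within the injection window)
#' @param trace a `simulation_trace` covering the injection window
#' @param onset,offset injection window (ms)
#' @param block_V,block_ms depolarization-block criterion
#' @return one of `"subthreshold"`, `"sustained"`,
#'   `"premature_termination"`, `"depolarization_block"`
#' @export
classify_step_response <- function(train, trace, onset, offset,
                                   block_V = -30, block_ms = 200) {
  times <- .spike_times(train)
  times <- times[times >= onset & times <= offset]
  win <- trace$t >= onset & trace$t <= offset
  tw <- trace$t[win]; Vw <- trace$V[win]
  if (length(times) == 0) {
    if (.longest_high_run(tw, Vw, block_V) > block_ms)
      return("depolarization_block")
    return("subthreshold")
  }
  # spike-free sub-windows that sit continuously above block_V
  gaps <- cbind(c(onset, times), c(times, offset))
  for (g in seq_len(nrow(gaps))) {
    sel <- tw > gaps[g, 1] & tw < gaps[g, 2]
    if (sum(sel) > 1 && .longest_high_run(tw[sel], Vw[sel], block_V) > block_ms)
      return("depolarization_block")
  }
  last_isi <- if (length(times) > 1) diff(utils::tail(times, 2)) else 0
  if ((offset - times[length(times)]) > max(500, 3 * last_isi))
    return("premature_termination")
  "sustained"
}

.longest_high_run <- function(t, V, v_thr) {
  if (length(t) < 2) return(0)
  high <- V > v_thr
  r <- rle(high)
  if (!any(r$values)) return(0)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  max(t[ends[r$values]] - t[starts[r$values]])
}

#' Burst segmentation and burst statistics
#'
#' Discards the first `transient_frac` of the record, splits the remaining
#' spikes into bursts at inter-spike intervals exceeding `gap_factor` times
#' the median ISI, and summarises period (mean inter-burst-onset interval),
#' burst duration (mean first-to-last-spike time within complete bursts)
#' and duty cycle (duration / period).
#'
#' @param train a [spike_train()] or numeric spike times (ms)
#' @param record_duration total record length (ms), for the transient cut
#' @param gap_factor burst-boundary criterion (multiple of the median ISI)
#' @param transient_frac initial fraction of the record to discard
#' @param min_cycles minimal number of burst onsets required
#' @return list with `bursting` (logical), `period` (s), `burst_duration`
#'   (s), `duty_cycle`, `n_cycles_used`, and `status`
#' @export
burst_segmentation <- function(train, record_duration,
                               gap_factor = 5, transient_frac = 0.2,
                               min_cycles = 3) {
  times <- .spike_times(train)
  times <- times[times >= transient_frac * record_duration]
  not_bursting <- list(bursting = FALSE, period = NA_real_,
                       burst_duration = NA_real_, duty_cycle = NA_real_,
                       n_cycles_used = 0L, status = "not bursting")
  if (length(times) < 4) return(not_bursting)
  isi <- diff(times)
  gap <- isi > gap_factor * stats::median(isi)
  if (!any(gap)) return(not_bursting)
  onset_idx <- c(1L, which(gap) + 1L)
  end_idx <- c(which(gap), length(times))
  onsets <- times[onset_idx]
  if (length(onsets) < min_cycles) return(not_bursting)
  period <- mean(diff(onsets)) / 1000
  # duration over complete bursts (those terminated by a gap)
  complete <- seq_len(length(onset_idx) - 1L)
  dur <- mean(times[end_idx[complete]] - times[onset_idx[complete]]) / 1000
  list(bursting = TRUE, period = period, burst_duration = dur,
       duty_cycle = dur / period,
       n_cycles_used = length(onsets), status = "bursting")
}

#' Time to first spike after a pulse onset
#'
#' @param train a [spike_train()] or numeric spike times (ms)
#' @param pulse_onset pulse onset (ms)
#' @param window optional window length (ms): only spikes before
#'   `pulse_onset + window` qualify
#' @return latency (ms), or `NA` with attribute `status = "no spike"`
#' @export
time_to_first_spike <- function(train, pulse_onset, window = Inf) {
  times <- .spike_times(train)
  times <- times[times >= pulse_onset & times < pulse_onset + window]
  if (length(times) == 0)
    return(structure(NA_real_, status = "no spike"))
  times[1L] - pulse_onset
}

#' Summarise a step response
#'
#' Bundles the step descriptors of a simulated response: initial/final IFR,
#' adaptation slope, AHP amplitude and half-duration, spike count and
#' response classification.
#'
#' @param trace a `simulation_trace` covering the step and its tail
#' @param onset,offset injection window (ms)
#' @param threshold,refractory spike detection settings
#' @param ahp compute AHP metrics (needs a long post-stimulus tail)
#' @return list of metrics (class `step_response_metrics`)
#' @export
step_response_metrics <- function(trace, onset, offset, threshold = -20,
                                  refractory = 2, ahp = TRUE) {
  train <- detect_spikes(trace, threshold, refractory)
  in_win <- train$times[train$times >= onset & train$times <= offset]
  ifr <- ifr_series(spike_train(in_win))
  cls <- classify_step_response(spike_train(in_win), trace, onset, offset)
  res <- list(
    n_spikes = length(in_win),
    IFR_ini = if (nrow(ifr) > 0) ifr$ifr[1L] else NA_real_,
    IFR_fin = if (nrow(ifr) > 0) ifr$ifr[nrow(ifr)] else NA_real_,
    s_adapt = adaptation_slope(ifr),
    classification = cls
  )
  if (ahp) {
    baseline_i <- max(which(trace$t <= onset))
    a <- ahp_metrics(trace, offset, baseline_V = trace$V[baseline_i])
    res$AHPamp <- a$AHPamp
    res$T_half <- a$T_half
    res$ahp_status <- a$status
  }
  structure(res, class = "step_response_metrics")
}

.spike_times <- function(train) {
  if (inherits(train, "spike_train")) train$times
  else if (is.numeric(train)) as.numeric(train)
  else stop("expected a spike_train or numeric spike times")
}
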