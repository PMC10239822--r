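# Synthetic fixtures with known ground-truth metrics, used to validate the
# analysis functions without running any simulation.

#' Synthetic spike trains
#'
#' Parameterised generators whose descriptors are known by construction:
#' \describe{
#'   \item{`constant`}{spikes at a fixed ISI (`rate_hz`); adaptation slope 0.}
#'   \item{`linear_ifr`}{a train whose IFR profile, read at the later spike
#'     of each interval, decreases linearly from `ifr_start` at slope
#'     `slope_hz_per_s` (Hz/s); built by stepping the ISI recursion
#'     `t_{k+1} = t_k + 1000 / ifr(t_{k+1})`, which is solved per interval.}
#'   \item{`bursting`}{`n_per_burst` spikes at `intra_isi` ms ISI, bursts
#'     repeated every `period` ms for `n_bursts` bursts; period, duration
#'     and duty cycle are exact.}
#' }
#'
#' @param kind one of `"constant"`, `"linear_ifr"`, `"bursting"`
#' @param n number of spikes (constant / linear_ifr)
#' @param rate_hz firing rate (constant)
#' @param ifr_start,slope_hz_per_s IFR profile (linear_ifr); slope is
#'   usually negative and must keep the IFR positive over the train
#' @param t0 time of the first spike (ms)
#' @param n_per_burst,intra_isi,period,n_bursts burst layout (bursting)
#' @return a [spike_train()]
#' @export
synthetic_spike_train <- function(kind = c("constant", "linear_ifr",
                                           "bursting"),
                                  n = 30, rate_hz = 20,
                                  ifr_start = 50, slope_hz_per_s = -1,
                                  t0 = 0,
                                  n_per_burst = 5, intra_isi = 100,
                                  period = 2000, n_bursts = 5) {
  kind <- match.arg(kind)
  times <- switch(kind,
    constant = t0 + (seq_len(n) - 1L) * 1000 / rate_hz,
    linear_ifr = {
      stopifnot(ifr_start > 0)
      tt <- numeric(n)
      tt[1L] <- t0
      for (k in seq_len(n - 1L)) {
        # solve t_next = t_k + 1000/ifr(t_next) with ifr linear in time
        a <- ifr_start + slope_hz_per_s * (tt[k] - t0) / 1000
        b <- slope_hz_per_s / 1000
        # b*d^2 + a*d - 1000 = 0 for the interval d
        d <- if (abs(b) < 1e-12) 1000 / a
             else (-a + sqrt(a^2 + 4 * b * 1000)) / (2 * b)
        if (!is.finite(d) || d <= 0)
          stop("IFR profile reaches zero within the requested train")
        tt[k + 1L] <- tt[k] + d
      }
      tt
    },
    bursting = {
      burst <- (seq_len(n_per_burst) - 1L) * intra_isi
      as.vector(outer(burst, t0 + (seq_len(n_bursts) - 1L) * period, "+"))
    })
  spike_train(sort(times))
}

#' Synthetic voltage trace with rest, spikes and an exponential AHP
#'
#' A resting baseline, optional stylised spikes during the injection
#' window, and a post-injection afterhyperpolarization of exact amplitude
#' `ahp_amp` decaying exponentially with time constant `ahp_tau`, so that
#' the AHP metrics are known in closed form (`T_half = ahp_tau * ln 2`).
#'
#' @param baseline resting potential (mV)
#' @param onset,offset injection window (ms)
#' @param duration total trace duration (ms)
#' @param dt sample interval (ms)
#' @param spike_times times of stylised spikes (ms); each is a brief
#'   triangular excursion to `spike_peak`
#' @param spike_peak spike peak (mV)
#' @param ahp_amp AHP amplitude (mV, negative for a hyperpolarization)
#' @param ahp_tau AHP decay time constant (ms)
#' @return a data frame with `t`, `V` usable by all metric functions
#' @export
synthetic_ahp_trace <- function(baseline = -60, onset = 1000, offset = 6000,
                                duration = 60000, dt = 0.5,
                                spike_times = seq(onset + 10, offset - 10,
                                                  by = 50),
                                spike_peak = 0, ahp_amp = -3.9,
                                ahp_tau = 5000) {
  t <- seq(0, duration, by = dt)
  V <- rep(baseline, length(t))
  post <- t > offset
  # decay is anchored at the first post-offset sample so that the sampled
  # trough equals baseline + ahp_amp exactly
  t_trough <- min(t[post])
  V[post] <- baseline + ahp_amp * exp(-(t[post] - t_trough) / ahp_tau)
  for (ts in spike_times) {
    sel <- abs(t - ts) <= 1
    V[sel] <- pmax(V[sel], spike_peak - abs(t[sel] - ts) *
                     (spike_peak - baseline))
  }
  data.frame(t = t, V = V)
}

#' Dispatcher over the synthetic fixture generators
#'
#' @param kind fixture kind: a spike-train kind (see
#'   [synthetic_spike_train()]) or `"ahp_trace"`
#' @param ... passed to the underlying generator
#' @return a [spike_train()] or a trace data frame
#' @export
make_synthetic_fixture <- function(kind, ...) {
  if (kind == "ahp_trace") synthetic_ahp_trace(...)
  else synthetic_spike_train(kind, ...)
}
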