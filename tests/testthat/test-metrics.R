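# Spike detection and the derived excitability descriptors, validated on
# synthetic fixtures with known ground truth.

test_that("spike detection counts threshold crossings and interpolates", {
  tr <- synthetic_ahp_trace(spike_times = seq(1100, 1400, by = 50),
                            offset = 1500, duration = 3000, ahp_amp = 0)
  train <- detect_spikes(tr)
  expect_length(train$times, 7)
  # interpolated times sit within one sample of the construction times
  expect_lt(max(abs(train$times - seq(1100, 1400, by = 50))), 1)
})

test_that("a subthreshold sinusoid produces no spikes", {
  t <- seq(0, 2000, by = 0.5)
  tr <- data.frame(t = t, V = -60 + 15 * sin(2 * pi * t / 500))
  expect_length(detect_spikes(tr)$times, 0)
})

test_that("crossings inside the refractory window are merged", {
  t <- seq(0, 20, by = 0.1)
  V <- rep(-60, length(t))
  near <- function(x) abs(t - x) < 0.01
  V[near(5) | near(5.5) | near(6)] <- 0  # three crossings within 2 ms
  tr <- data.frame(t = t, V = V)
  expect_length(detect_spikes(tr)$times, 1)
})

test_that("IFR series has one entry per interval, stamped at the later spike", {
  st <- synthetic_spike_train("constant", n = 5, rate_hz = 20)
  ifr <- ifr_series(st)
  expect_equal(nrow(ifr), 4)
  expect_equal(ifr$t, st$times[-1])
  expect_equal(ifr$ifr, rep(20, 4))
})

test_that("adaptation slope is zero for constant-rate trains", {
  st <- synthetic_spike_train("constant", n = 30, rate_hz = 20)
  expect_equal(adaptation_slope(st), 0)
})

test_that("adaptation slope recovers a constructed linear IFR decay", {
  st <- synthetic_spike_train("linear_ifr", n = 40, ifr_start = 50,
                              slope_hz_per_s = -1)
  expect_equal(adaptation_slope(st), -1, tolerance = 0.01)
  st2 <- synthetic_spike_train("linear_ifr", n = 60, ifr_start = 80,
                               slope_hz_per_s = -10)
  expect_equal(adaptation_slope(st2), -10, tolerance = 0.01)
})

test_that("adaptation slope is undefined below 19 IFR values", {
  st <- synthetic_spike_train("constant", n = 19, rate_hz = 20)  # 18 IFRs
  s <- adaptation_slope(st)
  expect_true(is.na(s))
  expect_identical(attr(s, "status"), "undefined")
  expect_false(is.na(adaptation_slope(
    synthetic_spike_train("constant", n = 20, rate_hz = 20))))
})

test_that("adaptation slope is invariant under time translation", {
  st <- synthetic_spike_train("linear_ifr", n = 40, ifr_start = 50,
                              slope_hz_per_s = -2)
  shifted <- spike_train(st$times + 1234.5)
  expect_equal(adaptation_slope(st), adaptation_slope(shifted),
               tolerance = 1e-12)
})

test_that("AHP metrics recover constructed amplitude and half time", {
  tr <- synthetic_ahp_trace(baseline = -60, offset = 6000, ahp_amp = -3.9,
                            ahp_tau = 5000, spike_times = numeric(0))
  a <- ahp_metrics(tr, 6000)
  expect_equal(a$AHPamp, -3.9, tolerance = 1e-6)
  expect_equal(a$T_half, 5 * log(2), tolerance = 0.01)
  expect_identical(a$status, "ok")
})

test_that("AHP metrics are invariant under a constant voltage offset", {
  tr <- synthetic_ahp_trace(baseline = -60, offset = 6000, ahp_amp = -2.5,
                            spike_times = numeric(0))
  tr2 <- tr; tr2$V <- tr2$V + 12.3
  a1 <- ahp_metrics(tr, 6000); a2 <- ahp_metrics(tr2, 6000)
  expect_equal(a1$AHPamp, a2$AHPamp, tolerance = 1e-12)
  expect_equal(a1$T_half, a2$T_half, tolerance = 1e-12)
})

test_that("a flat post-stimulus trace reports no AHP", {
  tr <- synthetic_ahp_trace(ahp_amp = 0, spike_times = numeric(0))
  expect_identical(ahp_metrics(tr, 6000)$status, "no AHP")
})

test_that("an unrecovered AHP yields a warning and undefined half time", {
  tr <- synthetic_ahp_trace(ahp_amp = -4, ahp_tau = 1e6, duration = 20000,
                            spike_times = numeric(0))
  expect_warning(a <- ahp_metrics(tr, 6000), "recovered")
  expect_identical(a$status, "unrecovered")
  expect_true(is.na(a$T_half))
})

test_that("step response classification covers the trivial cases", {
  t <- seq(0, 6000, by = 1)
  flat <- data.frame(t = t, V = rep(-60, length(t)))
  expect_identical(
    classify_step_response(spike_train(numeric(0)), flat, 0, 5000),
    "subthreshold")
  blocked <- data.frame(t = t, V = ifelse(t > 500 & t < 5000, -25, -60))
  expect_identical(
    classify_step_response(spike_train(numeric(0)), blocked, 0, 5000),
    "depolarization_block")
  sustained <- spike_train(seq(100, 4950, by = 50))
  expect_identical(classify_step_response(sustained, flat, 0, 5000),
                   "sustained")
  premature <- spike_train(seq(100, 2500, by = 50))
  expect_identical(classify_step_response(premature, flat, 0, 5000),
                   "premature_termination")
})

test_that("burst segmentation round-trips a constructed burst train", {
  st <- synthetic_spike_train("bursting", n_per_burst = 5, intra_isi = 100,
                              period = 2000, n_bursts = 10)
  b <- burst_segmentation(st, record_duration = 20000)
  expect_true(b$bursting)
  expect_equal(b$period, 2.0, tolerance = 1e-9)
  expect_equal(b$burst_duration, 0.4, tolerance = 1e-9)
  expect_equal(b$duty_cycle, 0.2, tolerance = 1e-9)
  expect_equal(b$duty_cycle, b$burst_duration / b$period)
})

test_that("tonic trains and too-few cycles are not bursting", {
  tonic <- synthetic_spike_train("constant", n = 100, rate_hz = 20)
  expect_false(burst_segmentation(tonic, 5000)$bursting)
  two <- synthetic_spike_train("bursting", n_bursts = 2)
  expect_false(burst_segmentation(two, 4000)$bursting)
})

test_that("burst boundaries are insensitive to the gap factor over a band", {
  st <- synthetic_spike_train("bursting", n_per_burst = 8, intra_isi = 80,
                              period = 3000, n_bursts = 8)
  for (gf in c(3, 5, 8)) {
    b <- burst_segmentation(st, 24000, gap_factor = gf)
    expect_equal(b$period, 3.0, tolerance = 1e-9)
  }
})

test_that("time to first spike measures latency and reports absence", {
  st <- spike_train(c(1012, 1050, 1100))
  expect_equal(time_to_first_spike(st, 1000), 12)
  none <- time_to_first_spike(st, 2000)
  expect_true(is.na(none))
  expect_identical(attr(none, "status"), "no spike")
})

test_that("spike detection on a simulated step is threshold-insensitive", {
  tr <- step_run("DynDyn", 50, tail = 200)$trace
  n20 <- length(detect_spikes(tr, threshold = -20)$times)
  n0 <- length(detect_spikes(tr, threshold = -5)$times)
  expect_identical(n20, n0)
  expect_gt(n20, 100)
})

test_that("spike counts are stable under output-grid refinement", {
  r <- rest_of("DynDyn")
  stim <- step_stimulus(50, 0, 1000, total = 1000)
  co <- integrate_model(dyn_dyn_model(), stim, 1000, init = r$state,
                        options = solver_options(output_dt = 0.05))
  fi <- integrate_model(dyn_dyn_model(), stim, 1000, init = r$state,
                        options = solver_options(output_dt = 0.01))
  expect_identical(length(detect_spikes(co)$times),
                   length(detect_spikes(fi)$times))
})
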