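# Gating kinetics, pump current, Nernst reversal, membrane currents and
# the state derivative.

test_that("gating steady states hit their printed half-activation points", {
  expect_equal(unname(gating_kinetics(-48.77)$x_inf[1, "mNaP"]), 0.5)
  expect_equal(unname(gating_kinetics(-29.13)$x_inf[1, "mNaT"]), 0.5)
  expect_equal(unname(gating_kinetics(-40.0)$x_inf[1, "hNaT"]), 0.5)
})

test_that("fixed time constants are 1 ms (mNaP) and 116 ms (hKf2) at any V", {
  for (V in c(-100, -60, 0, 50)) {
    tau <- gating_kinetics(V)$tau
    expect_identical(unname(tau[1, "mNaP"]), 1.0)
    expect_identical(unname(tau[1, "hKf2"]), 116.0)
  }
})

test_that("gating curves are monotone and time constants positive on a dense grid", {
  V <- seq(-100, 50, by = 0.25)
  gk <- gating_kinetics(V)
  expect_true(all(gk$tau > 0))
  expect_true(all(gk$x_inf >= 0 & gk$x_inf <= 1))
  signs <- c(mNaT = 1, hNaT = -1, mNaP = 1, mKf = 1, hKf1 = -1, hKf2 = -1,
             nKs = 1)
  for (g in colnames(gk$x_inf)) {
    x <- gk$x_inf[, g]
    d <- diff(x) * signs[[g]]
    expect_true(all(d >= 0), info = paste("monotonicity of", g))
    # strict away from the floating-point saturation of the sigmoid tails
    interior <- x[-1] > 1e-10 & x[-1] < 1 - 1e-10 &
      x[-length(x)] > 1e-10 & x[-length(x)] < 1 - 1e-10
    expect_true(all(d[interior] > 0),
                info = paste("strict monotonicity of", g))
  }
})

test_that("gating kinetics reject non-finite input", {
  expect_error(gating_kinetics(NaN))
  expect_error(gating_kinetics(Inf))
})

test_that("pump current half-activates at NaH and saturates at Ipumpmax", {
  p <- pump_parameters()
  expect_equal(pump_current(40, p), 37.5)
  expect_equal(pump_current(1e6, p), p$Ipumpmax, tolerance = 1e-12)
  # direct evaluation at the resting concentration (frozen scalar oracle)
  expect_equal(pump_current(40.08, p), 37.64999920000512, tolerance = 1e-12)
  expect_error(pump_current(0, p))
  expect_error(pump_current(-5, p))
})

test_that("pump current is strictly increasing and bounded", {
  p <- pump_parameters()
  na <- seq(0.5, 200, by = 0.5)
  ip <- pump_current(na, p)
  expect_true(all(diff(ip) > 0))
  expect_true(all(ip > 0 & ip < p$Ipumpmax))
})

test_that("sodium Nernst potential matches its closed forms", {
  env <- sodium_environment()
  expect_equal(nernst_sodium(135, env), 0)
  expect_equal(nernst_sodium(40.08, env), 31.2, tolerance = 0.05 / 31.2)
  # halving the concentration raises the reversal by (RT/F) ln 2
  expect_equal(nernst_sodium(20, env) - nernst_sodium(40, env),
               17.80873880152564, tolerance = 1e-12)
  na <- seq(1, 200, by = 1)
  expect_true(all(diff(nernst_sodium(na, env)) < 0))
  expect_error(nernst_sodium(0, env))
})

test_that("environment consistency check rejects an inconsistent ENa_rest", {
  expect_error(sodium_environment(ENa_rest = 30.0), "inconsistent")
  expect_silent(sodium_environment())
})

test_that("membrane currents vanish at their reversal potentials", {
  m <- neuron_model("DynDyn")
  ena <- nernst_sodium(40.08, m$env)
  s <- neuron_state(ena, resting_gating(ena), 40.08)
  cur <- membrane_currents(s, m)
  expect_equal(cur$INaT, 0)
  expect_equal(cur$INaP, 0)
  expect_equal(cur$INaleak, 0)
  s2 <- neuron_state(-80, resting_gating(-80), 40.08)
  cur2 <- membrane_currents(s2, m)
  expect_equal(cur2$IKf, 0)
  expect_equal(cur2$IKs, 0)
  expect_equal(cur2$IKleak, 0)
})

test_that("currents near rest match hand-evaluated values", {
  m <- neuron_model("DynDyn")
  s <- neuron_state(-60, resting_gating(-60), 40.08)
  cur <- membrane_currents(s, m)
  expect_equal(cur$INaleak, -109.4411992, tolerance = 1e-6)
  expect_equal(cur$Ipump, 37.6499992, tolerance = 1e-6)
  expect_true(cur$Ipump > 0 && cur$Ipump < m$pump$Ipumpmax)
})

test_that("the pump is about half activated at the resting concentration", {
  m <- neuron_model("DynDyn")
  frac <- pump_current(m$env$Na_rest, m$pump) / m$pump$Ipumpmax
  expect_gt(frac, 0.49)
  expect_lt(frac, 0.53)
})

test_that("effective reversal follows the variant switches", {
  s <- neuron_state(-55, resting_gating(-55), 30)
  dyn <- membrane_currents(s, neuron_model("DynDyn"))
  con <- membrane_currents(s, neuron_model("DynCon"))
  expect_equal(dyn$ENa_effective, nernst_sodium(30))
  expect_equal(con$ENa_effective, 31.2)
})

test_that("frozen-sodium variants have identically zero sodium derivative", {
  m <- neuron_model("ConCon")
  for (V in c(-70, -50, -20, 10)) {
    d <- state_derivative(0, neuron_state(V, Na_in = 40.08), 37, m)
    expect_identical(d[["Na"]], 0)
  }
})

test_that("gating derivatives follow (x_inf - x)/tau", {
  m <- neuron_model("DynDyn")
  set.seed(7)
  for (i in 1:5) {
    V <- stats::runif(1, -80, 10)
    g <- stats::runif(7)
    s <- neuron_state(V, stats::setNames(g, names(resting_gating(V))), 35)
    d <- state_derivative(0, s, 0, m)
    gk <- gating_kinetics(V)
    expect_equal(unname(d[2:8]),
                 unname((gk$x_inf[1, ] - g) / gk$tau[1, ]),
                 tolerance = 1e-12)
  }
})

test_that("rest state balances both charge and sodium flux", {
  r <- rest_of("DynDyn")
  expect_true(r$converged)
  d <- state_derivative(0, r$state, 0, neuron_model("DynDyn"))
  expect_lt(max(abs(d)), 1e-9)
  cur <- membrane_currents(r$state, neuron_model("DynDyn"))
  na_flux <- cur$INaT + cur$INaP + cur$INaleak + 3 * cur$Ipump
  i_total <- cur$INaT + cur$INaP + cur$INaleak + cur$IKf + cur$IKs +
    cur$IKleak + cur$Ipump
  expect_lt(abs(na_flux), 0.5)
  expect_lt(abs(i_total), 0.5)
})

test_that("compiled and R derivatives agree on random states", {
  set.seed(42)
  for (variant in c("ConCon", "DynCon", "DynDyn")) {
    m <- neuron_model(variant)
    for (i in 1:10) {
      V <- stats::runif(1, -90, 20)
      g <- stats::runif(7)
      na <- stats::runif(1, 10, 90)
      s <- neuron_state(V, stats::setNames(g, names(resting_gating(V))), na)
      iinj <- stats::runif(1, -20, 80)
      dR <- state_derivative(0, s, iinj, m)
      stim <- c(type = 0, p1 = iinj, p2 = 0, p3 = 0, p4 = 0, t0 = -1,
                t1 = 1)
      dC <- pumpneuron:::.state_derivative_c(0, s, m, stim)
      expect_equal(unname(dC$derivative), unname(dR), tolerance = 1e-12)
    }
  }
})

test_that("the meaningless variant combination is rejected", {
  expect_error(variant_switches(FALSE, TRUE), "requires")
  expect_s3_class(variant_switches(TRUE, FALSE), "variant_switches")
  expect_identical(variant_preset("ConCon")$na_dynamic, FALSE)
  expect_identical(variant_preset("DynDyn")$ena_dynamic, TRUE)
})

test_that("parameter constructors enforce their invariants", {
  expect_error(membrane_parameters(C = 0))
  expect_error(membrane_parameters(gNaT = -1))
  expect_error(pump_parameters(Ipumpmax = 0))
  expect_error(pump_parameters(NaS = -2))
  expect_error(neuron_state(-60, Na_in = -1))
  expect_error(neuron_state(-60, gating = rep(2, 7)))
})
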