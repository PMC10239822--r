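# Numerical integration of the model ODEs.
#
# The reference integrator is deSolve's adaptive, stiffness-switching
# lsoda with the published tolerances; a fixed-step classical Runge-Kutta
# integrator on the same compiled right-hand side serves as a
# cross-validation oracle. Stimulus discontinuities are breakpoints: the
# solver is restarted at each one so step/ramp edges are resolved exactly.

# parameter vector handed to the compiled right-hand side; layout kept in
# step with src/model.c
.model_parms_vector <- function(model, stim_parms = .null_stim()) {
  mem <- model$membrane; pump <- model$pump; env <- model$env
  as.double(c(mem$C, mem$gNaT, mem$gNaP, mem$gNaleak, mem$gKf, mem$gKs,
              mem$gKleak, mem$EK,
              pump$Ipumpmax, pump$NaH, pump$NaS,
              env$Na_out, env$RTF, env$ENa_rest, env$kNa,
              as.numeric(model$variant$na_dynamic),
              as.numeric(model$variant$ena_dynamic),
              stim_parms))
}

.segment_stim_parms <- function(seg) {
  c(type = seg$type, p1 = seg$p1, p2 = seg$p2, p3 = seg$p3, p4 = seg$p4,
    t0 = seg$t0, t1 = seg$t1)
}

#' Integrate the model under a stimulus
#'
#' Runs the model from an initial state for `duration` ms under a stimulus
#' protocol, sampling the trace on a uniform grid. Integration proceeds
#' segment-by-segment between the protocol breakpoints; the sampled output
#' grid only records the solution and does not influence it.
#'
#' @param model a [neuron_model()]
#' @param stimulus a `stimulus` object, or `NULL` for no injected current
#' @param duration total simulated time (ms)
#' @param init initial [neuron_state()]; defaults to the relaxed rest state
#'   of `model`
#' @param options a [solver_options()] object
#' @param method `"lsoda"` (adaptive reference integrator) or `"rk4"`
#'   (fixed-step cross-validation oracle with step `rk4_dt`)
#' @param rk4_dt fixed step (ms) for `method = "rk4"`
#' @return a `simulation_trace`: a data frame with columns `t` (ms),
#'   `V` (mV), `Na` (mM), `ENa` (mV), `Ipump` (pA), `Iinj` (pA), plus the
#'   full gating trajectory as attribute `"gating"`, and metadata
#'   attributes `model`, `options`, `method`
#' @export
integrate_model <- function(model, stimulus = NULL, duration,
                            init = NULL, options = solver_options(),
                            method = c("lsoda", "rk4"), rk4_dt = 0.01) {
  method <- match.arg(method)
  stopifnot(inherits(model, "neuron_model"), duration > 0)
  if (is.null(init)) {
    rest <- find_rest(model, options = options)
    if (!rest$converged)
      stop("model has no stable resting state; supply `init` explicitly")
    init <- rest$state
  }
  y0 <- .as_state(init)
  if (!model$variant$na_dynamic) y0[["Na"]] <- model$env$Na_rest

  grid <- seq(0, duration, by = options$output_dt)
  bp <- if (is.null(stimulus)) c(0, duration) else
    sort(unique(c(0, stimulus$breakpoints[stimulus$breakpoints < duration],
                  duration)))

  segs <- if (is.null(stimulus)) NULL else stimulus$segments
  n_state <- length(y0)
  rows <- vector("list", length(bp) - 1L)
  gat <- vector("list", length(bp) - 1L)
  y <- y0
  for (k in seq_len(length(bp) - 1L)) {
    t0 <- bp[k]; t1 <- bp[k + 1L]
    # active stimulus segment on [t0, t1), if any
    stim_p <- .null_stim()
    if (!is.null(segs) && nrow(segs) > 0) {
      hit <- which(segs$t0 <= t0 + 1e-9 & segs$t1 >= t1 - 1e-9)
      if (length(hit) > 0)
        stim_p <- .segment_stim_parms(segs[hit[1L], ])
    }
    times <- unique(c(t0, grid[grid > t0 + 1e-9 & grid < t1 - 1e-9], t1))
    sol <- .solve_segment(y, times, model, stim_p, options, method, rk4_dt)
    y <- sol[nrow(sol), 1L + seq_len(n_state)]
    names(y) <- .state_names
    # the sample at a breakpoint belongs to the segment that starts there,
    # matching the half-open stimulus windows
    keep <- if (k == length(bp) - 1L) seq_len(nrow(sol))
            else seq_len(nrow(sol) - 1L)
    rows[[k]] <- sol[keep, c("time", "V", "Na", "ENa", "Ipump", "Iinj"),
                     drop = FALSE]
    gat[[k]] <- sol[keep, .gating_names, drop = FALSE]
  }
  out <- as.data.frame(do.call(rbind, rows))
  names(out)[1L] <- "t"
  rownames(out) <- NULL
  structure(out,
            gating = do.call(rbind, gat),
            model = model, options = options, method = method,
            class = c("simulation_trace", "data.frame"))
}

.solve_segment <- function(y, times, model, stim_p, options, method,
                           rk4_dt) {
  parms <- .model_parms_vector(model, stim_p)
  common <- list(y = y, times = times, func = "pumpneuron_derivs",
                 parms = parms, dllname = "pumpneuron",
                 initfunc = "pumpneuron_initmod", nout = 3,
                 outnames = c("ENa", "Ipump", "Iinj"))
  sol <- if (method == "lsoda") {
    do.call(deSolve::lsoda,
            c(common, list(atol = options$abs_tol, rtol = options$rel_tol,
                           hmax = options$max_step, maxsteps = 50000)))
  } else {
    do.call(deSolve::ode,
            c(common, list(method = "rk4", hini = rk4_dt)))
  }
  if (method == "lsoda") {
    istate <- attr(sol, "istate")
    if (!is.null(istate) && istate[1L] < 0)
      stop(sprintf("solver failure (istate = %d) at t = %.6g ms",
                   istate[1L], sol[nrow(sol), 1L]))
  }
  sol
}

#' Find the resting state
#'
#' Relaxes the model with no stimulus for `relax_duration` ms from a cold
#' start (gating at steady state, sodium at its reference value), then
#' polishes the endpoint with damped Newton iterations on the full
#' right-hand side and verifies that every state derivative is below
#' `residual_tol` in natural units. Pump parameter sets that oscillate
#' endogenously (no fixed point reachable by relaxation) are flagged via
#' `converged = FALSE` rather than raising an error.
#'
#' @param model a [neuron_model()]
#' @param options a [solver_options()]
#' @param relax_duration relaxation horizon (ms)
#' @param residual_tol maximal absolute state derivative at rest
#' @param V0 cold-start potential (mV)
#' @return list with `state` (a [neuron_state()]), `converged` (logical),
#'   `residual` (max absolute derivative), and `oscillating` (logical;
#'   TRUE when the relaxation tail still shows large voltage excursions)
#' @export
find_rest <- function(model, options = solver_options(),
                      relax_duration = 200e3, residual_tol = 1e-7,
                      V0 = -60) {
  y0 <- neuron_state(V0, Na_in = model$env$Na_rest)
  # coarse sampling: only the endpoint and the tail statistics are used
  opts <- options
  opts$output_dt <- 10
  opts$max_step <- 10
  tr <- integrate_model(model, NULL, relax_duration, init = y0,
                        options = opts)
  tail_sel <- tr$t > 0.75 * relax_duration
  v_span <- diff(range(tr$V[tail_sel]))
  oscillating <- v_span > 1.0
  n <- nrow(tr)
  g <- attr(tr, "gating")[n, ]
  y <- c(V = tr$V[n], g, Na = tr$Na[n])
  names(y) <- .state_names

  if (!oscillating) {
    y <- .polish_rest(y, model)
  }
  resid <- max(abs(state_derivative(0, y, 0, model)))
  converged <- !oscillating && resid < residual_tol
  state <- neuron_state(y[["V"]], y[.gating_names], y[["Na"]])
  list(state = state, converged = converged, residual = resid,
       oscillating = oscillating)
}

# damped Newton on the autonomous RHS with a finite-difference Jacobian;
# frozen-sodium variants have a structurally zero sodium derivative, so the
# iteration is restricted to the active components
.polish_rest <- function(y, model, iter = 8) {
  act <- if (model$variant$na_dynamic) 1:9 else 1:8
  f <- function(z) unname(state_derivative(0, z, 0, model))[act]
  for (it in seq_len(iter)) {
    fy <- f(y)
    if (max(abs(fy)) < 1e-13) break
    n <- length(act)
    J <- matrix(0, n, n)
    h <- pmax(1e-7, abs(y[act]) * 1e-7)
    for (j in seq_len(n)) {
      yp <- y; yp[act[j]] <- yp[act[j]] + h[j]
      J[, j] <- (f(yp) - fy) / h[j]
    }
    step <- tryCatch(solve(J, fy), error = function(e) NULL)
    if (is.null(step) || any(!is.finite(step))) break
    cand <- y
    cand[act] <- y[act] - step
    cand[2:8] <- pmin(pmax(cand[2:8], 0), 1)
    if (cand[9] <= 0) cand[9] <- y[9]
    if (max(abs(f(cand))) <= max(abs(fy))) y <- cand else break
  }
  y
}
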