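# Shared, lazily computed simulation fixtures. The heavier traces are used
# by several test files; they are computed once per test run and cached.
.sim_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .sim_cache))
    assign(key, expr, envir = .sim_cache)
  get(key, envir = .sim_cache)
}

dyn_dyn_model <- function() neuron_model("DynDyn")
dyn_con_model <- function() neuron_model("DynCon")
con_con_model <- function() neuron_model("ConCon")

rest_of <- function(name) {
  cached(paste0("rest_", name), find_rest(neuron_model(name)))
}

# 50 pA, 5 s step with a 60 s tail - the central mechanism protocol
step50 <- function(name) {
  cached(paste0("step50_", name), {
    run_step_response(neuron_model(name), 50, rest = rest_of(name))
  })
}

step_run <- function(name, amplitude, tail = 1000, ahp = FALSE) {
  cached(sprintf("step_%s_%g_%g", name, amplitude, tail), {
    run_step_response(neuron_model(name), amplitude, tail = tail,
                      rest = rest_of(name), ahp = ahp)
  })
}
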