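# Configuration schema validation, trace CSV round trips, metrics JSON.

test_that("a full configuration validates into model objects", {
  cfg <- list(
    variant = list(name = "DynCon"),
    pump = list(Ipumpmax = 100),
    stimulus = list(type = "step", amplitude = 50, duration = 5000,
                    total = 6000),
    solver = list(output_dt = 0.1))
  v <- validate_config(cfg)
  expect_identical(v$model$variant$name, "DynCon")
  expect_identical(v$model$pump$Ipumpmax, 100)
  expect_identical(v$options$output_dt, 0.1)
  expect_equal(v$duration, 6000)
})

test_that("unknown sections and keys are rejected with field messages", {
  expect_error(validate_config(list(pmup = list())), "unknown config section")
  expect_error(validate_config(list(pump = list(IpumpMax = 75))),
               "unknown key.*pump")
})

test_that("the invalid variant combination is rejected at validation", {
  cfg <- list(variant = list(na_dynamic = FALSE, ena_dynamic = TRUE),
              duration = 100)
  expect_error(validate_config(cfg), "requires")
})

test_that("physical invariants are enforced before simulation", {
  expect_error(validate_config(list(pump = list(Ipumpmax = -5),
                                    duration = 10)), "positive")
  expect_error(validate_config(list(membrane = list(C = 0),
                                    duration = 10)), "capacitance")
})

test_that("YAML configs round-trip through file reading", {
  path <- tempfile(fileext = ".yaml")
  writeLines(c("variant:", "  name: DynDyn", "stimulus:",
               "  type: step", "  amplitude: 30", "  duration: 200",
               "  total: 400", "solver:", "  output_dt: 0.5"), path)
  v <- validate_config(read_run_config(path))
  expect_identical(v$model$variant$name, "DynDyn")
  expect_equal(eval_stimulus(v$stimulus, 100), 30)
})

test_that("trace CSV write/read round-trips to 12 significant digits", {
  r <- rest_of("DynDyn")
  stim <- step_stimulus(30, 0, 100, total = 150)
  tr <- integrate_model(dyn_dyn_model(), stim, 150, init = r$state)
  path <- tempfile(fileext = ".csv")
  write_trace(tr, path)
  back <- read_trace(path)
  for (col in c("t", "V", "Na", "ENa", "Ipump", "Iinj")) {
    scale <- pmax(abs(tr[[col]]), 1e-10)
    expect_lt(max(abs(tr[[col]] - back[[col]]) / scale), 1e-12)
  }
  expect_true(any(grepl("variant: DynDyn", attr(back, "meta"))))
})

test_that("malformed and empty traces are rejected", {
  path <- tempfile(fileext = ".csv")
  writeLines(c("# meta", "wrong,header", "1,2"), path)
  expect_error(read_trace(path), "malformed")
  r <- rest_of("DynDyn")
  tr <- integrate_model(dyn_dyn_model(), NULL, 10, init = r$state)
  tr0 <- tr[0, ]
  class(tr0) <- class(tr)
  attr(tr0, "model") <- attr(tr, "model")
  expect_error(write_trace(tr0, tempfile()), "empty")
})

test_that("metrics export as a flat JSON record", {
  m <- step_run("DynDyn", 50, tail = 200)$metrics
  path <- tempfile(fileext = ".json")
  write_metrics_json(m, path)
  rec <- jsonlite::read_json(path)
  expect_true(all(c("n_spikes", "IFR_ini", "IFR_fin", "s_adapt",
                    "classification") %in% names(rec)))
  expect_identical(rec$classification, "sustained")
  expect_equal(rec$IFR_ini, m$IFR_ini, tolerance = 1e-9)
})

test_that("run_simulation_config writes the configured outputs", {
  out_csv <- tempfile(fileext = ".csv")
  out_json <- tempfile(fileext = ".json")
  cfg <- list(variant = list(name = "DynDyn"),
              stimulus = list(type = "step", amplitude = 50,
                              duration = 1500, total = 3000),
              output = list(trace_csv = out_csv, metrics_json = out_json))
  tr <- run_simulation_config(cfg)
  expect_true(file.exists(out_csv))
  expect_true(file.exists(out_json))
  rec <- jsonlite::read_json(out_json)
  expect_gt(rec$n_spikes, 10)
  expect_identical(names(read_trace(out_csv)),
                   c("t", "V", "Na", "ENa", "Ipump", "Iinj"))
})

test_that("the command-line entry point validates configs end to end", {
  cli <- system.file("cli", "pumpneuron", package = "pumpneuron")
  expect_true(nzchar(cli))
  good <- tempfile(fileext = ".yaml")
  writeLines(c("variant:", "  name: DynDyn", "duration: 10"), good)
  bad <- tempfile(fileext = ".yaml")
  writeLines(c("variant:", "  na_dynamic: false", "  ena_dynamic: true",
               "duration: 10"), bad)
  rscript <- file.path(R.home("bin"), "Rscript")
  env <- paste0("R_LIBS=", paste(.libPaths(), collapse = ":"))
  ok <- system2(rscript, c(cli, "validate-config", "--config", good),
                stdout = TRUE, stderr = TRUE, env = env)
  expect_identical(attr(ok, "status"), NULL)
  fail <- suppressWarnings(
    system2(rscript, c(cli, "validate-config", "--config", bad),
            stdout = TRUE, stderr = TRUE, env = env))
  expect_false(is.null(attr(fail, "status")))
})
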