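# Configuration schema, trace/metrics file I/O.
#
# A run configuration is a declarative YAML mapping mirroring the type
# structure of the model: variant / membrane / pump / environment /
# stimulus / solver / output. Unknown keys are rejected and all physical
# values are validated before any simulation starts.

.config_schema <- list(
  variant = c("name", "na_dynamic", "ena_dynamic"),
  membrane = c("C", "gNaT", "gNaP", "gNaleak", "gKf", "gKs", "gKleak", "EK"),
  pump = c("Ipumpmax", "NaH", "NaS"),
  environment = c("Na_out", "Vol", "temperature", "Na_rest", "ENa_rest"),
  stimulus = c("type", "amplitude", "onset", "duration", "peak",
               "up_duration", "down_duration", "f0", "fmax", "tau_half",
               "test_amp", "test_dur", "main_amp", "main_dur", "delay",
               "total"),
  solver = c("abs_tol", "rel_tol", "max_step", "output_dt"),
  output = c("trace_csv", "metrics_json"),
  duration = NULL
)

#' Read a run configuration file
#'
#' @param path path to a YAML configuration file
#' @return the raw configuration list (validate with [validate_config()])
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  yaml::read_yaml(path)
}

#' Validate a run configuration
#'
#' Checks the section and key structure against the schema and constructs
#' the validated model, stimulus and solver objects, applying every type
#' invariant (so e.g. a dynamic reversal with a frozen concentration is
#' rejected here, before any simulation).
#'
#' @param config a configuration list (from [read_run_config()] or built
#'   in code)
#' @return list with `model`, `stimulus` (may be `NULL`), `options`,
#'   `duration` (ms) and `output`
#' @export
validate_config <- function(config) {
  if (!is.list(config)) stop("config must be a mapping")
  unknown <- setdiff(names(config), names(.config_schema))
  if (length(unknown) > 0)
    stop("unknown config section(s): ", paste(unknown, collapse = ", "))
  for (sec in intersect(names(config), names(.config_schema))) {
    allowed <- .config_schema[[sec]]
    if (is.null(allowed)) next
    bad <- setdiff(names(config[[sec]]), allowed)
    if (length(bad) > 0)
      stop("unknown key(s) in section '", sec, "': ",
           paste(bad, collapse = ", "))
  }

  variant <- if (is.null(config$variant)) variant_preset("DynDyn")
    else if (!is.null(config$variant$name)) variant_preset(config$variant$name)
    else variant_switches(isTRUE(config$variant$na_dynamic),
                          isTRUE(config$variant$ena_dynamic))
  membrane <- do.call(membrane_parameters,
                      config$membrane %||% list())
  pump <- do.call(pump_parameters, config$pump %||% list())
  env <- do.call(sodium_environment, config$environment %||% list())
  model <- neuron_model(variant, membrane, pump, env)
  options <- do.call(solver_options, config$solver %||% list())

  stimulus <- NULL
  if (!is.null(config$stimulus)) {
    sc <- config$stimulus
    if (is.null(sc$type)) stop("stimulus needs a 'type'")
    args <- sc[setdiff(names(sc), "type")]
    stimulus <- switch(sc$type,
      step = do.call(step_stimulus, args),
      ramp = do.call(ramp_stimulus, args),
      zap  = do.call(zap_stimulus,
                     stats::setNames(args,
                                     sub("^amplitude$", "Izapmax",
                                         names(args)))),
      memory = do.call(memory_stimulus, args),
      stop("unknown stimulus type: ", sc$type))
  }
  duration <- config$duration %||%
    (if (!is.null(stimulus)) stimulus$duration else
       stop("config needs 'duration' when no stimulus is given"))
  list(model = model, stimulus = stimulus, options = options,
       duration = duration, output = config$output %||% list())
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run a validated configuration
#'
#' Simulates the configured model from its rest state and writes the trace
#' CSV and metrics JSON when output paths are configured.
#'
#' @param config a configuration list or a path to a YAML file
#' @return the `simulation_trace`, invisibly; metrics as attribute
#'   `"metrics"`
#' @export
run_simulation_config <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  v <- validate_config(config)
  tr <- integrate_model(v$model, v$stimulus, v$duration,
                        options = v$options)
  metrics <- NULL
  if (!is.null(v$stimulus) && nrow(v$stimulus$segments) > 0) {
    seg <- v$stimulus$segments[1L, ]
    metrics <- step_response_metrics(tr, seg$t0, seg$t1,
                                     ahp = v$duration > seg$t1 + 30000)
  }
  if (!is.null(v$output$trace_csv))
    write_trace(tr, v$output$trace_csv)
  if (!is.null(v$output$metrics_json) && !is.null(metrics))
    write_metrics_json(metrics, v$output$metrics_json)
  attr(tr, "metrics") <- metrics
  invisible(tr)
}

#' Write a simulation trace to CSV
#'
#' Columns carry their units in the header
#' (`t_ms,V_mV,Na_mM,ENa_mV,Ipump_pA,Iinj_pA`); values are written with 15
#' significant digits so a read/write round trip is lossless to at least
#' 12 digits. Metadata (variant, parameters, package version) is stored in
#' `#`-prefixed header lines.
#'
#' @param trace a `simulation_trace`
#' @param path output file path
#' @return `path`, invisibly
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "simulation_trace"))
  if (nrow(trace) == 0) stop("refusing to write an empty trace")
  model <- attr(trace, "model")
  meta <- c(
    sprintf("# pumpneuron trace v%s",
            as.character(utils::packageVersion("pumpneuron"))),
    sprintf("# variant: %s", model$variant$name),
    sprintf("# pump: Ipumpmax=%g NaH=%g NaS=%g", model$pump$Ipumpmax,
            model$pump$NaH, model$pump$NaS),
    sprintf("# membrane: C=%g gNaT=%g gNaP=%g gNaleak=%g gKf=%g gKs=%g gKleak=%g EK=%g",
            model$membrane$C, model$membrane$gNaT, model$membrane$gNaP,
            model$membrane$gNaleak, model$membrane$gKf, model$membrane$gKs,
            model$membrane$gKleak, model$membrane$EK),
    sprintf("# environment: Na_out=%g Vol=%g T=%g Na_rest=%g ENa_rest=%g",
            model$env$Na_out, model$env$Vol, model$env$temperature,
            model$env$Na_rest, model$env$ENa_rest),
    sprintf("# method: %s", attr(trace, "method") %||% "lsoda"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(meta, con)
  writeLines("t_ms,V_mV,Na_mM,ENa_mV,Ipump_pA,Iinj_pA", con)
  body <- do.call(paste, c(lapply(trace[c("t", "V", "Na", "ENa", "Ipump",
                                          "Iinj")],
                                  function(x) formatC(x, digits = 15,
                                                      format = "g")),
                           sep = ","))
  writeLines(body, con)
  invisible(path)
}

#' Read a simulation trace CSV
#'
#' @param path file written by [write_trace()]
#' @return data frame with columns `t`, `V`, `Na`, `ENa`, `Ipump`, `Iinj`;
#'   metadata lines as attribute `"meta"`
#' @export
read_trace <- function(path) {
  lines <- readLines(path)
  meta <- grep("^#", lines, value = TRUE)
  first_data <- length(meta) + 1L
  if (first_data > length(lines) ||
      !startsWith(lines[first_data], "t_ms"))
    stop("malformed trace file at line ", first_data,
         ": expected header 't_ms,...'")
  df <- utils::read.csv(text = lines[first_data:length(lines)])
  expected <- c("t_ms", "V_mV", "Na_mM", "ENa_mV", "Ipump_pA", "Iinj_pA")
  if (!identical(names(df), expected))
    stop("malformed trace file: columns ", paste(names(df), collapse = ","))
  names(df) <- c("t", "V", "Na", "ENa", "Ipump", "Iinj")
  attr(df, "meta") <- meta
  df
}

#' Write step metrics as a flat JSON record
#'
#' @param metrics a [step_response_metrics()] result (or any named list of
#'   scalars)
#' @param path output file path
#' @return `path`, invisibly
#' @export
write_metrics_json <- function(metrics, path) {
  rec <- lapply(unclass(metrics), function(x)
    if (is.numeric(x)) as.numeric(x) else x)
  jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(path)
}
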