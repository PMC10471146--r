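# Scenario configuration and study drivers: base case, age subgroups,
# tornado, PSA, CEAC, with CSV/JSON outputs and a reproducibility manifest.

#' Define an analysis scenario
#'
#' The packaged study scenarios follow the cohort from the age at diagnosis
#' to the 80-year life expectancy: ages 20/40/60 at diagnosis give 60/40/20
#' annual cycles.
#'
#' @param start_age Age at diagnosis.
#' @param n_cycles Annual cycles (default `80 - start_age`).
#' @param discount Annual discount rate (default 0.03).
#' @param params Parameter scenario name, path, or [parameter_set()]
#'   (default `"text_canonical"`).
#' @param costs Cost schedule path or [load_cost_schedule()] object
#'   (default packaged synthetic schedule).
#' @param calibrate Calibrate the cost schedule to `calibration_targets`
#'   before running (default `TRUE`). Calibration always runs on the
#'   40-year-old reference case, whatever `start_age` is, so all age
#'   subgroups share one schedule.
#' @param calibration_targets `c(es = , as = )` lifetime-cost targets in
#'   yuan (default the published base-case totals ¥53,461 / ¥74,198).
#' @param wtp Willingness-to-pay (default [wtp_threshold()]).
#' @param seed Integer seed for any randomness downstream.
#' @param label Scenario label used in file names.
#' @return An object of class `scenario`.
#' @export
scenario <- function(start_age = 40L, n_cycles = 80L - start_age,
                     discount = 0.03, params = "text_canonical",
                     costs = NULL, calibrate = TRUE,
                     calibration_targets = c(es = 53461, as = 74198),
                     wtp = wtp_threshold(), seed = 1L,
                     label = paste0("age", start_age)) {
  stopifnot(start_age + n_cycles <= 81L)
  structure(
    list(start_age = as.integer(start_age), n_cycles = as.integer(n_cycles),
         discount = discount, params = params, costs = costs,
         calibrate = calibrate, calibration_targets = calibration_targets,
         wtp = wtp, seed = as.integer(seed), label = label),
    class = "scenario"
  )
}

# Build the (optionally calibrated) model bundle for a scenario.
scenario_model <- function(sc) {
  params <- if (inherits(sc$params, "parameter_set")) sc$params else
    load_parameters(sc$params)
  costs <- if (inherits(sc$costs, "cost_schedule")) sc$costs else
    load_cost_schedule(sc$costs)
  if (isTRUE(sc$calibrate)) {
    ref_model <- ce_model(params = params, costs = costs, start_age = 40L,
                          n_cycles = 40L, discount = sc$discount)
    cal <- calibrate_costs(costs, ref_model, targets = sc$calibration_targets)
    costs <- cal$schedule
  }
  ce_model(params = params, costs = costs, start_age = sc$start_age,
           n_cycles = sc$n_cycles, discount = sc$discount)
}

#' Run one scenario
#'
#' Runs both strategies at base case and assembles a results-table row set
#' (strategy, cost, delta cost, effectiveness, delta QALY, CER, ICER), the
#' two cohort traces, and a run log (input files, checksums, seed). With
#' `out_dir`, writes `report_<label>.csv`, `trace_as_<label>.csv`,
#' `trace_es_<label>.csv` and `log_<label>.json`.
#'
#' @param sc A [scenario()].
#' @param out_dir Output directory (created if missing); `NULL` = no files.
#' @return List of class `scenario_result`: `table` (rounded report rows),
#'   `ce`, `traces`, `model`, `log`, `files`.
#' @export
run_scenario <- function(sc, out_dir = NULL) {
  stopifnot(inherits(sc, "scenario"))
  model <- scenario_model(sc)
  bc <- run_base_case(model, wtp = sc$wtp)
  tab <- ce_table(bc$ce)
  input_files <- c(
    params = if (is.character(sc$params)) load_parameters(sc$params)$meta$path
    else NA_character_,
    costs = if (is.null(sc$costs) || is.character(sc$costs))
      system.file("extdata", "costs_synthetic_default.yaml", package = "ptmcCEA")
    else NA_character_,
    strategy_as = model$strategy_as$path,
    strategy_es = model$strategy_es$path
  )
  checksums <- vapply(input_files, function(f) {
    if (is.na(f) || !file.exists(f)) NA_character_ else
      unname(tools::md5sum(f))
  }, "")
  log <- list(
    label = sc$label, start_age = sc$start_age, n_cycles = sc$n_cycles,
    discount = sc$discount, wtp = sc$wtp, seed = sc$seed,
    calibrated = isTRUE(sc$calibrate),
    calibration_targets = as.list(sc$calibration_targets),
    inputs = as.list(input_files), checksums = as.list(checksums),
    load_log = if (inherits(model$params, "parameter_set"))
      model$params$meta$load_log else character()
  )
  files <- character()
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    files <- c(
      report = file.path(out_dir, paste0("report_", sc$label, ".csv")),
      trace_as = file.path(out_dir, paste0("trace_as_", sc$label, ".csv")),
      trace_es = file.path(out_dir, paste0("trace_es_", sc$label, ".csv")),
      log = file.path(out_dir, paste0("log_", sc$label, ".json"))
    )
    utils::write.csv(tab, files[["report"]], row.names = FALSE)
    utils::write.csv(trace_df(bc$as), files[["trace_as"]], row.names = FALSE)
    utils::write.csv(trace_df(bc$es), files[["trace_es"]], row.names = FALSE)
    jsonlite::write_json(log, files[["log"]], auto_unbox = TRUE, pretty = TRUE)
  }
  structure(
    list(table = tab, ce = bc$ce, traces = list(as = bc$as, es = bc$es),
         model = model, log = log, files = files),
    class = "scenario_result"
  )
}

#' @export
print.scenario_result <- function(x, ...) {
  cat(sprintf("<scenario_result> %s (ages %d-%d)\n", x$log$label,
              x$log$start_age, x$log$start_age + x$log$n_cycles))
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Study configuration
#'
#' @param ages Ages at diagnosis for the subgroup scenarios (default
#'   `c(20, 40, 60)`; each runs to age 80).
#' @param discount Annual discount rate.
#' @param params Parameter scenario for all runs.
#' @param calibrate,calibration_targets Cost calibration settings (see
#'   [scenario()]).
#' @param psa_iterations Monte Carlo iterations (default 1000).
#' @param wtp Willingness-to-pay threshold.
#' @param seed Master seed for all randomness.
#' @return List of class `study_config`.
#' @export
study_config <- function(ages = c(20L, 40L, 60L), discount = 0.03,
                         params = "text_canonical", calibrate = TRUE,
                         calibration_targets = c(es = 53461, as = 74198),
                         psa_iterations = 1000L, wtp = wtp_threshold(),
                         seed = 1L) {
  structure(
    list(ages = as.integer(ages), discount = discount, params = params,
         calibrate = calibrate, calibration_targets = calibration_targets,
         psa_iterations = as.integer(psa_iterations), wtp = wtp,
         seed = as.integer(seed)),
    class = "study_config"
  )
}

#' Run the full study
#'
#' One-shot driver: the age-subgroup scenarios, the one-way tornado analysis
#' over all inputs, and the probabilistic sensitivity analysis with its
#' acceptability curve -- all on the 40-year-old reference case for the
#' sensitivity analyses. Writes per-scenario reports and traces,
#' `tornado.csv`, `psa_points.csv`, `ceac.csv` and a `manifest.json` listing
#' every output with its MD5 checksum.
#'
#' @param config A [study_config()].
#' @param out_dir Output directory; `NULL` = no files, results only.
#' @return List of class `study_result`: `scenarios`, `tornado`, `psa`,
#'   `manifest`.
#' @export
run_full_study <- function(config = study_config(), out_dir = NULL) {
  stopifnot(inherits(config, "study_config"))
  scenarios <- lapply(config$ages, function(a) {
    run_scenario(scenario(
      start_age = a, discount = config$discount, params = config$params,
      calibrate = config$calibrate,
      calibration_targets = config$calibration_targets, wtp = config$wtp,
      seed = config$seed), out_dir = out_dir)
  })
  names(scenarios) <- paste0("age", config$ages)

  ref_model <- if (40L %in% config$ages)
    scenarios[[paste0("age", 40L)]]$model
  else
    scenario_model(scenario(start_age = 40L, discount = config$discount,
                            params = config$params,
                            calibrate = config$calibrate,
                            calibration_targets = config$calibration_targets))
  tornado <- tornado_analysis(ref_model)
  psa <- run_psa(ref_model, n_iterations = config$psa_iterations,
                 seed = config$seed, wtp = config$wtp)

  files <- unlist(lapply(scenarios, `[[`, "files"))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    tornado_file <- file.path(out_dir, "tornado.csv")
    psa_file <- file.path(out_dir, "psa_points.csv")
    ceac_file <- file.path(out_dir, "ceac.csv")
    utils::write.csv(as.data.frame(tornado), tornado_file, row.names = FALSE)
    utils::write.csv(psa$points, psa_file, row.names = FALSE)
    utils::write.csv(psa$ceac, ceac_file, row.names = FALSE)
    files <- c(files, tornado = tornado_file, psa = psa_file,
               ceac = ceac_file)
  }
  manifest <- data.frame(
    output = names(files), file = unname(files),
    md5 = vapply(files, function(f) unname(tools::md5sum(f)), ""),
    stringsAsFactors = FALSE
  )
  if (!is.null(out_dir)) {
    manifest_file <- file.path(out_dir, "manifest.json")
    jsonlite::write_json(manifest, manifest_file, pretty = TRUE)
  }
  structure(
    list(scenarios = scenarios, tornado = tornado, psa = psa,
         manifest = manifest, config = config),
    class = "study_result"
  )
}

#' @export
print.study_result <- function(x, ...) {
  cat("<study_result>\n")
  for (s in x$scenarios) print(s)
  cat(sprintf("tornado: %d inputs; widest spread %s (%s yuan/QALY)\n",
              nrow(x$tornado), x$tornado$parameter[1L],
              fmt_yuan(x$tornado$spread[1L])))
  print(x$psa)
  invisible(x)
}
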