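# Model bundle: parameter set + both strategy graphs + cost schedule +
# scenario settings, the unit the sensitivity analyses rerun.

#' Bundle model inputs for analysis
#'
#' @param params A [parameter_set()] (or scenario name / path for
#'   [load_parameters()]).
#' @param costs A [load_cost_schedule()] schedule (or path).
#' @param strategy_as,strategy_es Strategy graphs (default: packaged).
#' @param start_age Age at diagnosis (default 40, the reference case).
#' @param n_cycles Annual cycles (default `80 - start_age`: the cohort is
#'   followed to the 80-year life expectancy).
#' @param discount Annual discount rate; default: the parameter set's (3%).
#' @param half_cycle Half-cycle correction flag passed to [run_cohort()].
#' @return An object of class `ce_model`.
#' @export
ce_model <- function(params = "text_canonical", costs = NULL,
                     strategy_as = NULL, strategy_es = NULL,
                     start_age = 40L, n_cycles = 80L - start_age,
                     discount = NULL, half_cycle = FALSE) {
  if (!inherits(params, "parameter_set")) params <- load_parameters(params)
  if (!inherits(costs, "cost_schedule")) costs <- load_cost_schedule(costs)
  if (is.null(strategy_as)) strategy_as <- load_strategy("AS")
  if (is.null(strategy_es)) strategy_es <- load_strategy("ES")
  if (is.null(discount)) discount <- params$discount
  stopifnot(start_age >= 20L, n_cycles >= 1L)
  structure(
    list(params = params, costs = costs, strategy_as = strategy_as,
         strategy_es = strategy_es, start_age = as.integer(start_age),
         n_cycles = as.integer(n_cycles), discount = discount,
         half_cycle = half_cycle),
    class = "ce_model"
  )
}

#' @export
print.ce_model <- function(x, ...) {
  cat(sprintf(
    "<ce_model> %s vs %s, ages %d-%d, discount %.1f%%, parameters '%s'\n",
    x$strategy_as$name, x$strategy_es$name, x$start_age,
    x$start_age + x$n_cycles, 100 * x$discount,
    if (is.null(x$params$meta$scenario)) "?" else x$params$meta$scenario))
  invisible(x)
}

#' Run both strategies of a model at base-case values
#'
#' @param model A [ce_model()].
#' @param wtp Willingness-to-pay for NMB columns (default [wtp_threshold()]).
#' @return List with the two [run_cohort()] traces (`as`, `es`) and the
#'   [compute_icer()] comparison `ce` (AS incremental to ES).
#' @export
run_base_case <- function(model, wtp = wtp_threshold()) {
  stopifnot(inherits(model, "ce_model"))
  tr_es <- run_cohort(model$strategy_es, model$params, model$costs,
                      model$start_age, model$n_cycles, model$discount,
                      half_cycle = model$half_cycle)
  tr_as <- run_cohort(model$strategy_as, model$params, model$costs,
                      model$start_age, model$n_cycles, model$discount,
                      half_cycle = model$half_cycle)
  list(es = tr_es, as = tr_as,
       ce = compute_icer(tr_es, tr_as, labels = c("ES", "AS"), wtp = wtp))
}
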