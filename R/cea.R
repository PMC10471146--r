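# Cost-effectiveness metrics: CER, incremental cost/effect, ICER, net
# monetary benefit, WTP threshold, dominance classification.

#' Willingness-to-pay threshold
#'
#' The conventional threshold of the Chinese pharmacoeconomic guidelines:
#' a multiple of per-capita GDP per QALY gained (2021 per-capita GDP
#' ¥80,976; three times that is ¥242,928/QALY).
#'
#' @param gdp_per_capita Per-capita GDP in yuan (default ¥80,976, 2021).
#' @param multiplier GDP multiple (default 3).
#' @return Threshold in yuan per QALY.
#' @export
wtp_threshold <- function(gdp_per_capita = 80976, multiplier = 3) {
  stopifnot(is.numeric(gdp_per_capita), gdp_per_capita > 0,
            is.numeric(multiplier), multiplier > 0)
  gdp_per_capita * multiplier
}

#' Net monetary benefit
#'
#' `NMB = wtp * effect - cost`; at a given willingness-to-pay the strategy
#' with the higher NMB is the cost-effective one.
#'
#' @param cost Cost in yuan.
#' @param effect Effect in QALYs.
#' @param wtp Willingness-to-pay in yuan/QALY.
#' @return NMB in yuan. Vectorised.
#' @export
net_monetary_benefit <- function(cost, effect, wtp) {
  wtp * effect - cost
}

as_cost_effect <- function(x, what) {
  if (inherits(x, "cohort_trace")) {
    return(c(cost = x$discounted_cost, effect = x$discounted_qaly))
  }
  if (is.numeric(x) && length(x) == 2L) {
    if (!is.null(names(x)) && all(c("cost", "effect") %in% names(x))) {
      return(x[c("cost", "effect")])
    }
    return(stats::setNames(as.numeric(x), c("cost", "effect")))
  }
  stop("`", what, "` must be a (cost, effect) pair or a cohort_trace",
       call. = FALSE)
}

#' Incremental cost-effectiveness of two strategies
#'
#' Deltas are comparator minus reference; `ICER = delta_cost / delta_effect`.
#' When the comparator is cheaper and more effective it is labelled
#' `"dominant"` (and `"dominated"` in the opposite corner), but the signed
#' ratio is still reported, matching the convention of reporting e.g. a
#' negative ¥/QALY for a dominant strategy. A zero effect difference leaves
#' the ICER undefined (`NA`, labelled). Per-strategy CERs (cost/effect) and,
#' when `wtp` is supplied, NMBs are included.
#'
#' @param reference,comparator `(cost, effect)` pairs (named or positional)
#'   or [run_cohort()] traces.
#' @param labels Strategy names, reference first (default `c("ES", "AS")`).
#' @param wtp Optional willingness-to-pay for NMB columns.
#' @return An object of class `ce_result`: list with `strategies`
#'   (per-strategy data frame), `delta_cost`, `delta_effect`, `icer`,
#'   `label`, `wtp`.
#' @export
compute_icer <- function(reference, comparator, labels = c("ES", "AS"),
                         wtp = NULL) {
  ref <- as_cost_effect(reference, "reference")
  cmp <- as_cost_effect(comparator, "comparator")
  stopifnot(all(is.finite(c(ref, cmp))))
  dc <- unname(cmp[["cost"]] - ref[["cost"]])
  de <- unname(cmp[["effect"]] - ref[["effect"]])
  icer <- if (de == 0) NA_real_ else dc / de
  label <- if (de == 0) {
    "undefined (zero effect difference)"
  } else if (dc < 0 && de > 0) {
    "dominant"
  } else if (dc > 0 && de < 0) {
    "dominated"
  } else {
    ""
  }
  cer <- function(ce) if (ce[["effect"]] == 0) NA_real_ else
    ce[["cost"]] / ce[["effect"]]
  strategies <- data.frame(
    strategy = labels,
    cost = c(ref[["cost"]], cmp[["cost"]]),
    effect = c(ref[["effect"]], cmp[["effect"]]),
    cer = c(cer(ref), cer(cmp)),
    stringsAsFactors = FALSE
  )
  if (!is.null(wtp)) {
    strategies$nmb <- net_monetary_benefit(strategies$cost,
                                           strategies$effect, wtp)
  }
  structure(
    list(strategies = strategies, delta_cost = dc, delta_effect = de,
         icer = icer, label = label, wtp = wtp),
    class = "ce_result"
  )
}

#' @export
print.ce_result <- function(x, ...) {
  cat("<ce_result>\n")
  print(ce_table(x), row.names = FALSE)
  if (nzchar(x$label)) cat("comparator is", x$label, "\n")
  if (!is.null(x$wtp)) {
    best <- x$strategies$strategy[which.max(x$strategies$nmb)]
    cat(sprintf("at WTP %s yuan/QALY, '%s' has the higher net monetary benefit\n",
                fmt_yuan(x$wtp), best))
  }
  invisible(x)
}

#' Results-table view of a `ce_result`
#'
#' Formats the comparison the way cost-effectiveness tables are printed:
#' costs, CER and ICER rounded to whole yuan, QALYs to 0.1; internal
#' arithmetic stays full precision.
#'
#' @param result A [compute_icer()] result.
#' @param rounded Round to reporting precision (default `TRUE`).
#' @return A `data.frame` with columns strategy, cost, delta_cost, effect,
#'   delta_effect, cer, icer.
#' @export
ce_table <- function(result, rounded = TRUE) {
  stopifnot(inherits(result, "ce_result"))
  s <- result$strategies
  out <- data.frame(
    strategy = s$strategy,
    cost = s$cost,
    delta_cost = c(NA, result$delta_cost),
    effect = s$effect,
    delta_effect = c(NA, result$delta_effect),
    cer = s$cer,
    icer = c(NA, result$icer),
    stringsAsFactors = FALSE
  )
  if (rounded) {
    for (col in c("cost", "delta_cost", "cer", "icer")) {
      out[[col]] <- round(out[[col]])
    }
    for (col in c("effect", "delta_effect")) {
      out[[col]] <- round(out[[col]], 1)
    }
  }
  out
}
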