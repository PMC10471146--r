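# One-way deterministic sensitivity analysis (tornado) and probabilistic
# sensitivity analysis (Monte Carlo, CE plane, CEAC).

# Rerun the model with one input pinned and return the AS-vs-ES ce_result.
pinned_ce <- function(model, name, value) {
  if (identical(name, "discount")) {
    model$discount <- value
  } else if (name %in% c(names(model$params$probabilities),
                         names(model$params$utilities))) {
    model$params <- set_param(model$params, name, value)
  } else if (name %in% names(model$costs$items)) {
    model$costs$items[[name]] <- value
  } else {
    stop("unknown model input '", name, "'", call. = FALSE)
  }
  run_base_case(model, wtp = NULL)$ce
}

# Value an input takes at base case.
input_value <- function(model, name) {
  if (identical(name, "discount")) return(model$discount)
  if (name %in% c(names(model$params$probabilities),
                  names(model$params$utilities))) {
    return(get_param(model$params, name)$point)
  }
  if (name %in% names(model$costs$items)) {
    return(unname(model$costs$items[[name]]))
  }
  stop("unknown model input '", name, "'", call. = FALSE)
}

# Default one-way range for an input: stated analysis range for parameters,
# 1%-5% for the discount rate, +/-10% for cost items.
input_range <- function(model, name, fraction = 0.10) {
  if (identical(name, "discount")) return(c(low = 0.01, high = 0.05))
  if (name %in% c(names(model$params$probabilities),
                  names(model$params$utilities))) {
    return(dsa_range(get_param(model$params, name), fraction = fraction))
  }
  v <- input_value(model, name)
  c(low = v * (1 - fraction), high = v * (1 + fraction))
}

#' One-way deterministic sensitivity analysis of a single input
#'
#' Reruns both strategies with the named input pinned at the low and high
#' end of its range (all other inputs at base case) and reports the ICER at
#' both ends. Inputs may be transition probabilities, utilities, the
#' discount rate (`"discount"`), or cost items.
#'
#' @param model A [ce_model()].
#' @param name Input name.
#' @param range `c(low, high)`; default: the stated analysis range of the
#'   parameter, 1-5% for the discount rate, point +/- 10% otherwise.
#' @param fraction Half-width used when a range must be derived.
#' @return One-row `data.frame`: parameter, low, high, icer_low, icer_high,
#'   spread (`|icer_high - icer_low|`).
#' @export
one_way_dsa <- function(model, name, range = NULL, fraction = 0.10) {
  stopifnot(inherits(model, "ce_model"))
  if (is.null(range)) range <- input_range(model, name, fraction)
  stopifnot(is.numeric(range), length(range) == 2L, range[1] <= range[2])
  ce_lo <- pinned_ce(model, name, range[[1L]])
  ce_hi <- pinned_ce(model, name, range[[2L]])
  data.frame(
    parameter = name,
    low = range[[1L]], high = range[[2L]],
    icer_low = ce_lo$icer, icer_high = ce_hi$icer,
    spread = abs(ce_hi$icer - ce_lo$icer),
    stringsAsFactors = FALSE
  )
}

#' Tornado analysis over all model inputs
#'
#' Runs [one_way_dsa()] for every transition probability and utility, the
#' discount rate, and every cost item, and sorts by ICER spread (tornado
#' order). The base-case ICER is attached as an attribute.
#'
#' @param model A [ce_model()].
#' @param parameters Inputs to vary; default: all of them.
#' @param fraction Half-width for derived ranges (default 0.10).
#' @return A `data.frame` of class `tornado`, one row per input, sorted by
#'   decreasing `spread`.
#' @export
tornado_analysis <- function(model, parameters = NULL, fraction = 0.10) {
  stopifnot(inherits(model, "ce_model"))
  if (is.null(parameters)) {
    parameters <- c(names(model$params$probabilities),
                    names(model$params$utilities),
                    "discount",
                    names(model$costs$items))
  }
  rows <- lapply(parameters, function(nm) one_way_dsa(model, nm, fraction = fraction))
  out <- do.call(rbind, rows)
  out <- out[order(-out$spread), ]
  rownames(out) <- NULL
  attr(out, "base_icer") <- run_base_case(model, wtp = NULL)$ce$icer
  class(out) <- c("tornado", class(out))
  out
}

#' Probabilistic sensitivity analysis
#'
#' Monte Carlo PSA: per iteration, every uncertain input is drawn jointly
#' and independently -- transition probabilities and utilities from beta
#' distributions parameterised by method of moments from their stated
#' mean/sd ([beta_params_from_moments()]), cost items from normal
#' distributions truncated at zero by resampling -- and both strategies are
#' rerun, recording the incremental cost and effect of AS versus ES.
#' Age-banded progression schedules carry no stated uncertainty and stay
#' fixed. Reproducible given `seed`.
#'
#' @param model A [ce_model()].
#' @param n_iterations Number of Monte Carlo iterations (default 1000).
#' @param seed Integer RNG seed.
#' @param cost_sd_fraction Cost SD as a fraction of the item value; the
#'   default `0.10 / 1.96` makes the +/-10% analysis range a 95% interval.
#' @param wtp Willingness-to-pay used for the default CEAC grid endpoint.
#' @return An object of class `psa_result`: `points` (data frame with one
#'   row per iteration: costs, effects, `delta_cost`, `delta_effect`),
#'   `ceac` (WTP grid and probability AS is cost-effective),
#'   `quadrant_fractions`, `n_iterations`, `seed`, `base` (base-case
#'   deltas).
#' @export
run_psa <- function(model, n_iterations = 1000L, seed = 1L,
                    cost_sd_fraction = 0.10 / 1.96, wtp = wtp_threshold()) {
  stopifnot(inherits(model, "ce_model"), n_iterations >= 1L)
  all_params <- c(model$params$probabilities, model$params$utilities)
  uncertain <- Filter(function(d) d$kind == "beta" && d$sd > 0, all_params)
  # parameterise every distribution up front so infeasible moments fail at
  # setup, not mid-run
  shapes <- lapply(uncertain, function(d) beta_params_from_moments(d$mean, d$sd))
  items <- model$costs$items
  draw_items <- items[items > 0]

  base <- run_base_case(model, wtp = NULL)$ce
  out <- matrix(NA_real_, n_iterations, 4L,
                dimnames = list(NULL, c("cost_es", "qaly_es", "cost_as",
                                        "qaly_as")))
  with_local_seed(seed, {
    for (it in seq_len(n_iterations)) {
      m <- model
      for (nm in names(uncertain)) {
        m$params <- set_param(m$params, nm,
                              stats::rbeta(1L, shapes[[nm]][["alpha"]],
                                           shapes[[nm]][["beta"]]))
      }
      for (nm in names(draw_items)) {
        repeat {
          v <- stats::rnorm(1L, mean = draw_items[[nm]],
                            sd = cost_sd_fraction * draw_items[[nm]])
          if (v >= 0) break
        }
        m$costs$items[[nm]] <- v
      }
      bc <- run_base_case(m, wtp = NULL)
      out[it, ] <- c(bc$es$discounted_cost, bc$es$discounted_qaly,
                     bc$as$discounted_cost, bc$as$discounted_qaly)
    }
  })
  points <- data.frame(
    iteration = seq_len(n_iterations),
    cost_es = out[, "cost_es"], qaly_es = out[, "qaly_es"],
    cost_as = out[, "cost_as"], qaly_as = out[, "qaly_as"],
    delta_cost = out[, "cost_as"] - out[, "cost_es"],
    delta_effect = out[, "qaly_as"] - out[, "qaly_es"]
  )
  grid <- seq(0, wtp, length.out = 100L)
  structure(
    list(points = points,
         ceac = ceac_curve(points, grid),
         quadrant_fractions = quadrant_fractions(points),
         n_iterations = as.integer(n_iterations), seed = as.integer(seed),
         cost_sd_fraction = cost_sd_fraction,
         base = c(delta_cost = base$delta_cost,
                  delta_effect = base$delta_effect, icer = base$icer)),
    class = "psa_result"
  )
}

#' @export
print.psa_result <- function(x, ...) {
  cat(sprintf("<psa_result> %d iterations (seed %d)\n", x$n_iterations,
              x$seed))
  qf <- x$quadrant_fractions
  cat(sprintf(
    "  CE plane: %.1f%% NE (dC>0, dE>0), %.1f%% NW, %.1f%% SW, %.1f%% SE\n",
    100 * qf[["ne"]], 100 * qf[["nw"]], 100 * qf[["sw"]], 100 * qf[["se"]]))
  cat(sprintf("  median incremental: dC %s yuan, dE %.2f QALYs\n",
              fmt_yuan(stats::median(x$points$delta_cost)),
              stats::median(x$points$delta_effect)))
  invisible(x)
}

#' Cost-effectiveness acceptability curve
#'
#' At each willingness-to-pay, the probability that the comparator (AS) is
#' cost-effective: the fraction of PSA iterations in which its net monetary
#' benefit exceeds the reference's, i.e. `wtp * delta_effect - delta_cost >
#' 0`.
#'
#' @param points PSA points: a data frame with `delta_cost` and
#'   `delta_effect` columns (or a `psa_result`).
#' @param wtp_grid Vector of willingness-to-pay values.
#' @return `data.frame` with columns `wtp` and `probability`.
#' @export
ceac_curve <- function(points, wtp_grid = seq(0, wtp_threshold(),
                                              length.out = 100L)) {
  if (inherits(points, "psa_result")) points <- points$points
  stopifnot(is.data.frame(points), nrow(points) >= 1L,
            all(c("delta_cost", "delta_effect") %in% names(points)),
            length(wtp_grid) >= 1L)
  prob <- vapply(wtp_grid, function(w) {
    mean(w * points$delta_effect - points$delta_cost > 0)
  }, 0)
  data.frame(wtp = wtp_grid, probability = prob)
}

#' CE-plane quadrant occupancy of PSA points
#'
#' @inheritParams ceac_curve
#' @return Named vector of fractions (`ne`: dE>0 & dC>0, `nw`: dE<=0 &
#'   dC>0, `sw`: dE<=0 & dC<=0, `se`: dE>0 & dC<=0) summing to 1.
#' @export
quadrant_fractions <- function(points) {
  if (inherits(points, "psa_result")) points <- points$points
  de <- points$delta_effect
  dc <- points$delta_cost
  c(ne = mean(de > 0 & dc > 0),
    nw = mean(de <= 0 & dc > 0),
    sw = mean(de <= 0 & dc <= 0),
    se = mean(de > 0 & dc <= 0))
}
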