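# Strategy graphs: health states, parameter-bound transition edges, and
# per-age transition matrices.

#' Construct a health state
#'
#' @param name Identifier.
#' @param utility Utility parameter name (resolved against the parameter
#'   set's utility block) or a fixed number; death must have utility 0.
#' @param cycle_cost Cost key charged per cycle of occupancy (`NULL` = none).
#' @param entry_cost Cost key charged to flow entering the state (surgery
#'   plus any complication management); edges may override or suppress it.
#' @param absorbing Absorbing state (death).
#' @param permanent Once entered, left only to death.
#' @param temporary Occupied for exactly one cycle (resolves next cycle).
#' @return An object of class `health_state`.
#' @export
health_state <- function(name, utility, cycle_cost = NULL, entry_cost = NULL,
                         absorbing = FALSE, permanent = FALSE,
                         temporary = FALSE) {
  stopifnot(is.character(name), length(name) == 1L)
  if (absorbing && !(is.numeric(utility) && utility == 0)) {
    stop("absorbing state '", name, "' must have utility 0", call. = FALSE)
  }
  structure(
    list(name = name, utility = utility, cycle_cost = cycle_cost,
         entry_cost = entry_cost, absorbing = absorbing,
         permanent = permanent, temporary = temporary),
    class = "health_state"
  )
}

#' Load a strategy graph file
#'
#' Strategy files are YAML listing `states` (name, utility binding, cost
#' keys, absorbing/permanent/temporary flags), an `initial` occupancy (fixed
#' numbers or parameter expressions, summing to 1), and `transitions`. Each
#' transition's probability is a product of factors -- `{param: name}`,
#' `{schedule: growth|nodal}`, `{fixed: x}`, `{complement: name}` (1 - p), or
#' `{one_minus_sum: [names]}` -- and exactly one transition per state is
#' marked `residual: true`, receiving 1 minus the sum of the others.
#'
#' @param strategy `"AS"`, `"ES"`, or a path to a strategy YAML file.
#' @return An object of class `strategy`.
#' @export
load_strategy <- function(strategy = c("AS", "ES")) {
  path <- if (file.exists(strategy[1L])) strategy[1L] else
    system.file("extdata",
                paste0("strategy_", tolower(match.arg(strategy)), ".yaml"),
                package = "ptmcCEA")
  if (!nzchar(path) || !file.exists(path)) {
    stop("strategy file not found: '", strategy[1L], "'", call. = FALSE)
  }
  raw <- yaml::read_yaml(path)
  states <- lapply(raw$states, function(s) {
    health_state(
      name = s$name, utility = s$utility,
      cycle_cost = s$cycle_cost, entry_cost = s$entry_cost,
      absorbing = isTRUE(s$absorbing), permanent = isTRUE(s$permanent),
      temporary = isTRUE(s$temporary)
    )
  })
  names(states) <- vapply(states, `[[`, "", "name")
  if (anyDuplicated(names(states))) {
    stop("strategy '", raw$name, "': duplicate state names", call. = FALSE)
  }
  edges <- lapply(raw$transitions, function(tr) {
    list(from = tr$from, to = tr$to,
         factors = tr$factors,
         residual = isTRUE(tr$residual),
         charge_entry = !isFALSE(tr$charge_entry),
         entry_cost = tr$entry_cost)
  })
  for (e in edges) {
    if (!e$from %in% names(states) || !e$to %in% names(states)) {
      stop("strategy '", raw$name, "': transition references unknown state ",
           e$from, " -> ", e$to, call. = FALSE)
    }
  }
  n_resid <- table(vapply(Filter(function(e) e$residual, edges), `[[`, "", "from"))
  if (!setequal(names(n_resid), names(states)) || any(n_resid != 1L)) {
    stop("strategy '", raw$name,
         "': every state needs exactly one residual transition", call. = FALSE)
  }
  structure(
    list(name = raw$name, states = states, initial = raw$initial,
         transitions = edges, path = path),
    class = "strategy"
  )
}

#' @export
print.strategy <- function(x, ...) {
  cat(sprintf("<strategy> %s: %d states, %d transitions\n", x$name,
              length(x$states), length(x$transitions)))
  cat("states:", paste(names(x$states), collapse = ", "), "\n")
  invisible(x)
}

# Evaluate one probability factor against the working parameter values.
resolve_factor <- function(f, params, age) {
  if (!is.null(f$param)) return(get_param(params, f$param)$point)
  if (!is.null(f$fixed)) return(as.numeric(f$fixed))
  if (!is.null(f$complement)) return(1 - get_param(params, f$complement)$point)
  if (!is.null(f$one_minus_sum)) {
    return(1 - sum(vapply(f$one_minus_sum,
                          function(nm) get_param(params, nm)$point, 0)))
  }
  if (!is.null(f$schedule)) {
    sched <- switch(f$schedule,
                    growth = params$growth_schedule,
                    nodal = params$nodal_schedule,
                    stop("unknown schedule '", f$schedule, "'", call. = FALSE))
    return(lookup_age_prob(sched, age))
  }
  stop("unparseable transition factor: ", paste(names(f), collapse = "/"),
       call. = FALSE)
}

# All edges with numeric probabilities at a given age: residual edges filled
# with 1 - sum(others from the same state). Errors if any residual would be
# negative (parameter draws summing above 1).
resolve_edges <- function(strategy, params, age) {
  probs <- vapply(strategy$transitions, function(e) {
    if (e$residual) return(NA_real_)
    prod(vapply(e$factors, resolve_factor, 0, params = params, age = age))
  }, 0)
  from <- vapply(strategy$transitions, `[[`, "", "from")
  residual <- vapply(strategy$transitions, `[[`, TRUE, "residual")
  for (s in names(strategy$states)) {
    idx <- which(from == s)
    out_sum <- sum(probs[idx], na.rm = TRUE)
    if (out_sum > 1 + 1e-12) {
      stop("strategy '", strategy$name, "', state '", s,
           "': outgoing probabilities sum to ", format(out_sum),
           " > 1; residual would be negative", call. = FALSE)
    }
    probs[idx[residual[idx]]] <- max(0, 1 - out_sum)
  }
  if (any(probs < -1e-12 | probs > 1 + 1e-12)) {
    bad <- which(probs < -1e-12 | probs > 1 + 1e-12)[1L]
    stop("strategy '", strategy$name, "': edge ", from[bad], " -> ",
         strategy$transitions[[bad]]$to, " has probability ",
         format(probs[bad]), call. = FALSE)
  }
  data.frame(
    from = from,
    to = vapply(strategy$transitions, `[[`, "", "to"),
    prob = pmin(pmax(probs, 0), 1),
    charge_entry = vapply(strategy$transitions, `[[`, TRUE, "charge_entry"),
    entry_override = vapply(strategy$transitions, function(e) {
      if (is.null(e$entry_cost)) NA_character_ else e$entry_cost
    }, ""),
    stringsAsFactors = FALSE
  )
}

#' Build the per-cycle transition matrix
#'
#' Assembles the row-stochastic transition matrix of a strategy for a given
#' age: age-schedule factors are looked up at `age`, parameter factors use
#' the working point values, and each state's residual edge receives
#' 1 minus the sum of its other outgoing edges.
#'
#' @param strategy A [load_strategy()] graph.
#' @param params A [parameter_set()].
#' @param age Integer age (the age entering the cycle).
#' @return A square matrix over the strategy's states; rows sum to 1.
#' @export
build_transition_matrix <- function(strategy, params, age) {
  stopifnot(inherits(strategy, "strategy"), inherits(params, "parameter_set"))
  edges <- resolve_edges(strategy, params, age)
  nm <- names(strategy$states)
  M <- matrix(0, length(nm), length(nm), dimnames = list(nm, nm))
  for (i in seq_len(nrow(edges))) {
    M[edges$from[i], edges$to[i]] <- M[edges$from[i], edges$to[i]] +
      edges$prob[i]
  }
  stopifnot(all(abs(rowSums(M) - 1) < 1e-12))
  M
}

# Initial occupancy vector resolved against the parameter set.
resolve_initial <- function(strategy, params) {
  nm <- names(strategy$states)
  occ <- stats::setNames(numeric(length(nm)), nm)
  for (s in names(strategy$initial)) {
    if (!s %in% nm) {
      stop("strategy '", strategy$name, "': initial occupancy names unknown ",
           "state '", s, "'", call. = FALSE)
    }
    occ[s] <- resolve_factor(strategy$initial[[s]], params, age = NA)
  }
  if (abs(sum(occ) - 1) > 1e-10) {
    stop("strategy '", strategy$name, "': initial occupancy sums to ",
         format(sum(occ)), ", not 1", call. = FALSE)
  }
  occ
}

#' Validate a set of model inputs together
#'
#' Loads (or accepts) a parameter set, the two strategy graphs and a cost
#' schedule, and cross-checks every reference: parameter and schedule
#' bindings on edges, utility bindings on states, cost keys, initial
#' occupancies, and residual feasibility at all ages 20-80. Errors carry the
#' offending file and name.
#'
#' @param params Parameter scenario name, path, or `parameter_set`.
#' @param costs Path or `cost_schedule`.
#' @param strategies Character vector / list of strategies to check.
#' @return Invisibly, a list of the validated objects.
#' @export
validate_inputs <- function(params = "text_canonical", costs = NULL,
                            strategies = c("AS", "ES")) {
  ps <- if (inherits(params, "parameter_set")) params else
    load_parameters(params)
  cs <- if (inherits(costs, "cost_schedule")) costs else
    load_cost_schedule(costs)
  strats <- lapply(strategies, function(s) {
    if (inherits(s, "strategy")) s else load_strategy(s)
  })
  for (st in strats) {
    for (state in st$states) {
      if (is.character(state$utility)) get_param(ps, state$utility)
      for (key in c(state$cycle_cost, state$entry_cost)) cost_value(cs, key)
    }
    for (e in st$transitions) {
      if (!is.null(e$entry_cost)) cost_value(cs, e$entry_cost)
    }
    resolve_initial(st, ps)
    for (age in 20:80) resolve_edges(st, ps, age)
  }
  invisible(list(params = ps, costs = cs, strategies = strats))
}
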