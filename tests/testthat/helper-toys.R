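# Small models built in code: used as closed-form oracles for the cohort
# engine, independent of the packaged strategy graphs.

zero_schedule <- function(nm) {
  age_schedule(data.frame(age_low = 20L, age_high = 120L, prob = 0), name = nm)
}

empty_params <- function(probabilities = list(), utilities = list(),
                         discount = 0.03) {
  parameter_set(probabilities, utilities,
                growth_schedule = zero_schedule("growth"),
                nodal_schedule = zero_schedule("nodal"),
                discount = discount)
}

write_yaml_fixture <- function(text) {
  path <- tempfile(fileext = ".yaml")
  writeLines(text, path)
  path
}

toy_costs <- function(items) {
  lines <- c("currency: CNY", "price_year: 2021", "label: toy", "items:",
             vapply(names(items), function(nm) {
               sprintf("  %s: {value: %s}", nm, format(items[[nm]]))
             }, ""))
  load_cost_schedule(write_yaml_fixture(lines))
}

# Alive -> Death chain; per-cycle probability of death `p_death`, alive
# utility 1, optional alive-year cost.
toy_two_state <- function(p_death = 0, alive_cost = 0) {
  strat <- load_strategy(write_yaml_fixture(c(
    "name: toy2",
    "states:",
    "  - {name: Alive, utility: 1, cycle_cost: alive_year}",
    "  - {name: Death, utility: 0, absorbing: true}",
    "initial:",
    "  Alive: {fixed: 1}",
    "transitions:",
    "  - {from: Alive, to: Death, factors: [{param: p_death}]}",
    "  - {from: Alive, to: Alive, residual: true}",
    "  - {from: Death, to: Death, residual: true}"
  )))
  list(
    strategy = strat,
    params = empty_params(probabilities = list(
      p_death = param_dist("p_death", "fixed", p_death))),
    costs = toy_costs(c(alive_year = alive_cost))
  )
}

# A -> B -> Death chain with constant transition probabilities, per-cycle
# costs in both states and a one-time entry cost into B; admits an exact
# geometric-series solution (see test-markov.R).
toy_three_state <- function(p_ab = 0.1, p_ad = 0.05, p_bd = 0.2,
                            u_a = 0.9, u_b = 0.6,
                            cost_a = 100, cost_b = 300, entry_b = 1000) {
  strat <- load_strategy(write_yaml_fixture(c(
    "name: toy3",
    "states:",
    sprintf("  - {name: A, utility: %s, cycle_cost: cost_a}", format(u_a)),
    sprintf("  - {name: B, utility: %s, cycle_cost: cost_b, entry_cost: entry_b}",
            format(u_b)),
    "  - {name: Death, utility: 0, absorbing: true}",
    "initial:",
    "  A: {fixed: 1}",
    "transitions:",
    sprintf("  - {from: A, to: B, factors: [{fixed: %s}]}", format(p_ab)),
    sprintf("  - {from: A, to: Death, factors: [{fixed: %s}]}", format(p_ad)),
    "  - {from: A, to: A, residual: true}",
    sprintf("  - {from: B, to: Death, factors: [{fixed: %s}]}", format(p_bd)),
    "  - {from: B, to: B, residual: true}",
    "  - {from: Death, to: Death, residual: true}"
  )))
  list(strategy = strat, params = empty_params(),
       costs = toy_costs(c(cost_a = cost_a, cost_b = cost_b,
                           entry_b = entry_b)))
}

# Packaged parameter set with every probability/utility jittered uniformly
# within its stated analysis range (seeded); used for property tests.
jittered_params <- function(seed, scenario = "text_canonical") {
  ps <- load_parameters(scenario)
  set.seed(seed)
  for (nm in c(names(ps$probabilities), names(ps$utilities))) {
    d <- get_param(ps, nm)
    rng <- dsa_range(d)
    ps <- set_param(ps, nm, stats::runif(1, rng[["low"]], rng[["high"]]))
  }
  ps
}

# Calibrated reference-case model, built once per test run.
calibrated_model_40 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      m <- ce_model()
      cal <- calibrate_costs(m$costs, m)
      m$costs <- cal$schedule
      cache <<- m
    }
    cache
  }
})
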