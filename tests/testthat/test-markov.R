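# Cohort engine: transition matrices, discounting, reward accrual, and the
# closed-form oracles for small chains.

annuity <- function(rate, n) sum((1 + rate)^-(1:n))

test_that("discount factors follow (1+r)^-k", {
  expect_identical(discount_factor(0.03, 0), 1)
  expect_equal(discount_factor(0.03, 1), 0.970874, tolerance = 1e-6)
  expect_identical(discount_factor(0, 100), 1)
})

test_that("an immortal cohort accrues exactly the annuity factor", {
  toy <- toy_two_state(p_death = 0)
  tr <- run_cohort(toy$strategy, toy$params, toy$costs, start_age = 40,
                   n_cycles = 40, discount = 0)
  expect_equal(tr$discounted_qaly, 40, tolerance = 1e-12)
  expect_equal(tr$discounted_cost, 0)

  tr3 <- run_cohort(toy$strategy, toy$params, toy$costs, start_age = 40,
                    n_cycles = 40, discount = 0.03)
  # closed-form annuity: sum_{k=1..40} 1.03^-k = (1 - 1.03^-40) / 0.03
  expect_equal(tr3$discounted_qaly, (1 - 1.03^-40) / 0.03, tolerance = 1e-9)
  expect_equal(round(tr3$discounted_qaly, 4), 23.1148)
})

test_that("a dying cohort accrues the geometric series", {
  toy <- toy_two_state(p_death = 0.5)
  tr <- run_cohort(toy$strategy, toy$params, toy$costs, start_age = 40,
                   n_cycles = 40, discount = 0)
  expect_equal(tr$discounted_qaly, 1 - 0.5^40, tolerance = 1e-9)
  # absorbing occupancy is non-decreasing and complements the living mass
  expect_true(all(diff(tr$occupancy[, "Death"]) >= 0))
  expect_equal(rowSums(tr$occupancy), rep(1, 41), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("the three-state chain matches its geometric-series closed form", {
  p_ab <- 0.1; p_ad <- 0.05; p_bd <- 0.2
  a <- 1 - p_ab - p_ad; b <- 1 - p_bd
  u_a <- 0.9; u_b <- 0.6; cost_a <- 100; cost_b <- 300; entry_b <- 1000
  r <- 0.03; N <- 40; d <- 1 / (1 + r)
  toy <- toy_three_state(p_ab, p_ad, p_bd, u_a, u_b, cost_a, cost_b, entry_b)
  tr <- run_cohort(toy$strategy, toy$params, toy$costs, start_age = 40,
                   n_cycles = N, discount = r)
  # occ_A(k) = a^k; occ_B(k) = p_ab (a^k - b^k)/(a - b); rewards at end of
  # cycle k discounted by d^k; entry into B during cycle k = p_ab a^(k-1).
  g <- function(x) (x * d) * (1 - (x * d)^N) / (1 - x * d)  # sum (xd)^k
  sum_A <- g(a)
  sum_B <- p_ab / (a - b) * (g(a) - g(b))
  sum_entry <- d * (1 - (a * d)^N) / (1 - a * d)            # sum d^k a^(k-1)
  expect_equal(tr$discounted_qaly, u_a * sum_A + u_b * sum_B, tolerance = 1e-9)
  expect_equal(tr$discounted_cost,
               cost_a * sum_A + cost_b * sum_B + entry_b * p_ab * sum_entry,
               tolerance = 1e-9)
})

test_that("packaged transition matrices carry the decade-band entries", {
  ps <- load_parameters("table1_verbatim")
  as_strat <- load_strategy("AS")
  M45 <- build_transition_matrix(as_strat, ps, 45)
  expect_equal(rowSums(M45), rep(1, nrow(M45)), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_true(all(M45 >= 0 & M45 <= 1))
  # total leaving probability = growth + nodal at the 40-49 band
  expect_equal(1 - M45["StableAS", "StableAS"], 0.0380 + 0.0380,
               tolerance = 1e-12)
  # growth flow splits over the HT surgical outcomes
  expect_equal(M45["StableAS", "PostHT_NoComp"],
               0.0380 * (1 - 0.002 - 0.015 - 0.015), tolerance = 1e-12)
  expect_equal(M45["StableAS", "PostHT_Perm"], 0.0380 * 0.015,
               tolerance = 1e-12)
  # death row is an identity row
  expect_equal(M45["Death", ], c(rep(0, ncol(M45) - 1), 1),
               tolerance = 0, ignore_attr = TRUE)
  M65 <- build_transition_matrix(as_strat, ps, 65)
  expect_equal(1 - M65["StableAS", "StableAS"], 0.0003 + 0.0068,
               tolerance = 1e-12)
})

test_that("probability mass is conserved under random parameter draws", {
  as_strat <- load_strategy("AS")
  es_strat <- load_strategy("ES")
  costs <- load_cost_schedule()
  for (seed in 1:5) {
    ps <- jittered_params(seed)
    for (cfg in list(list(s = as_strat, age = 20L, n = 60L),
                     list(s = es_strat, age = 40L, n = 40L),
                     list(s = as_strat, age = 60L, n = 20L))) {
      tr <- run_cohort(cfg$s, ps, costs, cfg$age, cfg$n)
      expect_equal(rowSums(tr$occupancy), rep(1, cfg$n + 1), tolerance = 1e-10,
                   ignore_attr = TRUE)
      expect_true(all(diff(tr$occupancy[, "Death"]) >= -1e-12))
    }
  }
})

test_that("costs increase with unit costs and totals decrease with discounting", {
  m <- ce_model()
  base <- run_base_case(m)
  dearer <- m
  dearer$costs$items[["ht_surgery"]] <- dearer$costs$items[["ht_surgery"]] + 5000
  up <- run_base_case(dearer)
  expect_gte(up$es$discounted_cost, base$es$discounted_cost)
  expect_gte(up$as$discounted_cost, base$as$discounted_cost)

  m5 <- ce_model(discount = 0.05)
  high <- run_base_case(m5)
  expect_lte(high$es$discounted_cost, base$es$discounted_cost)
  expect_lte(high$es$discounted_qaly, base$es$discounted_qaly)
  expect_lte(high$as$discounted_qaly, base$as$discounted_qaly)
})

test_that("with zero progression the AS arm reduces to utility times annuity", {
  ps <- load_parameters()
  ps$growth_schedule <- zero_schedule("growth")
  ps$nodal_schedule <- zero_schedule("nodal")
  tr <- run_cohort(load_strategy("AS"), ps, load_cost_schedule(),
                   start_age = 40, n_cycles = 40, discount = 0.03)
  expect_equal(tr$discounted_qaly,
               get_param(ps, "u_as_stable")$point * annuity(0.03, 40),
               tolerance = 1e-12)
  # and its only cost is the discounted surveillance stream
  expect_equal(tr$discounted_cost,
               cost_value(load_cost_schedule(), "as_surveillance_year") *
                 annuity(0.03, 40),
               tolerance = 1e-9)
})

test_that("a temporary complication resolves after exactly one cycle", {
  ps <- load_parameters()
  es <- load_strategy("ES")
  tr <- run_cohort(es, ps, load_cost_schedule(), 40, 3, discount = 0)
  # initial temporary-complication mass moves to the no-complication state
  expect_equal(tr$occupancy[1, "PostHT_Temp"],
               get_param(ps, "p_temp_comp_ht")$point)
  expect_equal(tr$occupancy[2, "PostHT_Temp"], 0)
})

test_that("infeasible draws abort with the offending state named", {
  ps <- load_parameters("table1_verbatim")
  ps <- set_param(ps, "p_death_tt", 0.95) # TT outcome split now sums > 1
  expect_error(
    build_transition_matrix(load_strategy("AS"), ps, 45),
    "probability")
})

test_that("cohort traces export one labelled row per cycle", {
  m <- ce_model(start_age = 60L)
  tr <- run_base_case(m)$as
  df <- trace_df(tr)
  expect_identical(nrow(df), 21L)
  expect_identical(df$age, 60:80)
  expect_equal(df$cum_discounted_cost[nrow(df)], tr$discounted_cost,
               tolerance = 1e-9)
  expect_equal(df$cum_discounted_qaly[nrow(df)], tr$discounted_qaly,
               tolerance = 1e-9)
})
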