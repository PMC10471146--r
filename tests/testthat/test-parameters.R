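# Rate/probability conversions, beta parameterisation, DSA ranges, age
# schedules, and the packaged parameter files.

test_that("cumulative-to-annual rate conversion matches the constant-hazard formula", {
  # a 10-year cumulative incidence of 3.7% is an annual rate of 0.38%/year
  r <- annual_rate_from_cumulative(0.037, 10)
  expect_equal(r, 0.0037702, tolerance = 1e-5)
  expect_equal(round(100 * r, 2), 0.38)
  expect_identical(annual_rate_from_cumulative(0, 5), 0)
  expect_equal(annual_rate_from_cumulative(0.5, 1), 0.6931472, tolerance = 1e-7)
  expect_error(annual_rate_from_cumulative(1, 1), "`p`")
  expect_error(annual_rate_from_cumulative(0.5, 0), "`t`")
  expect_error(annual_rate_from_cumulative(-0.1, 1), "`p`")
})

test_that("rate-to-probability conversion inverts the rate formula", {
  expect_equal(prob_from_rate(0.003770, 1), 0.0037629, tolerance = 1e-6)
  expect_identical(prob_from_rate(0, 10), 0)
  expect_equal(prob_from_rate(0.693147, 1), 0.5, tolerance = 1e-6)
  expect_error(prob_from_rate(-0.01, 1), "`r`")

  # round-trip identity across the probability grid, several interval lengths
  p <- seq(0, 0.99, by = 0.01)
  for (t in c(0.5, 1, 10)) {
    expect_equal(prob_from_rate(annual_rate_from_cumulative(p, t), t), p,
                 tolerance = 1e-12)
  }
})

test_that("the rate conversion is monotone in both arguments", {
  set.seed(11)
  p <- sort(runif(50, 0, 0.95))
  r <- annual_rate_from_cumulative(p, 5)
  expect_true(all(diff(r) > 0))
  t <- sort(runif(50, 0.1, 30))
  rt <- annual_rate_from_cumulative(0.3, t)
  expect_true(all(diff(rt) < 0))
})

test_that("method-of-moments beta shapes reproduce the requested moments", {
  # sampling oracle: empirical mean/sd of many draws hit the targets
  cases <- list(c(mean = 0.684, sd = 0.035), c(mean = 0.016, sd = 0.0008))
  set.seed(101)
  for (cs in cases) {
    sh <- beta_params_from_moments(cs[["mean"]], cs[["sd"]])
    expect_true(all(sh > 0))
    x <- rbeta(1e6, sh[["alpha"]], sh[["beta"]])
    expect_lt(abs(mean(x) - cs[["mean"]]), 3 * cs[["sd"]] / sqrt(1e6))
    expect_lt(abs(sd(x) - cs[["sd"]]), 3 * cs[["sd"]] / sqrt(2 * (1e6 - 1)))
  }
  # frozen shape values for the two Table-style cases
  expect_equal(unname(beta_params_from_moments(0.684, 0.035)),
               c(120.0037, 55.4403), tolerance = 1e-4)
  expect_equal(unname(beta_params_from_moments(0.016, 0.0008)),
               c(393.584, 24205.42), tolerance = 1e-4)
  # uniform-distribution moments give the flat beta
  expect_equal(unname(beta_params_from_moments(0.5, sqrt(1 / 12))), c(1, 1),
               tolerance = 1e-6)
  expect_error(beta_params_from_moments(0.5, 0.6), "infeasible")
  expect_error(beta_params_from_moments(1.2, 0.1), "mean")
})

test_that("DSA ranges derive from +/-10%, clip to the domain, and honour stated ranges", {
  d <- param_dist("p_hypo", "beta", 0.089, mean = 0.09, sd = 0.005)
  expect_equal(unname(dsa_range(d)), c(0.0801, 0.0979), tolerance = 1e-12)
  u <- param_dist("u_top", "beta", 1.0, mean = 0.99, sd = 0.05)
  expect_equal(unname(dsa_range(u)), c(0.9, 1.0))
  disc <- param_dist("discount", "fixed", 0.03)
  expect_equal(unname(dsa_range(disc, fraction = 0.5)), c(0.01, 0.05))
  stated <- param_dist("p", "beta", 0.089, mean = 0.09, sd = 0.005,
                       dsa_low = 0.080, dsa_high = 0.098)
  expect_equal(unname(dsa_range(stated)), c(0.080, 0.098))
  expect_equal(unname(dsa_range(stated, use_stated = FALSE)),
               c(0.0801, 0.0979), tolerance = 1e-12)
})

test_that("age-band lookup is inclusive, decade-stepped, and extends past the top band", {
  ps <- load_parameters("table1_verbatim")
  expect_equal(lookup_age_prob(ps$growth_schedule, 45), 0.0380)
  expect_equal(lookup_age_prob(ps$growth_schedule, 49), 0.0380)
  expect_equal(lookup_age_prob(ps$growth_schedule, 50), 0.0240)
  expect_equal(lookup_age_prob(ps$nodal_schedule, 25), 0.165)
  expect_equal(lookup_age_prob(ps$nodal_schedule, 65), 0.0068)
  # >= 80 carries the 70-79 band forward; below the schedule errors
  expect_equal(lookup_age_prob(ps$growth_schedule, 85),
               lookup_age_prob(ps$growth_schedule, 75))
  expect_error(lookup_age_prob(ps$growth_schedule, 15), "extend")
})

test_that("age schedules reject gaps, overlaps and short coverage", {
  expect_error(age_schedule(data.frame(age_low = c(20, 31), age_high = c(29, 79),
                                       prob = 0), "g"), "contiguous")
  expect_error(age_schedule(data.frame(age_low = 30, age_high = 79, prob = 0),
                            "g"), "cover")
  expect_error(age_schedule(data.frame(age_low = 20, age_high = 79, prob = 1.2),
                            "g"), "probabilities")
})

test_that("both packaged parameter files load every input row", {
  for (scen in c("table1_verbatim", "text_canonical")) {
    ps <- load_parameters(scen)
    expect_length(ps$probabilities, 11L)
    expect_length(ps$utilities, 16L)
    expect_identical(nrow(ps$growth_schedule$bands), 6L)
    expect_identical(nrow(ps$nodal_schedule$bands), 6L)
    expect_equal(ps$growth_schedule$bands$age_low[1L], 20)
    expect_equal(ps$growth_schedule$bands$age_high[6L], 79)
    expect_equal(ps$discount, 0.03)
    for (d in c(ps$probabilities, ps$utilities)) {
      expect_true(d$point >= 0 && d$point <= 1)
      expect_true(d$dsa_low <= d$point && d$point <= d$dsa_high)
    }
  }
  # the two scenarios share every name; only the decade bands differ
  v <- load_parameters("table1_verbatim")
  cn <- load_parameters("text_canonical")
  expect_identical(names(v$probabilities), names(cn$probabilities))
  expect_identical(names(v$utilities), names(cn$utilities))
})

test_that("the text-canonical bands equal the converted verbatim bands", {
  v <- load_parameters("table1_verbatim")
  cn <- load_parameters("text_canonical")
  for (sched in c("growth_schedule", "nodal_schedule")) {
    p10 <- v[[sched]]$bands$prob
    expect_equal(cn[[sched]]$bands$prob,
                 prob_from_rate(annual_rate_from_cumulative(p10, 10), 1),
                 tolerance = 1e-5)
  }
})

test_that("the verbatim scenario's unit conflict is recorded in the load log", {
  v <- load_parameters("table1_verbatim")
  expect_true(any(grepl("verbatim as annual", v$meta$load_log)))
  expect_true(any(grepl("u_active_surveillance", v$meta$load_log)))
  expect_message(load_parameters("table1_verbatim", quiet = FALSE), "load log")
})

test_that("parameter constructors enforce their invariants", {
  expect_error(param_dist("x", "beta", point = 1.2), "outside")
  expect_error(param_dist("x", "beta", point = 0.5, mean = 0.5, sd = 0.51),
               "infeasible")
  expect_error(param_dist("x", "beta", point = 0.5, mean = 0.5, sd = 0.01,
                          dsa_low = 0.6, dsa_high = 0.7), "analysis range")
  expect_error(empty_params(discount = 0.06), "discount")
  ps <- load_parameters()
  expect_error(get_param(ps, "nope"), "unknown parameter")
  expect_equal(get_param(set_param(ps, "p_recur_ht", 0.01),
                         "p_recur_ht")$point, 0.01)
})
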