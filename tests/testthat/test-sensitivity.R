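# One-way DSA (tornado) and probabilistic sensitivity analysis.

test_that("a parameter bound to no edge leaves the ICER bit-identical", {
  m <- ce_model()
  base <- run_base_case(m)$ce$icer
  # TreeAge-style event utilities are loaded but unused by the graphs
  for (nm in c("u_early_surgery", "u_nodal_metastasis")) {
    entry <- one_way_dsa(m, nm)
    expect_identical(entry$icer_low, base)
    expect_identical(entry$icer_high, base)
    expect_identical(entry$spread, 0)
  }
})

test_that("one-way DSA re-runs the model at both ends of the range", {
  m <- ce_model()
  base <- run_base_case(m)$ce

  # raising the post-HT utility favours ES: dE falls, dC stays, ICER rises
  pin <- function(nm, v) {
    m2 <- m; m2$params <- set_param(m2$params, nm, v)
    run_base_case(m2)$ce
  }
  u0 <- get_param(m$params, "u_ht_nocomp")$point
  lo <- pin("u_ht_nocomp", u0 * 0.9)
  hi <- pin("u_ht_nocomp", min(1, u0 * 1.1))
  expect_equal(lo$delta_cost, hi$delta_cost, tolerance = 1e-9)
  expect_gt(lo$delta_effect, hi$delta_effect)
  expect_gt(hi$icer, lo$icer)
  entry <- one_way_dsa(m, "u_ht_nocomp", range = c(u0 * 0.9, min(1, u0 * 1.1)))
  expect_equal(entry$icer_low, lo$icer, tolerance = 1e-12)
  expect_equal(entry$icer_high, hi$icer, tolerance = 1e-12)

  # the discount rate spans 1-5% and moves the ICER
  disc <- one_way_dsa(m, "discount")
  expect_equal(c(disc$low, disc$high), c(0.01, 0.05))
  expect_gt(disc$spread, 0)

  expect_error(one_way_dsa(m, "not_an_input"), "unknown model input")
})

test_that("tornado analysis covers every input and sorts by spread", {
  m <- ce_model(start_age = 60L) # shortest horizon, fastest reruns
  torn <- tornado_analysis(m, parameters = c("u_ht_nocomp", "u_as_stable",
                                             "p_recur_ht", "discount",
                                             "ht_surgery", "u_early_surgery"))
  expect_identical(nrow(torn), 6L)
  expect_true(all(diff(torn$spread) <= 0))
  expect_true(all(torn$spread >= 0))
  expect_true(is.finite(attr(torn, "base_icer")))
  expect_identical(torn$spread[torn$parameter == "u_early_surgery"], 0)
})

test_that("the PSA is reproducible under a seed and degenerates without noise", {
  m <- calibrated_model_40()
  p1 <- run_psa(m, n_iterations = 20, seed = 99)
  p2 <- run_psa(m, n_iterations = 20, seed = 99)
  expect_identical(p1$points, p2$points)
  expect_false(identical(p1$points,
                         run_psa(m, n_iterations = 20, seed = 100)$points))

  # all-zero SDs: every iteration reproduces the base case exactly
  m0 <- m
  for (nm in c(names(m0$params$probabilities), names(m0$params$utilities))) {
    d <- get_param(m0$params, nm)
    if (nm %in% names(m0$params$probabilities)) {
      m0$params$probabilities[[nm]]$sd <- 0
    } else {
      m0$params$utilities[[nm]]$sd <- 0
    }
  }
  p0 <- run_psa(m0, n_iterations = 5, seed = 1, cost_sd_fraction = 0)
  base <- run_base_case(m0)$ce
  expect_equal(p0$points$delta_cost, rep(base$delta_cost, 5), tolerance = 1e-12)
  expect_equal(p0$points$delta_effect, rep(base$delta_effect, 5),
               tolerance = 1e-12)
})

test_that("CEAC probabilities derive from the NMB rule over the same points", {
  # one point: step from 0 to 1 at its ICER
  pt <- data.frame(delta_cost = 5000, delta_effect = 2) # ICER 2500
  cc <- ceac_curve(pt, wtp_grid = c(0, 2000, 3000, 1e6))
  expect_equal(cc$probability, c(0, 0, 1, 1))

  # symmetric cloud of ICERs around W: probability 1/2 at W
  W <- 50000
  cloud <- data.frame(delta_cost = W + c(-2000, -500, 500, 2000),
                      delta_effect = 1)
  expect_equal(ceac_curve(cloud, wtp_grid = W)$probability, 0.5)

  # uniformly positive dE: monotone nondecreasing, -> 1 as WTP -> Inf
  set.seed(31)
  pts <- data.frame(delta_cost = rnorm(200, 2e4, 1e4),
                    delta_effect = runif(200, 0.1, 2))
  cc2 <- ceac_curve(pts, wtp_grid = seq(0, 1e6, length.out = 50))
  expect_true(all(diff(cc2$probability) >= 0))
  expect_equal(cc2$probability[50], 1)
  # WTP = 0 identity: probability equals the fraction of cost-saving points
  expect_equal(ceac_curve(pts, wtp_grid = 0)$probability,
               mean(pts$delta_cost < 0))
})

test_that("quadrant fractions partition the CE plane", {
  set.seed(32)
  pts <- data.frame(delta_cost = rnorm(500), delta_effect = rnorm(500))
  qf <- quadrant_fractions(pts)
  expect_equal(sum(qf), 1)
  expect_true(all(qf >= 0 & qf <= 1))
  # CEAC at WTP 0 counts exactly the cost-saving half-plane
  expect_equal(ceac_curve(pts, wtp_grid = 0)$probability,
               mean(pts$delta_cost < 0))
})
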