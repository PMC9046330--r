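test_that("annual-to-cycle conversion follows the constant-rate transform", {
  expect_equal(annual_to_cycle_prob(0.36, 0.25), 1 - 0.64^0.25)
  expect_equal(annual_to_cycle_prob(0.36, 0.25), 0.1055728, tolerance = 1e-7)
  expect_identical(annual_to_cycle_prob(0, 0.25), 0)
  expect_identical(annual_to_cycle_prob(1, 0.25), 1)
  # monotone in both arguments
  ps <- seq(0, 1, by = 0.1)
  expect_true(all(diff(annual_to_cycle_prob(ps, 0.25)) >= 0))
  fs <- seq(0.05, 1, by = 0.05)
  expect_true(all(diff(annual_to_cycle_prob(0.4, fs)) >= 0))
  expect_error(annual_to_cycle_prob(1.2, 0.25), "0, 1")
})

test_that("fall outcome tree is a probability distribution with the right masses", {
  p <- base_params()
  for (arm in c("control", "intervention")) {
    d <- fall_outcome_distribution(p, arm, age = 68)
    expect_equal(sum(d), 1, tolerance = 1e-12)
    expect_true(all(d >= 0))
  }
  # control, age 68: fracture mass is p_fracture split 62/38, death only via
  # major events at the 65-69 band probability
  d <- fall_outcome_distribution(p, "control", age = 68)
  expect_equal(unname(d["fracture_minor"]), 0.12 * 0.38)
  expect_equal(unname(d["fracture_major"]), 0.12 * 0.62 * (1 - 0.043))
  maj <- 0.12 * 0.62 + 0.88 * 0.88 * 0.06
  expect_equal(unname(d["dead"]), 0.043 * maj, tolerance = 1e-12)
  # exercise arm preserves the marginal fracture RR: conditional fracture
  # mass scales by rr_fracture / rr_fall relative to control
  di <- fall_outcome_distribution(p, "intervention", age = 68)
  expect_equal(di[["fracture_minor"]] / d[["fracture_minor"]], 0.44 / 0.76,
               tolerance = 1e-9)
  expect_equal(di[["fracture_major"]] / d[["fracture_major"]], 0.44 / 0.76,
               tolerance = 1e-9)
  # after the sustained-effect window the arms coincide
  dl <- fall_outcome_distribution(p, "intervention", age = 71.25,
                                  years_elapsed = 3.25)
  dc <- fall_outcome_distribution(p, "control", age = 71.25,
                                  years_elapsed = 3.25)
  expect_equal(dl, dc)
})

test_that("infeasible fracture decompositions error; the injury branch saturates", {
  p <- base_params()
  p$rr_fracture_exercise <- 10
  expect_error(fall_outcome_distribution(p, "intervention", 68),
               "conditional fracture probability")
  p <- base_params()
  p$rr_injury_exercise <- 2
  d <- fall_outcome_distribution(p, "intervention", 68)
  expect_equal(sum(d), 1, tolerance = 1e-12)
  # saturated: every non-fracture faller is injured, so no injury-free mass
  q_fx <- p$p_fracture * p$rr_fracture_exercise / p$rr_fall_exercise
  expect_equal(unname(d["injury_major"] / (1 - q_fx)),
               p$p_inj_major * (1 - 0.043), tolerance = 1e-12)
})

test_that("transition matrices are row-stochastic with the allowed sparsity", {
  for (seed in 1:10) {
    p <- random_params(seed)
    arm <- if (seed %% 2 == 0) "control" else "intervention"
    t <- sample(0:11, 1)
    M <- build_transition_matrix(p, arm, t)
    expect_equal(unname(rowSums(M)), rep(1, 7), tolerance = 1e-12)
    expect_true(all(M >= 0 & M <= 1))
    # absent transitions are structural zeros
    expect_identical(unname(M[7, 1:6]), rep(0, 6))   # death absorbing
    expect_identical(unname(M[3:6, c(1, 3:6)]), matrix(0, 4, 5)) # tunnels exit
    expect_identical(unname(M[2, 1]), 0)  # no return to the pre-fall state
  }
  # aggregate fall mass out of the pre-fall state equals the cycle fall prob
  p <- base_params()
  M <- build_transition_matrix(p, "control", 0)
  q_bg <- annual_to_cycle_prob(p$background_mortality[["68"]], 0.25)
  p_fall <- annual_to_cycle_prob(0.36, 0.25)
  expect_equal(sum(M[1, 3:6]) + M[1, 7] - (1 - p_fall) * q_bg, p_fall,
               tolerance = 1e-12)
})

test_that("age bands and background mortality advance with cycle index", {
  p <- base_params()
  # cohort aged 70.25 at cycle 9: fall-death band 70-74
  M9 <- build_transition_matrix(p, "control", 9)
  M0 <- build_transition_matrix(p, "control", 0)
  maj <- p$p_fracture * p$p_fx_major +
    (1 - p$p_fracture) * p$p_nonfx_injury * p$p_inj_major
  q_bg9 <- annual_to_cycle_prob(p$background_mortality[["70"]], 0.25)
  p_fall <- annual_to_cycle_prob(0.36, 0.25)
  expect_equal(M9[1, 7], p_fall * 0.065 * maj + (1 - p_fall) * q_bg9,
               tolerance = 1e-12)
  expect_equal(M0[1, 7],
               p_fall * 0.043 * maj +
                 (1 - p_fall) * annual_to_cycle_prob(
                   p$background_mortality[["68"]], 0.25),
               tolerance = 1e-12)
  expect_error(build_transition_matrix(p, "control", 12), "cycle_index")
})

test_that("occupancy conserves mass and starts in the pre-fall state", {
  for (seed in 11:16) {
    p <- random_params(seed)
    tr <- run_cohort(p, if (seed %% 2 == 0) "control" else "intervention")
    expect_equal(unname(rowSums(tr$occupancy)), rep(1, tr$n_cycles + 1),
                 tolerance = 1e-9)
    expect_identical(unname(tr$occupancy[1, ]), c(1, rep(0, 6)))
    expect_true(all(tr$cycle_qalys >= 0))
    expect_lte(tr$undiscounted_life_years, p$horizon_years)
  }
})

test_that("no falls and no background mortality give the closed-form QALY total", {
  p <- base_params()
  p$p_fall_year1 <- 0
  p$discount_annual <- 0
  p$background_mortality[] <- 0
  for (arm in c("control", "intervention")) {
    tr <- run_cohort(p, arm)
    expect_equal(tr$total_qalys, 0.79 * 3)  # u_baseline * horizon, exactly
    expect_equal(unname(tr$occupancy[13, 1]), 1)
  }
  # cost difference is exactly the upfront intervention cost
  expect_equal(run_cohort(p, "intervention")$total_cost -
                 run_cohort(p, "control")$total_cost, p$c_intervention)
})

test_that("rewards respond monotonically to costs, utilities and discounting", {
  p <- base_params()
  up <- run_cohort(with_value(p, "c_fx_major", 25000), "control")
  expect_gt(up$total_cost, run_cohort(p, "control")$total_cost)
  up <- run_cohort(with_value(p, "u_recurrent_exercise", 0.80), "intervention")
  expect_gt(up$total_qalys, run_cohort(p, "intervention")$total_qalys)
  flat <- with_value(p, "discount_annual", 0)
  for (arm in c("control", "intervention")) {
    d0 <- run_cohort(flat, arm)
    d5 <- run_cohort(p, arm)
    expect_lt(d5$total_cost, d0$total_cost)
    expect_lt(d5$total_qalys, d0$total_qalys)
  }
})

test_that("trace export has the documented layout", {
  tr <- run_cohort(base_params(), "intervention")
  tab <- trace_table(tr)
  expect_identical(nrow(tab), 13L)
  expect_true(all(health_states() %in% names(tab)))
  expect_equal(tab$cum_cost[13], tr$total_cost)
  expect_equal(tab$cum_qalys[13], tr$total_qalys)
  expect_equal(tab$cost_disc[1], base_params()$c_intervention)
})
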