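test_that("net monetary benefit is the threshold-weighted QALY surplus", {
  # inverting the published per-arm cells: nmb = wtp*E - C
  expect_equal(nmb(4135, 2.06472, 50000), 99101)
  expect_equal(nmb(2952, 2.10128, 50000), 102112)
  expect_equal(nmb(1234, 0, 0), -1234)
  # linear in all three arguments
  expect_equal(nmb(10, 2, 500) + nmb(5, 1, 500), nmb(15, 3, 500))
  expect_equal(nmb(0, 2, 700), 2 * 700)
  expect_error(nmb(1, 1, -1), "non-negative")
})

test_that("comparing an arm against itself yields null increments", {
  tr <- run_cohort(base_params(), "control")
  res <- compare_arms(tr, tr)
  expect_equal(res$delta_cost, 0)
  expect_equal(res$delta_qalys, 0)
  expect_equal(res$inmb, 0)
  expect_identical(res$dominance, "trade_off")
})

test_that("dominance classification and ICER suppression follow the quadrant", {
  p <- base_params()
  res <- run_cua(p)
  expect_identical(res$dominance, "intervention_dominant")
  expect_true(is.na(res$icer))
  expect_equal(res$inmb, p$wtp * res$delta_qalys - res$delta_cost)
  expect_equal(res$control$nmb,
               p$wtp * res$control$total_qalys - res$control$total_cost)
  # a very expensive intervention with no effect is dominated
  worse <- apply_override(p, scenario_override("exp", list(
    c_intervention = 50000, rr_fall_exercise = 1, rr_fracture_exercise = 1,
    rr_injury_exercise = 1, u_recurrent_exercise = p$u_recurrent_control - 0.05)))
  res2 <- run_cua(worse)
  expect_identical(res2$dominance, "control_dominant")
  expect_true(is.na(res2$icer))
  # trade-off quadrant reports a numeric ICER
  tr_off <- apply_override(p, scenario_override("costly", list(
    c_intervention = 5000)))
  res3 <- run_cua(tr_off)
  expect_identical(res3$dominance, "trade_off")
  expect_equal(res3$icer, res3$delta_cost / res3$delta_qalys)
})

test_that("mismatched horizons cannot be compared", {
  p <- base_params()
  p6 <- apply_override(p, scenario_override("h6", list(horizon_years = 6)))
  expect_error(compare_arms(run_cohort(p, "control"),
                            run_cohort(p6, "intervention")),
               "incompatible traces")
})

test_that("iNMB is linear in the threshold and in the intervention cost", {
  p <- base_params()
  ctl <- run_cohort(p, "control")
  int <- run_cohort(p, "intervention")
  base <- compare_arms(ctl, int, wtp = 50000)
  for (w in c(0, 20000, 80000)) {
    res <- compare_arms(ctl, int, wtp = w)
    expect_equal(res$inmb, w * base$delta_qalys - base$delta_cost,
                 tolerance = 1e-9)
  }
  expect_equal(compare_arms(ctl, int, wtp = 0)$inmb, -base$delta_cost)
  # slope -1 in the upfront intervention cost
  for (cost in c(0, 767, 1500, 2338, 3304)) {
    res <- run_scenario(p, scenario_override("c", list(c_intervention = cost)))
    expect_equal(res$inmb, base$inmb - (cost - 767), tolerance = 1e-6)
  }
})

test_that("the results table mirrors the published layout", {
  res <- run_cua(base_params())
  tab <- cua_table(res)
  expect_identical(tab$group, c("control", "intervention", "difference"))
  expect_identical(tab$dominance[3], "intervention_dominant")
  expect_equal(tab$cost[3], round(res$delta_cost))
  expect_equal(tab$qalys[3], round(res$delta_qalys, 2))
})
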