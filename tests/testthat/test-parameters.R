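test_that("packaged defaults carry the published point estimates", {
  p <- base_params()
  expect_equal(p$p_fall_year1, 0.36)
  expect_equal(p$p_fall_recurrent, 0.65)
  expect_equal(p$rr_fall_exercise, 0.76)
  expect_equal(p$p_fracture, 0.12)
  expect_equal(p$rr_fracture_exercise, 0.44)
  expect_equal(p$p_fx_major + p$p_fx_minor, 1)
  expect_equal(p$p_inj_major + p$p_inj_minor, 1)
  expect_equal(p$c_fx_major, 20724)
  expect_equal(p$c_intervention, 767)
  expect_equal(p$u_baseline, 0.79)
  expect_equal(p$u_recurrent_exercise - p$u_recurrent_control, 0.02)
  expect_equal(p$start_age, 68)
  expect_equal(p$horizon_years, 3)
  expect_equal(p$cycle_months, 3)
  expect_equal(p$discount_annual, 0.05)
  expect_equal(p$wtp, 50000)
  # every registered CI brackets its mean
  est <- p$estimates
  ok <- is.na(est$ci_low) | (est$ci_low <= est$mean & est$mean <= est$ci_high)
  expect_true(all(ok))
})

test_that("intervention cost components sum to the packaged total", {
  comp <- intervention_cost_components()
  expect_identical(nrow(comp), 4L)
  expect_identical(sum(comp$cost_aud), 767L)
  expect_equal(sum(comp$cost_aud), base_params()$c_intervention)
})

test_that("load -> serialise -> load is the identity", {
  p <- base_params()
  tmp <- withr::local_tempfile(fileext = ".yaml")
  write_parameters(p, tmp)
  p2 <- load_parameters(tmp)
  for (nm in setdiff(names(p), c("estimates", "background_mortality")))
    expect_equal(p2[[nm]], p[[nm]], info = nm)
  expect_equal(p2$estimates, p$estimates)
  expect_equal(p2$background_mortality, p$background_mortality)
})

test_that("invalid configurations are rejected with named errors", {
  p <- base_params()
  expect_error(validate_parameters(with_value(p, "p_fx_minor", 0.30)),
               "sum to 1")
  expect_error(validate_parameters(with_value(p, "u_baseline", 1.4)),
               "u_baseline")
  expect_error(validate_parameters(with_value(p, "c_intervention", -5)),
               "c_intervention")
  expect_error(validate_parameters(with_value(p, "rr_fall_exercise", 0)),
               "rr_fall_exercise")
  expect_error(validate_parameters(with_value(p, "horizon_years", 0)),
               "horizon_years")
  expect_error(validate_parameters(with_value(p, "cycle_months", 5)),
               "whole cycles")

  # unknown and missing keys in a config file
  tmp <- withr::local_tempfile(fileext = ".yaml")
  write_parameters(p, tmp)
  cfg <- yaml::read_yaml(tmp)
  cfg$not_a_parameter <- list(mean = 1)
  yaml::write_yaml(cfg, tmp)
  expect_error(load_parameters(tmp), "unknown parameter")
  cfg$not_a_parameter <- NULL
  cfg$p_fall_year1 <- NULL
  yaml::write_yaml(cfg, tmp)
  expect_error(load_parameters(tmp), "missing field")
})

test_that("scenario overrides apply cleanly and reject bad keys", {
  p <- base_params()
  sc <- scenario_override("SA4a", list(c_intervention = 3304))
  p2 <- apply_override(p, sc)
  expect_equal(p2$c_intervention, 3304)
  expect_equal(p2$p_fall_year1, p$p_fall_year1)
  expect_error(scenario_override("bad", list(nonexistent_field = 1)),
               "not among model parameters")
  expect_error(apply_override(p, scenario_override("neg",
                                                   list(c_intervention = -1))),
               "non-negative")
})

test_that("background mortality table is usable and override-able", {
  bg <- default_background_mortality()
  expect_true(all(as.character(60:75) %in% names(bg)))
  expect_true(all(diff(bg) > 0))  # mortality rises with age
  expect_true(all(bg > 0 & bg < 0.1))
  # an override that fails to cover the horizon is rejected
  expect_error(load_parameters(background_mortality = bg[as.character(60:69)]),
               "does not cover")
  p <- load_parameters(background_mortality = setNames(rep(0.02, 16), 60:75))
  expect_equal(unname(p$background_mortality[["68"]]), 0.02)
})
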