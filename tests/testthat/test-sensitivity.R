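oc_spec <- one_compartment_spec(v_l_kg = 10, cl_ml_min_kg = 5, body_weight_kg = 1)
oc_config <- sim_config(t_end_hr = 120, grid_step_hr = 0.5)

test_that("clearance doubling halves AUC: S = -0.5 at a single factor of 2", {
  r <- sensitivity_coefficient(oc_spec, "clearance", output = "auc_0_inf",
                               dose_mg_per_kg = 0.1, factors = 2,
                               config = oc_config)
  expect_equal(r$sensitivity, -0.5, tolerance = 1e-3)
})

test_that("small-perturbation limit recovers the analytic elasticity -1", {
  r <- sensitivity_coefficient(oc_spec, "clearance", output = "auc_0_inf",
                               dose_mg_per_kg = 0.1, factors = c(0.9, 1.1),
                               config = oc_config)
  # d ln AUC / d ln CL = -1; the two-sided factor mean gives -(1/0.9+1/1.1)/2
  expect_lt(abs(r$sensitivity + 1), 0.02)
  expect_equal(r$sensitivity, -(1 / 0.9 + 1 / 1.1) / 2, tolerance = 1e-3)
})

test_that("increasing clearance never increases AUC (sign property)", {
  r <- sensitivity_coefficient(oc_spec, "clearance", output = "auc_0_inf",
                               dose_mg_per_kg = 0.1,
                               factors = c(0.5, 2, 5), config = oc_config)
  expect_true(all(r$per_factor < 0))   # S_f < 0 for every factor
})

test_that("structurally inert parameters have exactly zero sensitivity", {
  spec <- model_spec(toy_physiology(v_organ = 100, q_blood_ml_min = 100,
                                    with_salivary_gland = TRUE),
                     tracer_compound(fu = 0.5),
                     clearance_spec("calibrated_total",
                                    total_plasma_clearance_ml_min_kg = 2),
                     eliminating_organs = "rest_of_body")
  cfg <- sim_config(t_end_hr = 48, grid_step_hr = 0.5)
  r <- sensitivity_coefficient(spec, "pKa", output = "auc_0_inf",
                               dose_mg_per_kg = 0.1, factors = c(0.5, 2),
                               config = cfg)
  expect_equal(r$sensitivity, 0)
})

test_that("the screen ranks cells and is dose-invariant for linear kinetics", {
  spec <- model_spec(toy_physiology(v_organ = 100, q_blood_ml_min = 100,
                                    with_salivary_gland = TRUE),
                     tracer_compound(fu = 0.5, logP = 0.5),
                     clearance_spec("calibrated_total",
                                    total_plasma_clearance_ml_min_kg = 2),
                     eliminating_organs = "rest_of_body")
  cfg <- sim_config(t_end_hr = 48, grid_step_hr = 1)
  tab <- sensitivity_screen(spec, parameters = c("clearance", "logP", "pKa"),
                            outputs = "auc_0_inf",
                            compartments = "venous_plasma",
                            doses_mg_per_kg = c(0.1, 0.25, 0.5),
                            factors = c(0.5, 2), config = cfg)
  expect_equal(nrow(tab), 3 * 3)     # parameter x dose
  # ranking identical across the three doses (linear model)
  by_dose <- split(tab, tab$dose_mg_per_kg)
  orders <- lapply(by_dose, function(d) d$parameter[order(d$rank)])
  expect_identical(orders[[1]], orders[[2]])
  expect_identical(orders[[2]], orders[[3]])
  # sensitivities themselves are dose-independent
  s1 <- by_dose[[1]][order(by_dose[[1]]$parameter), "sensitivity"]
  s3 <- by_dose[[3]][order(by_dose[[3]]$parameter), "sensitivity"]
  expect_equal(s1, s3, tolerance = 1e-6)
  # clearance dominates the inert pKa
  top <- tab$parameter[tab$dose_mg_per_kg == 0.1][1]
  expect_equal(top, "clearance")

  # reproducibility: a second run gives the identical table
  tab2 <- sensitivity_screen(spec, parameters = c("clearance", "logP", "pKa"),
                             outputs = "auc_0_inf",
                             compartments = "venous_plasma",
                             doses_mg_per_kg = c(0.1, 0.25, 0.5),
                             factors = c(0.5, 2), config = cfg)
  expect_identical(tab, tab2)
})

test_that("every screen row is reproducible by a single-parameter recomputation", {
  spec <- model_spec(toy_physiology(v_organ = 100, q_blood_ml_min = 100,
                                    with_salivary_gland = TRUE),
                     tracer_compound(fu = 0.5, logP = 0.5),
                     clearance_spec("calibrated_total",
                                    total_plasma_clearance_ml_min_kg = 2),
                     eliminating_organs = "rest_of_body")
  cfg <- sim_config(t_end_hr = 48, grid_step_hr = 1)
  tab <- sensitivity_screen(spec, parameters = "fu_plasma",
                            outputs = "auc_0_inf", compartments = "saliva",
                            doses_mg_per_kg = 0.1, factors = c(0.5, 2),
                            config = cfg)
  direct <- sensitivity_coefficient(spec, "fu_plasma", output = "auc_0_inf",
                                    compartment = "saliva",
                                    dose_mg_per_kg = 0.1, factors = c(0.5, 2),
                                    config = cfg)
  expect_equal(tab$sensitivity, direct$sensitivity, tolerance = 1e-12)
})

test_that("failed factors raise a partial-result error unless tolerated", {
  spec <- model_spec(toy_physiology(v_organ = 100, q_blood_ml_min = 100,
                                    with_salivary_gland = TRUE),
                     tracer_compound(fu = 0.5),
                     clearance_spec("calibrated_total",
                                    total_plasma_clearance_ml_min_kg = 2),
                     eliminating_organs = "rest_of_body")
  cfg <- sim_config(t_end_hr = 24, grid_step_hr = 1)
  # hematocrit x 10 = 4.5 is unphysical and must fail that factor
  expect_error(sensitivity_coefficient(spec, "hematocrit",
                                       dose_mg_per_kg = 0.1,
                                       factors = c(1.1, 10), config = cfg),
               "partial result.*10")
  expect_warning(r <- sensitivity_coefficient(spec, "hematocrit",
                                              dose_mg_per_kg = 0.1,
                                              factors = c(1.1, 10),
                                              config = cfg,
                                              allow_partial = TRUE),
                 "failed")
  expect_equal(r$failed_factors, "10")
  expect_false(is.na(r$sensitivity))
})

test_that("variation factors must be positive and different from one", {
  expect_error(sensitivity_coefficient(oc_spec, "clearance", factors = c(1, 2),
                                       config = oc_config), "!= 1")
  expect_error(sensitivity_coefficient(oc_spec, "clearance", factors = -2,
                                       config = oc_config), "!= 1|> 0")
})
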