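coarse <- sim_config(t_end_hr = 24, grid_step_hr = 0.25)

test_that("mass is conserved with and without clearance", {
  # closed system: zero calibrated clearance
  m0 <- build_model(toy_physiology(with_salivary_gland = TRUE),
                    tracer_compound(),
                    clearance_spec("calibrated_total",
                                   total_plasma_clearance_ml_min_kg = 0),
                    eliminating_organs = "rest_of_body")
  s0 <- simulate_pbpk(m0, dose_event(0.1), coarse)
  expect_lt(s0$mass_balance_rel_err, 1e-6)
  expect_equal(unname(s0$states[nrow(s0$states), "eliminated"]), 0)

  # eliminating system: amount + cumulative eliminated = dose at all times
  s1 <- simulate_pbpk(mouse_model(), dose_event(0.1), coarse)
  expect_lt(s1$mass_balance_rel_err, 1e-6)
  expect_gt(s1$states[nrow(s1$states), "eliminated"], 0)
})

test_that("the model is linear in dose", {
  m <- mouse_model()
  s1 <- simulate_pbpk(m, dose_event(0.1), coarse)
  s2 <- simulate_pbpk(m, dose_event(0.2), coarse)
  keep <- s1$data$time_hr > 0
  a <- 2 * s1$data$conc_ng_per_ml[keep]
  b <- s2$data$conc_ng_per_ml[keep]
  expect_lt(max(abs(b - a) / pmax(a, 1e-9 * max(a))), 1e-6)
})

test_that("states and reported concentrations are non-negative", {
  s <- simulate_pbpk(mouse_model(), dose_event(0.1), coarse)
  expect_true(all(s$data$conc_ng_per_ml >= 0))
  expect_true(all(s$states > -1e-9 * s$dose_ng))
})

test_that("the whole-body model collapses to the one-compartment closed form", {
  # fast exchange, small pools: venous concentration must match
  # (Dose/V) exp(-CL/V t) with V the total accessible volume
  phys <- toy_physiology(v_organ = 1000, q_blood_ml_min = 3e5)
  cl_ml_min <- 10
  m <- build_model(phys, tracer_compound(),
                   clearance_spec("calibrated_total",
                                  total_plasma_clearance_ml_min_kg = cl_ml_min),
                   eliminating_organs = "rest_of_body")
  s <- simulate_pbpk(m, dose_event(0.1),
                     sim_config(t_end_hr = 12, grid_step_hr = 0.1))
  prof <- get_profile(s, "plasma")
  v_eff <- sum(phys$organs$volume_ml * m$k_organ) +
    (phys$arterial_volume_ml + phys$venous_volume_ml) * (1 - phys$hematocrit) +
    phys$saliva_volume_ml
  ke <- cl_ml_min * 60 / v_eff
  keep <- prof$time_hr >= 0.1
  closed <- (s$dose_ng / v_eff) * exp(-ke * prof$time_hr[keep])
  expect_lt(max(abs(prof$conc_ng_per_ml[keep] / closed - 1)), 1e-3)

  # the explicit one-compartment reduction is exact to solver tolerance
  oc <- one_compartment_model(v_l_kg = 1, cl_ml_min_kg = 10, body_weight_kg = 1)
  so <- simulate_pbpk(oc, dose_event(0.1),
                      sim_config(t_end_hr = 12, grid_step_hr = 0.1))
  po <- get_profile(so, "plasma")
  co <- (so$dose_ng / 1000) * exp(-10 * 60 / 1000 * po$time_hr)
  expect_equal(po$conc_ng_per_ml, co, tolerance = 1e-7)
})

test_that("tissue:plasma ratio approaches K_organ in a closed system", {
  phys <- toy_physiology(v_organ = 50, q_blood_ml_min = 100,
                         f_water = 0.5, f_lipid = 0.15, f_protein = 0)
  m <- build_model(phys, tracer_compound(logP = 1),  # k = 0.5 + 10*0.15 = 2
                   clearance_spec("calibrated_total",
                                  total_plasma_clearance_ml_min_kg = 0),
                   eliminating_organs = "rest_of_body")
  expect_equal(unname(m$k_organ["rest_of_body"]), 2)
  s <- simulate_pbpk(m, dose_event(0.1),
                     sim_config(t_end_hr = 48, grid_step_hr = 0.5))
  tis <- get_profile(s, "rest_of_body")
  pl <- get_profile(s, "plasma")
  n <- nrow(tis)
  ratio <- tis$conc_ng_per_ml[n] / pl$conc_ng_per_ml[n]
  expect_equal(ratio, 2, tolerance = 1e-2)
})

test_that("saliva tracks the partition-scaled salivary-gland plasma level", {
  m <- mouse_model()
  s <- simulate_pbpk(m, dose_event(0.1), sim_config())
  sal <- get_profile(s, "saliva")
  sg <- get_profile(s, "salivary_gland")
  sg_plasma <- sg$conc_ng_per_ml / m$k_organ["salivary_gland"]
  late <- sal$time_hr > 2     # past the equilibration transient (k_sal = 10/hr)
  expect_equal(sal$conc_ng_per_ml[late],
               m$saliva_partition * sg_plasma[late], tolerance = 0.02)
  # shape mirrors plasma once equilibrated
  pl <- get_profile(s, "plasma")
  expect_gt(cor(sal$conc_ng_per_ml[late], pl$conc_ng_per_ml[late]), 0.98)
})

test_that("permeability-limited transport retards tissue uptake", {
  phys <- toy_physiology(v_organ = 100, q_blood_ml_min = 50)
  cl0 <- clearance_spec("calibrated_total", total_plasma_clearance_ml_min_kg = 0)
  m_perf <- build_model(phys, tracer_compound(), cl0,
                        eliminating_organs = "rest_of_body")
  m_perm <- build_model(phys, tracer_compound(), cl0,
                        eliminating_organs = "rest_of_body",
                        permeability = c(rest_of_body = 0.5))
  cfg <- sim_config(t_end_hr = 6, grid_step_hr = 0.1)
  s_perf <- simulate_pbpk(m_perf, dose_event(0.1), cfg)
  s_perm <- simulate_pbpk(m_perm, dose_event(0.1), cfg)
  expect_lt(s_perm$mass_balance_rel_err, 1e-6)
  t_probe <- 1
  up_perf <- get_profile(s_perf, "rest_of_body")
  up_perm <- get_profile(s_perm, "rest_of_body")
  expect_lt(up_perm$conc_ng_per_ml[up_perm$time_hr == t_probe],
            up_perf$conc_ng_per_ml[up_perf$time_hr == t_probe])
})

test_that("simulation inputs are validated", {
  m <- mouse_model()
  expect_error(simulate_pbpk(m, dose_event(0.1, time_hr = 1), coarse),
               "dose time")
  expect_error(sim_config(t_start_hr = 5, t_end_hr = 1), "t_start")
  expect_error(sim_config(rtol = 0), "admissible")
})

test_that("profile CSV round-trips through the tidy dialect", {
  s <- simulate_pbpk(mouse_model(), dose_event(0.1),
                     sim_config(t_end_hr = 2, grid_step_hr = 0.5))
  path <- withr::local_tempfile(fileext = ".csv")
  write_profiles_csv(s, path)
  back <- read_profiles_csv(path)
  expect_equal(nrow(back), nrow(s$data))
  expect_equal(back$conc_ng_per_ml, s$data$conc_ng_per_ml, tolerance = 1e-12)
  expect_error(read_profiles_csv({
    p2 <- withr::local_tempfile(fileext = ".csv")
    write.csv(data.frame(a = 1), p2, row.names = FALSE); p2
  }), "lacks columns")
})
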