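mono_profile <- function(c0, ke, times) {
  data.frame(time_hr = times, conc_ng_per_ml = c0 * exp(-ke * times))
}

test_that("terminal slope is exact on noiseless exponentials", {
  p <- mono_profile(1, 1, seq(0, 10, by = 0.25))
  ts <- terminal_slope(p)
  expect_equal(ts$ke_per_hr, 1, tolerance = 1e-12)
  expect_equal(ts$r_squared, 1, tolerance = 1e-12)
  expect_equal(ts$t_half_hr, log(2), tolerance = 1e-12)

  # the 91.13-hr half-life anchor: ke = ln2 / t_half
  p2 <- mono_profile(10, log(2) / 91.13, seq(0, 24, by = 0.05))
  ts2 <- terminal_slope(p2)
  expect_equal(ts2$ke_per_hr, log(2) / 91.13, tolerance = 1e-10)
  expect_equal(signif(ts2$ke_per_hr, 2), 0.0076)
})

test_that("terminal slope equals an independent least-squares refit", {
  spec <- profile_spec("mono_exponential", c0_ng_ml = 50, ke_per_hr = 0.2,
                       grid_hr = seq(0, 30, by = 0.5), cv = 0.1, seed = 42)
  p <- generate_profile(spec)
  ts <- terminal_slope(p[, c("time_hr", "conc_ng_per_ml")])
  sub <- p[p$time_hr %in% ts$fit_times, ]
  oracle <- lm(log(conc_ng_per_ml) ~ time_hr, data = sub)
  expect_equal(ts$ke_per_hr, -unname(coef(oracle)[2]), tolerance = 1e-10)
  expect_equal(ts$r_squared, summary(oracle)$r.squared, tolerance = 1e-10)
})

test_that("terminal slope error conditions", {
  expect_error(terminal_slope(mono_profile(1, 1, c(0, 1))), "insufficient")
  rising <- data.frame(time_hr = 0:5, conc_ng_per_ml = c(1, 2, 3, 4, 5, 6))
  expect_error(terminal_slope(rising), "insufficient|no terminal")
  flat0 <- data.frame(time_hr = 0:5, conc_ng_per_ml = c(5, 0, 0, 0, 0, 0))
  expect_error(terminal_slope(flat0), "insufficient")
})

test_that("AUC quadrature matches hand-computed oracles", {
  # constant concentration: plain rectangle
  const <- data.frame(time_hr = c(0, 0.5, 1), conc_ng_per_ml = c(1, 1, 1))
  expect_equal(nca_auc(const, ke_per_hr = 1e6)$auc_0_t, 1)

  # halving profile: log-down trapezoid, hand quadrature (10-5)/ln2 + (5-2.5)/ln2
  p3 <- data.frame(time_hr = c(0, 1, 2), conc_ng_per_ml = c(10, 5, 2.5))
  a <- nca_auc(p3, ke_per_hr = log(2))
  expect_equal(a$auc_0_t, 5 / log(2) + 2.5 / log(2), tolerance = 1e-12)
  # tail: C_last/ke on top of the observed area
  expect_equal(a$auc_0_inf, a$auc_0_t + 2.5 / log(2), tolerance = 1e-12)

  # exact exponential, extrapolated: AUC0-inf = C0/ke
  pe <- mono_profile(1, 1, seq(0, 12, by = 0.1))
  ae <- nca_auc(pe, ke_per_hr = 1)
  expect_equal(ae$auc_0_inf, 1, tolerance = 1e-10)
  expect_equal(ae$aumc_0_inf, 1, tolerance = 1e-8)   # mono-exp: AUMC = C0/ke^2

  # missing ke with positive tail: warning, NA extrapolation
  expect_warning(am <- nca_auc(mono_profile(1, 1, 0:5)), "unavailable")
  expect_true(is.na(am$auc_0_inf))
})

test_that("AUC error on a curved profile shrinks as O(h^2)", {
  f <- function(t) exp(-t) + exp(-5 * t)
  truth <- (1 - exp(-4)) + (1 - exp(-20)) / 5
  err <- vapply(c(0.4, 0.2, 0.1), function(h) {
    p <- data.frame(time_hr = seq(0, 4, by = h), conc_ng_per_ml = f(seq(0, 4, by = h)))
    abs(nca_auc(p, ke_per_hr = 1)$auc_0_t - truth)
  }, numeric(1))
  expect_gt(err[1] / err[2], 3)    # halving h cuts error ~4x
  expect_gt(err[2] / err[3], 3)
})

test_that("pk_summary satisfies the NCA identity ring to 1e-9", {
  p <- mono_profile(40, 0.15, seq(0, 30, by = 0.25))
  r <- pk_summary(p, dose_mg_per_kg = 0.1, exclude_time_zero = FALSE)
  expect_lt(abs(r$t_half_hr * r$ke_per_hr / log(2) - 1), 1e-9)
  expect_lt(abs(r$cl_ml_min_kg * 60 * r$auc_0_inf / (0.1 * 1e6) - 1), 1e-9)
  expect_lt(abs(r$vd_l_kg * 1000 * r$ke_per_hr / (r$cl_ml_min_kg * 60) - 1), 1e-9)
  expect_lt(abs(r$mrt_hr * r$auc_0_inf / r$aumc_0_inf - 1), 1e-9)
  expect_gte(r$auc_0_inf, r$auc_0_t)
  expect_true(r$extrapolated_fraction >= 0 && r$extrapolated_fraction < 1)
})

test_that("pk_summary recovers one-compartment ground truth within 0.5%", {
  oc <- one_compartment_model(v_l_kg = 41.54, cl_ml_min_kg = 4.58,
                              body_weight_kg = 1)
  s <- simulate_pbpk(oc, dose_event(0.1),
                     sim_config(t_end_hr = 550, grid_step_hr = 0.5))
  r <- pk_summary(get_profile(s, "plasma"), 0.1)
  expect_rel(r$vd_l_kg, 41.54, 0.005)
  expect_rel(r$cl_ml_min_kg, 4.58, 0.005)
  expect_rel(r$t_half_hr, log(2) * 41.54 * 1000 / (4.58 * 60), 0.005)
})

test_that("Vd identity: CL 4.58 ml/min/kg with t1/2 104.58 hr gives 41.5 L/kg", {
  # mono-exponential with that half-life and AUC = dose/CL
  ke <- log(2) / 104.58
  cl_ml_hr_kg <- 4.58 * 60
  c0 <- 0.1 * 1e6 / cl_ml_hr_kg * ke    # makes AUC0-inf = dose/CL
  p <- mono_profile(c0, ke, seq(0, 500, by = 0.5))
  r <- pk_summary(p, 0.1, exclude_time_zero = FALSE)
  expect_equal(signif(r$vd_l_kg, 3), 41.5)
})

test_that("degenerate profiles raise informative errors", {
  zeros <- data.frame(time_hr = 0:10, conc_ng_per_ml = 0)
  expect_error(pk_summary(zeros, 0.1), "identically zero")
  expect_error(pk_summary(mono_profile(1, 1, 0:10), 0), "admissible")
})

test_that("batch NCA from CSV equals per-profile computation", {
  s <- simulate_pbpk(mouse_model(), dose_event(0.1),
                     sim_config(t_end_hr = 24, grid_step_hr = 0.25))
  path <- withr::local_tempfile(fileext = ".csv")
  write_profiles_csv(s, path)
  tab <- nca_from_csv(path, dose_mg_per_kg = 0.1)
  expect_equal(nrow(tab), 1)
  direct <- pk_summary(get_profile(s, "plasma"), 0.1)
  expect_equal(tab$auc_0_inf, direct$auc_0_inf, tolerance = 1e-10)
  expect_equal(tab$ke_per_hr, direct$ke_per_hr, tolerance = 1e-10)
})
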