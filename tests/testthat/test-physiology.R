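test_that("species registries reproduce the literature anatomy", {
  mouse <- get_species_physiology("mouse")
  expect_equal(mouse$hematocrit, 0.45)
  expect_equal(mouse$body_weight_kg, 0.0275)
  expect_equal(mouse$saliva_volume_ml, 0.00226)
  expect_equal(mouse$organs["liver", "volume_ml"], 1.70)
  expect_equal(mouse$organs["lung", "blood_flow_ml_min"], 7.11)
  expect_equal(mouse$organs["kidney", "blood_flow_ml_min"], 1.7)

  human <- get_species_physiology("human")
  expect_equal(human$body_weight_kg, 80.35)
  expect_equal(human$bmi_kg_m2, 25.22)
  expect_equal(human$organs["liver", "volume_ml"], 2366.5)
  expect_equal(human$organs["brain", "volume_ml"], 1509.06)
  expect_equal(human$saliva_volume_ml, 6.6)

  # full 15-organ whole-body topology in both fixtures
  for (ph in list(mouse, human)) {
    expect_setequal(ph$organs$name, salivapk:::REQUIRED_ORGANS)
    q_lung <- ph$organs["lung", "blood_flow_ml_min"]
    q_sys <- sum(ph$organs$blood_flow_ml_min[ph$organs$name != "lung"])
    expect_lt(abs(q_lung - q_sys) / q_lung, 1e-9)
  }

  expect_error(get_species_physiology("rat"), "unsupported species")
})

test_that("allometric scaling uses exponent 1 for volumes, 0.75 for flows", {
  base <- get_species_physiology("mouse")

  ident <- scale_physiology(base, base$body_weight_kg)
  expect_equal(ident$organs$volume_ml, base$organs$volume_ml)
  expect_equal(ident$organs$blood_flow_ml_min, base$organs$blood_flow_ml_min)

  half <- scale_physiology(base, 0.01375)   # half the 27.5 g reference
  expect_equal(half$organs$volume_ml, base$organs$volume_ml * 0.5)
  expect_equal(half$organs$blood_flow_ml_min,
               base$organs$blood_flow_ml_min * 0.5^0.75)
  expect_equal(half$saliva_volume_ml, base$saliva_volume_ml * 0.5)
  expect_equal(half$hematocrit, base$hematocrit)

  expect_error(scale_physiology(base, 0), "admissible range")
  expect_error(scale_physiology(base, -1), "admissible range")
})

test_that("scaling preserves flow conservation and is monotone in weight", {
  base <- get_species_physiology("human")
  weights <- c(45, 60, 80.35, 100, 130)
  prev_vol <- prev_flow <- NULL
  for (w in weights) {
    ph <- scale_physiology(base, w)
    expect_s3_class(validate_physiology(ph), "physiology")
    if (!is.null(prev_vol)) {
      expect_true(all(ph$organs$volume_ml > prev_vol))
      expect_true(all(ph$organs$blood_flow_ml_min > prev_flow))
    }
    prev_vol <- ph$organs$volume_ml
    prev_flow <- ph$organs$blood_flow_ml_min
  }
})

test_that("organ overrides are applied and rebalanced against cardiac output", {
  ph <- get_species_physiology("mouse",
          organ_overrides = list(adipose = list(volume_ml = 2.5)))
  expect_equal(ph$organs["adipose", "volume_ml"], 2.5)
  expect_equal(ph$organs["adipose", "source"], "user")
  validate_physiology(ph)

  ph2 <- get_species_physiology("mouse",
           organ_overrides = list(gut = list(blood_flow_ml_min = 2.0)))
  q_lung <- ph2$organs["lung", "blood_flow_ml_min"]
  q_sys <- sum(ph2$organs$blood_flow_ml_min[ph2$organs$name != "lung"])
  expect_lt(abs(q_lung - q_sys) / q_lung, 1e-9)

  expect_error(get_species_physiology("mouse",
                 organ_overrides = list(tail = list(volume_ml = 1))),
               "unknown organ")
})

test_that("physiology JSON serialization round-trips", {
  ph <- get_species_physiology("mouse")
  path <- withr::local_tempfile(fileext = ".json")
  write_physiology(ph, path)
  back <- read_physiology(path)
  expect_equal(back$organs$volume_ml, ph$organs$volume_ml)
  expect_equal(back$organs$blood_flow_ml_min, ph$organs$blood_flow_ml_min)
  expect_equal(back$hematocrit, ph$hematocrit)
  expect_equal(back$saliva_volume_ml, ph$saliva_volume_ml)
})

test_that("structural invariants are enforced", {
  organs <- data.frame(name = c("lung", "rest_of_body"), volume_ml = c(1, 10),
                       blood_flow_ml_min = c(5, 5), f_vas = 0.1,
                       f_water = 0.7, f_lipid = 0.2, f_protein = 0.05,
                       eor_abundance = 0, stringsAsFactors = FALSE)
  ok <- physiology("toy", 1, 0.45, organs, 0.01, 0.1, 0.1,
                   require_full_organ_set = FALSE)
  expect_s3_class(ok, "physiology")

  bad_comp <- organs
  bad_comp$f_lipid <- 0.4   # water + lipid + protein > 1
  expect_error(physiology("toy", 1, 0.45, bad_comp, 0.01, 0.1, 0.1,
                          require_full_organ_set = FALSE), "<= 1")

  bad_flow <- organs
  bad_flow$blood_flow_ml_min <- c(5, 4)
  expect_error(physiology("toy", 1, 0.45, bad_flow, 0.01, 0.1, 0.1,
                          require_full_organ_set = FALSE), "not conserved")

  expect_error(physiology("toy", 1, 1.2, organs, 0.01, 0.1, 0.1,
                          require_full_organ_set = FALSE), "hematocrit")
})
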