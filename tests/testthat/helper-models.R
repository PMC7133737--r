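# Shared builders for toy and reference models used across the suite.

# Minimal whole-body topology: lung in series plus one or two systemic
# organs; fast flows and small blood pools so the system approaches its
# one-compartment limit. All-water composition gives K_organ = 1.
toy_physiology <- function(v_organ = 1000, q_blood_ml_min = 3e4,
                           v_lung = 0.5, v_pool = 0.1,
                           f_water = 1, f_lipid = 0, f_protein = 0,
                           with_salivary_gland = FALSE) {
  organs <- data.frame(
    name = c("lung", "rest_of_body"),
    volume_ml = c(v_lung, v_organ),
    blood_flow_ml_min = c(q_blood_ml_min, q_blood_ml_min),
    f_vas = 0.1, f_water = f_water, f_lipid = f_lipid,
    f_protein = f_protein, eor_abundance = c(0, 1),
    stringsAsFactors = FALSE)
  if (with_salivary_gland) {
    sg <- organs[2, ]
    sg$name <- "salivary_gland"
    sg$volume_ml <- 1
    sg$blood_flow_ml_min <- 0.02 * q_blood_ml_min
    sg$eor_abundance <- 0
    organs$blood_flow_ml_min[2] <- 0.98 * q_blood_ml_min
    organs <- rbind(organs, sg)
  }
  physiology(species = "toy", body_weight_kg = 1, hematocrit = 0.45,
             organs = organs, saliva_volume_ml = 0.001,
             arterial_volume_ml = v_pool, venous_volume_ml = v_pool,
             require_full_organ_set = FALSE)
}

# Neutral tracer: no binding, no lipid partitioning.
tracer_compound <- function(fu = 1, logP = 0) {
  compound("tracer", molecular_weight_g_mol = 300, logP = logP, pKa = 7,
           solubility_pH74_mg_ml = 1, fu_plasma = fu)
}

mouse_model <- function(cl_ml_min_kg = 4.58, ...) {
  build_model(get_species_physiology("mouse"), load_compound("at_rvd1"),
              clearance_spec("calibrated_total",
                             total_plasma_clearance_ml_min_kg = cl_ml_min_kg),
              ...)
}

# Mouse model with the endothelial-barrier (permeability-limited) transport
# mode on all systemic organs, PS = P x SA with SA from the organ
# vascularization rule.
mouse_barrier_model <- function(p_per_unit_sa = 1, cl_ml_min_kg = 4.58) {
  phys <- get_species_physiology("mouse")
  org <- phys$organs
  sa <- vapply(seq_len(nrow(org)), function(i)
    endothelial_surface_area(1, org$f_vas[i], org$volume_ml[i]), numeric(1))
  ps <- setNames(p_per_unit_sa * sa, org$name)
  build_model(phys, load_compound("at_rvd1"),
              clearance_spec("calibrated_total",
                             total_plasma_clearance_ml_min_kg = cl_ml_min_kg),
              permeability = ps[setdiff(org$name, "lung")])
}

expect_rel <- function(actual, expected, tol) {
  testthat::expect_lt(abs(actual / expected - 1), tol)
}
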