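# Compound parameterization and distribution/elimination primitives:
# endothelial surface area (organ vascularization rule), tissue-to-plasma
# partition coefficients from tissue composition, and the eicosanoid
# oxidoreductase (EOR) Michaelis-Menten elimination rate.

# Plasma protein volume fraction used when deriving the protein/water
# partition coefficient from fu_plasma (plasma is ~6% protein by volume).
F_PROTEIN_PLASMA <- 0.06

#' Define a compound
#'
#' Physicochemical and binding parameters of a drug. The shipped fixture
#' for AT-RvD1 is available via [load_compound()]; `fu_plasma` for AT-RvD1
#' has never been measured, so the fixture value (0.05) is flagged as an
#' assumption and propagated into run manifests.
#'
#' @param name compound name.
#' @param molecular_weight_g_mol molecular weight (> 0).
#' @param logP octanol/water log partition coefficient.
#' @param pKa acid dissociation constant (carried as metadata; ionization
#'   partitioning is out of scope).
#' @param solubility_pH74_mg_ml aqueous solubility at pH 7.4 (> 0).
#' @param fu_plasma fraction unbound in plasma, (0, 1]. Required: no silent
#'   default exists.
#' @param binding_protein plasma binding protein label.
#' @param fu_plasma_assumed flag recorded in run manifests.
#' @return an object of class `compound`.
#' @export
compound <- function(name, molecular_weight_g_mol, logP, pKa,
                     solubility_pH74_mg_ml, fu_plasma,
                     binding_protein = "albumin", fu_plasma_assumed = FALSE) {
  check_number(molecular_weight_g_mol, "molecular_weight_g_mol",
               lower = 0, strict_lower = TRUE)
  check_number(logP, "logP")
  check_number(pKa, "pKa")
  check_number(solubility_pH74_mg_ml, "solubility_pH74_mg_ml",
               lower = 0, strict_lower = TRUE)
  check_number(fu_plasma, "fu_plasma", lower = 0, upper = 1, strict_lower = TRUE)
  structure(list(name = name,
                 molecular_weight_g_mol = molecular_weight_g_mol,
                 logP = logP, pKa = pKa,
                 solubility_pH74_mg_ml = solubility_pH74_mg_ml,
                 fu_plasma = fu_plasma, binding_protein = binding_protein,
                 fu_plasma_assumed = isTRUE(fu_plasma_assumed)),
            class = "compound")
}

#' Load a compound fixture or config file
#'
#' `load_compound("at_rvd1")` returns the shipped AT-RvD1 parameter set;
#' any other argument is treated as a path to a JSON file with the same
#' fields as [compound()].
#'
#' @param what fixture name or file path.
#' @return a `compound`.
#' @export
load_compound <- function(what = "at_rvd1") {
  path <- if (identical(what, "at_rvd1")) extdata("at_rvd1.json") else what
  raw <- jsonlite::fromJSON(path)
  compound(name = raw$name,
           molecular_weight_g_mol = raw$molecular_weight_g_mol,
           logP = raw$logP, pKa = raw$pKa,
           solubility_pH74_mg_ml = raw$solubility_pH74_mg_ml,
           fu_plasma = raw$fu_plasma,
           binding_protein = raw$binding_protein,
           fu_plasma_assumed = isTRUE(raw$fu_plasma_assumed))
}

#' @export
print.compound <- function(x, ...) {
  cat(sprintf("<compound> %s: MW %.3f g/mol, logP %.2f, pKa %.2f, fu %.3g%s\n",
              x$name, x$molecular_weight_g_mol, x$logP, x$pKa, x$fu_plasma,
              if (x$fu_plasma_assumed) " (assumed)" else ""))
  invisible(x)
}

#' Clearance specification
#'
#' Either a calibrated total plasma clearance (ml/min/kg, allocated to the
#' eliminating organs in proportion to their blood flows) or mechanistic
#' Michaelis-Menten elimination by eicosanoid oxidoreductase (EOR) with
#' per-organ relative abundances from the physiology.
#'
#' @param mode `"calibrated_total"` or `"enzymatic"`.
#' @param total_plasma_clearance_ml_min_kg total plasma clearance
#'   (calibrated mode, >= 0; zero gives a closed, mass-conserving system).
#' @param vmax_ng_min maximal elimination rate per unit enzyme abundance
#'   (enzymatic mode, > 0).
#' @param km_ng_ml Michaelis constant on unbound plasma concentration
#'   (enzymatic mode, > 0).
#' @return an object of class `clearance_spec`.
#' @export
clearance_spec <- function(mode = c("calibrated_total", "enzymatic"),
                           total_plasma_clearance_ml_min_kg = NULL,
                           vmax_ng_min = NULL, km_ng_ml = NULL) {
  mode <- match.arg(mode)
  if (mode == "calibrated_total") {
    # zero is admitted: it degenerates to a closed (conservative) system
    check_number(total_plasma_clearance_ml_min_kg,
                 "total_plasma_clearance_ml_min_kg", lower = 0)
  } else {
    check_number(vmax_ng_min, "vmax_ng_min", lower = 0, strict_lower = TRUE)
    check_number(km_ng_ml, "km_ng_ml", lower = 0, strict_lower = TRUE)
  }
  structure(list(mode = mode,
                 total_plasma_clearance_ml_min_kg = total_plasma_clearance_ml_min_kg,
                 vmax_ng_min = vmax_ng_min, km_ng_ml = km_ng_ml),
            class = "clearance_spec")
}

#' Capillary endothelial surface area (organ vascularization rule)
#'
#' `SA = k * f_vas * V_organ`: surface area available for permeation across
#' the endothelial barrier, proportional to the vascular fraction of the
#' organ volume. Used by the optional permeability-limited transport mode.
#'
#' @param k proportionality constant (per ml of vascular space).
#' @param f_vas fraction of organ volume that is vascular space.
#' @param v_organ_ml organ volume (ml).
#' @return surface area in units of `k` times ml.
#' @examples endothelial_surface_area(1, 0.1, 10) # 1
#' @export
endothelial_surface_area <- function(k, f_vas, v_organ_ml) {
  check_number(k, "k", lower = 0)
  check_number(f_vas, "f_vas", lower = 0, upper = 1)
  check_number(v_organ_ml, "v_organ_ml", lower = 0)
  k * f_vas * v_organ_ml
}

#' Lipid/water partition coefficient from lipophilicity
#'
#' The minimal octanol/water reading: `K_lipid = 10^logP`. Override-able in
#' [build_model()] for users with a measured membrane affinity.
#'
#' @param logP log10 octanol/water partition coefficient.
#' @return dimensionless lipid/water partition coefficient.
#' @export
lipid_water_partition <- function(logP) {
  check_number(logP, "logP")
  10^logP
}

#' Protein/water partition coefficient from plasma binding
#'
#' Chosen so that the plasma compartment's own protein binding is
#' self-consistent with the fraction unbound:
#' `K_protein = (1/fu_plasma - 1) / f_protein_plasma`. With `fu = 1` (no
#' binding) the coefficient is zero.
#'
#' @param fu_plasma fraction unbound in plasma, (0, 1].
#' @param f_protein_plasma protein volume fraction of plasma (default 0.06).
#' @return dimensionless protein/water partition coefficient.
#' @export
protein_water_partition <- function(fu_plasma, f_protein_plasma = F_PROTEIN_PLASMA) {
  check_number(fu_plasma, "fu_plasma", lower = 0, upper = 1, strict_lower = TRUE)
  check_number(f_protein_plasma, "f_protein_plasma", lower = 0, upper = 1,
               strict_lower = TRUE, strict_upper = TRUE)
  (1 / fu_plasma - 1) / f_protein_plasma
}

#' Tissue-to-plasma partition coefficient from tissue composition
#'
#' The composition-based rule
#' `K_organ = f_water + K_lipid * f_lipid + K_protein * f_protein * fu_plasma`,
#' with the unbound fraction scaling the protein term only (the printed
#' form). `fu_scales_all = TRUE` exposes the alternative precedence in which
#' `fu_plasma` multiplies the whole sum.
#'
#' @param f_water,f_lipid,f_protein organ volume fractions (>= 0).
#' @param k_lipid lipid/water partition coefficient (>= 0).
#' @param k_protein protein/water partition coefficient (>= 0).
#' @param fu_plasma fraction unbound in plasma, (0, 1].
#' @param fu_scales_all precedence switch, see Details.
#' @return dimensionless tissue-to-plasma partition coefficient.
#' @examples
#' organ_partition_coefficient(1, 0, 0, 10, 5, 0.5)               # 1
#' organ_partition_coefficient(0.7, 0.1, 0.2, 10, 5, 0.5)         # 2.2
#' @export
organ_partition_coefficient <- function(f_water, f_lipid, f_protein,
                                        k_lipid, k_protein, fu_plasma,
                                        fu_scales_all = FALSE) {
  for (v in c("f_water", "f_lipid", "f_protein", "k_lipid", "k_protein"))
    check_number(get(v), v, lower = 0)
  check_number(fu_plasma, "fu_plasma", lower = 0, upper = 1)
  core <- f_water + k_lipid * f_lipid
  if (isTRUE(fu_scales_all))
    fu_plasma * (core + k_protein * f_protein)
  else
    core + k_protein * f_protein * fu_plasma
}

#' Michaelis-Menten elimination rate by eicosanoid oxidoreductase
#'
#' `rate = abundance * Vmax * Cu / (Km + Cu)` where `Cu` is the unbound
#' plasma concentration in the metabolizing organ. At trace concentrations
#' (`Cu << Km`) this reduces to a linear intrinsic clearance
#' `abundance * (Vmax/Km) * Cu`.
#'
#' @param clearance an enzymatic-mode [clearance_spec()].
#' @param c_unbound_ng_ml unbound plasma concentration (ng/ml, >= 0).
#' @param abundance relative enzyme abundance in the organ (>= 0).
#' @return elimination rate in ng/min.
#' @export
enzymatic_rate <- function(clearance, c_unbound_ng_ml, abundance = 1) {
  stopifnot(inherits(clearance, "clearance_spec"))
  if (clearance$mode != "enzymatic")
    stop_domain("enzymatic_rate requires an enzymatic-mode clearance_spec")
  check_number(c_unbound_ng_ml, "c_unbound_ng_ml", lower = 0)
  check_number(abundance, "abundance", lower = 0)
  abundance * clearance$vmax_ng_min * c_unbound_ng_ml /
    (clearance$km_ng_ml + c_unbound_ng_ml)
}
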