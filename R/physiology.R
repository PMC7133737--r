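# Species physiology registry and allometric scaling.
#
# A physiology is the body-level description a whole-body PBPK model is
# assembled from: per-organ volumes, blood flows, vascularization and tissue
# composition, plus hematocrit, blood-pool volumes and a saliva volume.
# Reference fixtures for the NOD/ShiLtJ mouse and an 80.35 kg adult human are
# shipped as JSON under extdata; values not available in the literature are
# package defaults flagged `source = "default"` and can be overridden.

REQUIRED_ORGANS <- c("lung", "heart", "brain", "kidney", "liver", "spleen",
                     "gut", "muscle", "skin", "adipose", "bone", "gonads",
                     "pancreas", "salivary_gland", "rest_of_body")

ORGAN_COLUMNS <- c("name", "volume_ml", "blood_flow_ml_min", "f_vas",
                   "f_water", "f_lipid", "f_protein", "eor_abundance",
                   "source")

#' Construct a physiology object
#'
#' Builds and validates the body-level parameter set used by
#' [build_model()]. Most users will start from [get_species_physiology()]
#' rather than calling this directly.
#'
#' @param species species identifier string.
#' @param body_weight_kg body weight in kg.
#' @param hematocrit volume fraction of red cells in blood (0, 1).
#' @param organs data frame with columns `name`, `volume_ml`,
#'   `blood_flow_ml_min`, `f_vas`, `f_water`, `f_lipid`, `f_protein`,
#'   `eor_abundance` and optionally `source`.
#' @param saliva_volume_ml saliva compartment volume (ml).
#' @param arterial_volume_ml,venous_volume_ml blood-pool volumes (ml).
#' @param bmi_kg_m2 optional body mass index.
#' @param require_full_organ_set if `TRUE` (the species fixtures) every organ
#'   of the standard whole-body topology must be present; toy physiologies
#'   used for reductions may set this `FALSE` (lung plus at least one
#'   systemic organ is always required).
#' @param age_years,sex optional covariates carried as metadata.
#'
#' @return an object of class `physiology`.
#' @export
physiology <- function(species, body_weight_kg, hematocrit, organs,
                       saliva_volume_ml, arterial_volume_ml, venous_volume_ml,
                       bmi_kg_m2 = NULL, require_full_organ_set = TRUE,
                       age_years = NULL, sex = NULL) {
  check_number(body_weight_kg, "body_weight_kg", lower = 0, strict_lower = TRUE)
  check_number(hematocrit, "hematocrit", lower = 0, upper = 1,
               strict_lower = TRUE, strict_upper = TRUE)
  check_number(saliva_volume_ml, "saliva_volume_ml", lower = 0, strict_lower = TRUE)
  check_number(arterial_volume_ml, "arterial_volume_ml", lower = 0, strict_lower = TRUE)
  check_number(venous_volume_ml, "venous_volume_ml", lower = 0, strict_lower = TRUE)
  organs <- as.data.frame(organs, stringsAsFactors = FALSE)
  if (!"source" %in% names(organs)) organs$source <- "user"
  missing_cols <- setdiff(ORGAN_COLUMNS, names(organs))
  if (length(missing_cols))
    stop_domain("organ table lacks columns: ", paste(missing_cols, collapse = ", "))
  organs <- organs[, ORGAN_COLUMNS]
  rownames(organs) <- organs$name

  obj <- structure(
    list(species = species, body_weight_kg = body_weight_kg,
         bmi_kg_m2 = bmi_kg_m2, hematocrit = hematocrit, organs = organs,
         saliva_volume_ml = saliva_volume_ml,
         arterial_volume_ml = arterial_volume_ml,
         venous_volume_ml = venous_volume_ml,
         age_years = age_years, sex = sex,
         require_full_organ_set = isTRUE(require_full_organ_set)),
    class = "physiology")
  validate_physiology(obj)
  obj
}

#' Validate a physiology object
#'
#' Checks the structural invariants: positive volumes, non-negative flows,
#' fractions within bounds, tissue composition fractions summing to at most
#' one, and conservation of blood flow (lung flow equals the sum of the
#' systemic organ flows, to 1e-9 relative).
#'
#' @param phys a `physiology` object.
#' @return `phys`, invisibly; errors describe the first violated invariant.
#' @export
validate_physiology <- function(phys) {
  stopifnot(inherits(phys, "physiology"))
  org <- phys$organs
  if (anyDuplicated(org$name))
    stop_domain("duplicated organ names in physiology")
  if (!"lung" %in% org$name)
    stop_domain("physiology must contain a lung compartment")
  if (nrow(org) < 2L)
    stop_domain("physiology needs lung plus at least one systemic organ")
  if (phys$require_full_organ_set) {
    missing <- setdiff(REQUIRED_ORGANS, org$name)
    if (length(missing))
      stop_domain("physiology is missing required organs: ",
                  paste(missing, collapse = ", "))
  }
  incomplete <- org$name[!stats::complete.cases(
    org[, c("volume_ml", "blood_flow_ml_min", "f_vas", "f_water", "f_lipid",
            "f_protein", "eor_abundance")])]
  if (length(incomplete))
    stop_domain("missing organ parameter value(s) for organ(s): ",
                paste(incomplete, collapse = ", "))
  if (any(org$volume_ml <= 0))
    stop_domain("all organ volumes must be > 0")
  if (any(org$blood_flow_ml_min < 0))
    stop_domain("organ blood flows must be >= 0")
  if (any(org$f_vas < 0 | org$f_vas > 1))
    stop_domain("f_vas must lie in [0, 1]")
  comp <- org$f_water + org$f_lipid + org$f_protein
  if (any(org$f_water < 0 | org$f_lipid < 0 | org$f_protein < 0))
    stop_domain("tissue composition fractions must be >= 0")
  if (any(comp > 1 + 1e-12))
    stop_domain("f_water + f_lipid + f_protein must be <= 1 (organ ",
                paste(org$name[comp > 1 + 1e-12], collapse = ", "), ")")
  if (any(org$eor_abundance < 0))
    stop_domain("eor_abundance must be >= 0")
  q_lung <- org["lung", "blood_flow_ml_min"]
  q_sys <- sum(org$blood_flow_ml_min[org$name != "lung"])
  if (rel_diff(q_lung, q_sys) > 1e-9)
    stop_domain(sprintf(
      "blood flow not conserved: lung %.9g vs systemic sum %.9g ml/min",
      q_lung, q_sys))
  invisible(phys)
}

load_physiology_json <- function(path) {
  raw <- jsonlite::fromJSON(path)
  physiology(
    species = raw$species,
    body_weight_kg = raw$body_weight_kg,
    bmi_kg_m2 = raw$bmi_kg_m2,
    hematocrit = raw$hematocrit,
    organs = raw$organs,
    saliva_volume_ml = raw$saliva_volume_ml,
    arterial_volume_ml = raw$arterial_volume_ml,
    venous_volume_ml = raw$venous_volume_ml)
}

SPECIES_ALIASES <- list(
  mouse_nod_shiltj = c("mouse", "mouse_nod_shiltj", "nod/shiltj", "nod_shiltj"),
  human_adult = c("human", "human_adult"))

#' Retrieve a species reference physiology
#'
#' Returns the fully populated reference physiology for one of the two
#' supported species. Named-organ values (brain, heart, kidney, liver, lung,
#' spleen), body weight, hematocrit and saliva volume are literature values;
#' the remaining organs of the 15-organ whole-body topology carry documented
#' package defaults (flagged in the `source` column) which can be overridden
#' via `organ_overrides`.
#'
#' @param species `"mouse"` (NOD/ShiLtJ) or `"human"` (adult, 80.35 kg).
#' @param organ_overrides optional named list: per organ, a named list of
#'   column values to replace (e.g. `list(adipose = list(volume_ml = 2.1))`).
#' @return a `physiology` object.
#' @examples
#' mouse <- get_species_physiology("mouse")
#' mouse$hematocrit            # 0.45
#' mouse$saliva_volume_ml      # 0.00226
#' @export
get_species_physiology <- function(species, organ_overrides = NULL) {
  key <- tolower(trimws(species))
  match <- names(SPECIES_ALIASES)[vapply(SPECIES_ALIASES, function(a) key %in% a, logical(1))]
  if (length(match) != 1L)
    stop_domain("unsupported species '", species,
                "'; supported: mouse (NOD/ShiLtJ), human (adult)")
  phys <- load_physiology_json(extdata(paste0(match, ".json")))
  if (!is.null(organ_overrides)) {
    for (org in names(organ_overrides)) {
      if (!org %in% phys$organs$name)
        stop_domain("override names unknown organ '", org, "'")
      for (col in names(organ_overrides[[org]])) {
        if (!col %in% ORGAN_COLUMNS || col %in% c("name", "source"))
          stop_domain("cannot override organ column '", col, "'")
        phys$organs[org, col] <- organ_overrides[[org]][[col]]
        phys$organs[org, "source"] <- "user"
      }
    }
    # keep flow conservation by absorbing any flow edit into rest_of_body
    q_lung <- phys$organs["lung", "blood_flow_ml_min"]
    sys <- setdiff(phys$organs$name, c("lung", "rest_of_body"))
    q_rest <- q_lung - sum(phys$organs[sys, "blood_flow_ml_min"])
    if (q_rest < 0)
      stop_domain("organ flow overrides exceed lung (cardiac output) flow")
    phys$organs["rest_of_body", "blood_flow_ml_min"] <- q_rest
    validate_physiology(phys)
  }
  phys
}

#' Allometric scaling of a physiology to a new body weight
#'
#' Organ, blood-pool and saliva volumes scale linearly with body weight
#' (exponent 1); blood flows scale with the standard allometric exponent
#' 0.75. Hematocrit and tissue composition are unchanged. Scaling back to
#' the reference weight is the identity.
#'
#' @param base reference `physiology`.
#' @param body_weight_kg target body weight (> 0).
#' @param age_years,sex optional covariates recorded as metadata (human
#'   populations map age and sex to body weight before calling this).
#' @return a scaled, validated `physiology`.
#' @export
scale_physiology <- function(base, body_weight_kg, age_years = NULL, sex = NULL) {
  stopifnot(inherits(base, "physiology"))
  check_number(body_weight_kg, "body_weight_kg", lower = 0, strict_lower = TRUE)
  r <- body_weight_kg / base$body_weight_kg
  out <- base
  out$organs$volume_ml <- base$organs$volume_ml * r
  out$organs$blood_flow_ml_min <- base$organs$blood_flow_ml_min * r^0.75
  out$saliva_volume_ml <- base$saliva_volume_ml * r
  out$arterial_volume_ml <- base$arterial_volume_ml * r
  out$venous_volume_ml <- base$venous_volume_ml * r
  out$body_weight_kg <- body_weight_kg
  out$age_years <- age_years
  out$sex <- sex
  validate_physiology(out)
  out
}

#' @export
print.physiology <- function(x, ...) {
  cat(sprintf("<physiology> %s: %.4g kg, hematocrit %.2f, %d organs + saliva (%.4g ml)\n",
              x$species, x$body_weight_kg, x$hematocrit, nrow(x$organs),
              x$saliva_volume_ml))
  invisible(x)
}

#' Write a physiology to a JSON config file
#'
#' The serialized form round-trips through [read_physiology()].
#'
#' @param phys a `physiology`.
#' @param path output file path.
#' @export
write_physiology <- function(phys, path) {
  stopifnot(inherits(phys, "physiology"))
  jsonlite::write_json(
    list(species = phys$species, body_weight_kg = phys$body_weight_kg,
         bmi_kg_m2 = phys$bmi_kg_m2, hematocrit = phys$hematocrit,
         saliva_volume_ml = phys$saliva_volume_ml,
         arterial_volume_ml = phys$arterial_volume_ml,
         venous_volume_ml = phys$venous_volume_ml,
         organs = phys$organs),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE, null = "null")
  invisible(path)
}

#' Read a physiology from a JSON config file
#' @param path file written by [write_physiology()] or a fixture.
#' @return a `physiology` object.
#' @export
read_physiology <- function(path) load_physiology_json(path)
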