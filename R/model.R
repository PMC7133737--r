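# Assembly of the whole-body compartment model: organs connected through
# arterial and venous blood pools, lung bridging the venous return to the
# arterial supply, a first-order saliva compartment coupled to salivary-gland
# plasma, and clearance allocated to eliminating organs.

#' Intravenous bolus dose event
#'
#' @param amount_mg_per_kg dose in mg per kg body weight (> 0).
#' @param route only `"iv_bolus"` is supported (single bolus).
#' @param time_hr dose time; must coincide with the simulation start.
#' @return an object of class `dose_event`.
#' @export
dose_event <- function(amount_mg_per_kg, route = "iv_bolus", time_hr = 0) {
  if (!identical(route, "iv_bolus"))
    stop_domain("unsupported route '", route, "'; only iv_bolus is implemented")
  check_number(amount_mg_per_kg, "amount_mg_per_kg", lower = 0, strict_lower = TRUE)
  check_number(time_hr, "time_hr", lower = 0)
  structure(list(route = route, amount_mg_per_kg = amount_mg_per_kg,
                 time_hr = time_hr), class = "dose_event")
}

#' Simulation settings
#'
#' @param t_start_hr,t_end_hr simulation window (hours); default 0 to 24.
#' @param grid_step_hr reporting grid step (hours); the default 0.05 hr
#'   (3 min) resolves the early post-bolus maximum.
#' @param output_times_hr explicit strictly increasing output grid; overrides
#'   `grid_step_hr` when given.
#' @param rtol,atol relative/absolute solver tolerances (lsoda).
#' @param seed random seed recorded for population use.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(t_start_hr = 0, t_end_hr = 24, grid_step_hr = 0.05,
                       output_times_hr = NULL, rtol = 1e-10, atol = 1e-8,
                       seed = NULL) {
  check_number(t_start_hr, "t_start_hr")
  check_number(t_end_hr, "t_end_hr")
  if (t_start_hr >= t_end_hr) stop_domain("t_start_hr must be < t_end_hr")
  check_number(rtol, "rtol", lower = 0, strict_lower = TRUE)
  check_number(atol, "atol", lower = 0, strict_lower = TRUE)
  if (is.null(output_times_hr)) {
    check_number(grid_step_hr, "grid_step_hr", lower = 0, strict_lower = TRUE)
    output_times_hr <- seq(t_start_hr, t_end_hr, by = grid_step_hr)
  }
  if (any(diff(output_times_hr) <= 0))
    stop_domain("output grid must be strictly increasing")
  structure(list(t_start_hr = t_start_hr, t_end_hr = t_end_hr,
                 output_times_hr = output_times_hr, rtol = rtol, atol = atol,
                 seed = seed), class = "sim_config")
}

#' Assemble a whole-body PBPK model
#'
#' Computes one tissue-to-plasma partition coefficient per organ from its
#' composition ([organ_partition_coefficient()]), allocates clearance, and
#' wires the compartment graph (organs in parallel between the arterial and
#' venous pools, lung in series on the venous return, saliva coupled to the
#' salivary gland). Distribution is perfusion-limited by default; individual
#' organs may be switched to permeability-limited transport by supplying a
#' permeability-surface-area product.
#'
#' In calibrated mode the total plasma clearance (ml/min/kg x body weight)
#' is shared among `eliminating_organs` in proportion to their blood flows,
#' and each organ share is converted to an intrinsic clearance by the
#' well-stirred relation `CLint = CL * Qp / (Qp - CL)` so that the effective
#' whole-body plasma clearance equals the calibrated value exactly. A share
#' exceeding the organ's plasma flow is physically undeliverable and raises
#' an error; `eliminating_organs = "systemic"` spreads the load over all
#' systemic organs instead.
#'
#' @param physiology a `physiology`.
#' @param compound a `compound`.
#' @param clearance a `clearance_spec`.
#' @param eliminating_organs organs receiving calibrated clearance
#'   (default liver and kidney), or the string `"systemic"`.
#' @param k_lipid,k_protein optional overrides of the derived lipid/water
#'   and protein/water partition coefficients.
#' @param fu_scales_all partition-rule precedence switch, see
#'   [organ_partition_coefficient()].
#' @param saliva_rate_per_hr first-order saliva equilibration rate (1/hr).
#' @param saliva_partition saliva:plasma partition coefficient; default is
#'   the unbound fraction (saliva equilibrates with unbound plasma drug).
#' @param permeability optional named numeric vector of
#'   permeability-surface-area products (ml/min) switching those organs to
#'   permeability-limited transport.
#' @return an object of class `pbpk_model`.
#' @export
build_model <- function(physiology, compound, clearance,
                        eliminating_organs = c("liver", "kidney"),
                        k_lipid = NULL, k_protein = NULL,
                        fu_scales_all = FALSE,
                        saliva_rate_per_hr = 10, saliva_partition = NULL,
                        permeability = NULL) {
  stopifnot(inherits(physiology, "physiology"), inherits(compound, "compound"),
            inherits(clearance, "clearance_spec"))
  validate_physiology(physiology)
  org <- physiology$organs
  fu <- compound$fu_plasma

  incomplete <- org$name[!stats::complete.cases(
    org[, c("f_water", "f_lipid", "f_protein")])]
  if (length(incomplete))
    stop_domain("missing tissue composition for organ(s): ",
                paste(incomplete, collapse = ", "))

  if (is.null(k_lipid)) k_lipid <- lipid_water_partition(compound$logP)
  if (is.null(k_protein)) k_protein <- protein_water_partition(fu)
  k_organ <- setNames(mapply(organ_partition_coefficient,
                             org$f_water, org$f_lipid, org$f_protein,
                             MoreArgs = list(k_lipid = k_lipid,
                                             k_protein = k_protein,
                                             fu_plasma = fu,
                                             fu_scales_all = fu_scales_all)),
                      org$name)
  if (any(k_organ <= 0))
    stop_domain("non-positive partition coefficient for organ(s): ",
                paste(org$name[k_organ <= 0], collapse = ", "))

  qp <- setNames(org$blood_flow_ml_min * (1 - physiology$hematocrit), org$name)
  systemic <- setdiff(org$name, "lung")

  clint <- setNames(rep(0, nrow(org)), org$name)
  cl_total_ml_min <- NULL
  if (clearance$mode == "calibrated_total") {
    cl_total_ml_min <- clearance$total_plasma_clearance_ml_min_kg *
      physiology$body_weight_kg
    elim <- if (identical(eliminating_organs, "systemic")) systemic
            else eliminating_organs
    missing <- setdiff(elim, org$name)
    if (length(missing))
      stop_domain("eliminating organ(s) not in physiology: ",
                  paste(missing, collapse = ", "))
    q_elim <- org[elim, "blood_flow_ml_min"]
    share <- cl_total_ml_min * q_elim / sum(q_elim)
    infeasible <- share >= qp[elim]
    if (any(infeasible))
      stop_domain("calibrated clearance share exceeds organ plasma flow for: ",
                  paste(elim[infeasible], collapse = ", "),
                  "; the requested total plasma clearance cannot be delivered ",
                  "by these organs' plasma flows - spread it with ",
                  "eliminating_organs = \"systemic\" or lower the value")
    clint[elim] <- share * qp[elim] / (qp[elim] - share)
    eliminating <- elim
  } else {
    eliminating <- org$name[org$eor_abundance > 0]
    if (!length(eliminating))
      stop_domain("enzymatic mode requires eor_abundance > 0 in some organ")
  }

  if (!is.null(permeability)) {
    bad <- setdiff(names(permeability), systemic)
    if (length(bad))
      stop_domain("permeability-limited flag on unknown/unsupported organ(s): ",
                  paste(bad, collapse = ", "))
    if (any(permeability <= 0)) stop_domain("PS products must be > 0")
  }

  if (is.null(saliva_partition)) saliva_partition <- fu
  check_number(saliva_rate_per_hr, "saliva_rate_per_hr", lower = 0)
  check_number(saliva_partition, "saliva_partition", lower = 0)

  structure(list(topology = "whole_body",
                 physiology = physiology, compound = compound,
                 clearance = clearance, k_lipid = k_lipid,
                 k_protein = k_protein, k_organ = k_organ,
                 qp_ml_min = qp, clint_ml_min = clint,
                 eliminating_organs = eliminating,
                 cl_total_ml_min = cl_total_ml_min,
                 fu_scales_all = isTRUE(fu_scales_all),
                 saliva_rate_per_hr = saliva_rate_per_hr,
                 saliva_partition = saliva_partition,
                 permeability_ml_min = permeability),
            class = "pbpk_model")
}

#' One-compartment reduction
#'
#' The single-compartment limit of the whole-body model: one well-stirred
#' volume with first-order elimination, `dA/dt = -(CL/V) A`. Used for
#' closed-form verification, terminal half-life identities and analytic
#' sensitivity checks.
#'
#' @param v_l_kg apparent volume of distribution (L/kg).
#' @param cl_ml_min_kg total plasma clearance (ml/min/kg).
#' @param body_weight_kg body weight (kg).
#' @return an object of class `pbpk_model` with `topology = "one_compartment"`.
#' @export
one_compartment_model <- function(v_l_kg, cl_ml_min_kg, body_weight_kg = 1) {
  check_number(v_l_kg, "v_l_kg", lower = 0, strict_lower = TRUE)
  check_number(cl_ml_min_kg, "cl_ml_min_kg", lower = 0)
  check_number(body_weight_kg, "body_weight_kg", lower = 0, strict_lower = TRUE)
  structure(list(topology = "one_compartment",
                 volume_ml = v_l_kg * 1000 * body_weight_kg,
                 cl_ml_min = cl_ml_min_kg * body_weight_kg,
                 body_weight_kg = body_weight_kg,
                 cl_total_ml_min = cl_ml_min_kg * body_weight_kg),
            class = "pbpk_model")
}

#' @export
print.pbpk_model <- function(x, ...) {
  if (x$topology == "one_compartment") {
    cat(sprintf("<pbpk_model> one-compartment: V %.4g ml, CL %.4g ml/min\n",
                x$volume_ml, x$cl_ml_min))
  } else {
    cat(sprintf("<pbpk_model> whole-body %s: %d organs + 2 blood pools + saliva; %s clearance (%s)\n",
                x$physiology$species, length(x$k_organ), x$clearance$mode,
                paste(x$eliminating_organs, collapse = ", ")))
  }
  invisible(x)
}

model_body_weight <- function(model) {
  if (model$topology == "one_compartment") model$body_weight_kg
  else model$physiology$body_weight_kg
}

#' Initial compartment amounts after an IV bolus
#'
#' Places the full dose (`amount_mg_per_kg * body_weight`, in ng) in the
#' venous blood pool; all other compartments start at zero.
#'
#' @param model a `pbpk_model`.
#' @param dose a [dose_event()].
#' @param body_weight_kg body weight; defaults to the model's physiology.
#' @return named numeric vector of initial amounts (ng) per state.
#' @export
apply_dose <- function(model, dose, body_weight_kg = model_body_weight(model)) {
  stopifnot(inherits(model, "pbpk_model"), inherits(dose, "dose_event"))
  check_number(body_weight_kg, "body_weight_kg", lower = 0, strict_lower = TRUE)
  dose_ng <- dose$amount_mg_per_kg * 1e6 * body_weight_kg
  states <- state_names(model)
  y0 <- setNames(rep(0, length(states)), states)
  y0[if (model$topology == "one_compartment") "central" else "venous"] <- dose_ng
  attr(y0, "dose_ng") <- dose_ng
  y0
}

state_names <- function(model) {
  if (model$topology == "one_compartment") return(c("central", "eliminated"))
  org <- model$physiology$organs$name
  perm <- names(model$permeability_ml_min)
  nm <- character(0)
  for (o in org) {
    nm <- c(nm, o)
    if (o %in% perm) nm <- c(nm, paste0(o, "_tissue"))
  }
  c(nm, "arterial", "venous", "saliva", "eliminated")
}
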