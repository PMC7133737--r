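# Variation-factor local sensitivity analysis. Each model input parameter
# is multiplied by a set of variation factors f; for every factor the
# relative output change is normalized by the relative input change,
#   S_f = (y(f p) / y(p) - 1) / (f - 1),
# and the reported sensitivity is the mean of S_f over the factors. Outputs
# are AUC0-inf and total body clearance (dose/AUC0-inf), each obtained by a
# full simulation plus NCA of the perturbed model.

#' Describe a perturbable model configuration
#'
#' Bundles the inputs [build_model()] needs so the sensitivity machinery can
#' rebuild the model under parameter perturbations.
#'
#' @param physiology a `physiology`.
#' @param compound a `compound`.
#' @param clearance a `clearance_spec`.
#' @param ... further arguments forwarded to [build_model()].
#' @return an object of class `model_spec`.
#' @export
model_spec <- function(physiology, compound, clearance, ...) {
  structure(list(type = "whole_body", physiology = physiology,
                 compound = compound, clearance = clearance,
                 build_args = list(...)),
            class = "model_spec")
}

#' One-compartment model configuration
#'
#' @param v_l_kg volume of distribution (L/kg).
#' @param cl_ml_min_kg clearance (ml/min/kg).
#' @param body_weight_kg body weight (kg).
#' @return an object of class `model_spec`.
#' @export
one_compartment_spec <- function(v_l_kg, cl_ml_min_kg, body_weight_kg = 1) {
  structure(list(type = "one_compartment", v_l_kg = v_l_kg,
                 cl_ml_min_kg = cl_ml_min_kg,
                 body_weight_kg = body_weight_kg),
            class = "model_spec")
}

build_from_spec <- function(spec) {
  if (spec$type == "one_compartment")
    one_compartment_model(spec$v_l_kg, spec$cl_ml_min_kg, spec$body_weight_kg)
  else
    do.call(build_model, c(list(physiology = spec$physiology,
                                compound = spec$compound,
                                clearance = spec$clearance),
                           spec$build_args))
}

# Multiply one addressable parameter by `factor` and return the new spec.
# Addresses: logP, pKa, fu_plasma, molecular_weight, solubility, clearance,
# hematocrit, volume_<organ>, flow_<organ>; one-compartment specs accept
# volume and clearance.
perturb_spec <- function(spec, parameter, factor) {
  stopifnot(inherits(spec, "model_spec"))
  check_number(factor, "factor", lower = 0, strict_lower = TRUE)
  if (spec$type == "one_compartment") {
    if (parameter == "volume") spec$v_l_kg <- spec$v_l_kg * factor
    else if (parameter == "clearance") spec$cl_ml_min_kg <- spec$cl_ml_min_kg * factor
    else stop_domain("one-compartment specs expose parameters 'volume' and 'clearance'")
    return(spec)
  }
  cmp <- spec$compound
  cls <- spec$clearance
  phys <- spec$physiology
  if (parameter %in% c("logP", "pKa")) {
    cmp[[parameter]] <- cmp[[parameter]] * factor
  } else if (parameter == "fu_plasma") {
    cmp$fu_plasma <- cmp$fu_plasma * factor
    if (cmp$fu_plasma > 1)
      stop_domain("perturbed fu_plasma exceeds 1")
  } else if (parameter == "molecular_weight") {
    cmp$molecular_weight_g_mol <- cmp$molecular_weight_g_mol * factor
  } else if (parameter == "solubility") {
    cmp$solubility_pH74_mg_ml <- cmp$solubility_pH74_mg_ml * factor
  } else if (parameter == "clearance") {
    if (cls$mode == "calibrated_total")
      cls$total_plasma_clearance_ml_min_kg <-
        cls$total_plasma_clearance_ml_min_kg * factor
    else
      cls$vmax_ng_min <- cls$vmax_ng_min * factor
  } else if (parameter == "hematocrit") {
    phys$hematocrit <- phys$hematocrit * factor
    if (phys$hematocrit >= 1)
      stop_domain("perturbed hematocrit reaches 1 (no plasma flow)")
  } else if (grepl("^(volume|flow)_", parameter)) {
    col <- if (startsWith(parameter, "volume")) "volume_ml" else "blood_flow_ml_min"
    org <- sub("^(volume|flow)_", "", parameter)
    if (!org %in% phys$organs$name)
      stop_domain("parameter '", parameter, "' names unknown organ '", org, "'")
    phys$organs[org, col] <- phys$organs[org, col] * factor
    if (col == "blood_flow_ml_min") {
      # rebalance rest_of_body so cardiac output stays conserved
      if (org == "lung" || org == "rest_of_body")
        stop_domain("perturb a named systemic organ flow, not '", org, "'")
      sys <- setdiff(phys$organs$name, c("lung", "rest_of_body"))
      q_rest <- phys$organs["lung", "blood_flow_ml_min"] -
        sum(phys$organs[sys, "blood_flow_ml_min"])
      if (q_rest < 0) stop_domain("flow perturbation exceeds cardiac output")
      phys$organs["rest_of_body", "blood_flow_ml_min"] <- q_rest
    }
    validate_physiology(phys)
  } else {
    stop_domain("parameter '", parameter, "' is not addressable")
  }
  spec$compound <- cmp
  spec$clearance <- cls
  spec$physiology <- phys
  spec
}

# Simulate a spec and return the NCA-derived outputs for each compartment.
eval_spec <- function(spec, dose_mg_per_kg, config, compartments) {
  model <- build_from_spec(spec)
  dose <- dose_event(dose_mg_per_kg)
  sim <- simulate_pbpk(model, dose, config)
  out <- list()
  for (cm in compartments) {
    r <- pk_summary(get_profile(sim, cm), dose_mg_per_kg)
    out[[cm]] <- c(auc_0_inf = r$auc_0_inf, clearance = r$cl_ml_min_kg)
  }
  out
}

DEFAULT_FACTORS <- c(0.1, 0.5, 0.9, 1.1, 2, 10)

#' Variation-factor sensitivity of one output to one parameter
#'
#' @param spec a [model_spec()] or [one_compartment_spec()].
#' @param parameter addressable parameter name (see [perturb_spec]
#'   addresses in Details of [sensitivity_screen()]).
#' @param output `"auc_0_inf"` or `"clearance"`.
#' @param compartment profile analyzed (default venous plasma).
#' @param dose_mg_per_kg dose (mg/kg).
#' @param factors variation factors, all > 0 and != 1. The default spans a
#'   10-fold change in both directions plus a small-perturbation pair.
#' @param config a [sim_config()].
#' @param allow_partial if `TRUE`, factors whose simulation fails are
#'   dropped with a warning; otherwise a partial-result error lists them.
#' @return an object of class `sensitivity_result`: mean `sensitivity`,
#'   per-factor coefficients, and the failed factors if any.
#' @export
sensitivity_coefficient <- function(spec, parameter,
                                    output = c("auc_0_inf", "clearance"),
                                    compartment = "venous_plasma",
                                    dose_mg_per_kg = 0.1,
                                    factors = DEFAULT_FACTORS,
                                    config = sim_config(),
                                    allow_partial = FALSE) {
  output <- match.arg(output)
  if (any(factors <= 0) || any(factors == 1))
    stop_domain("variation factors must be > 0 and != 1")
  if (compartment == "plasma") compartment <- "venous_plasma"
  y0 <- eval_spec(spec, dose_mg_per_kg, config, compartment)[[compartment]][output]
  s_f <- setNames(rep(NA_real_, length(factors)), paste0("f_", factors))
  failed <- character(0)
  for (i in seq_along(factors)) {
    f <- factors[i]
    yf <- tryCatch(
      eval_spec(perturb_spec(spec, parameter, f), dose_mg_per_kg, config,
                compartment)[[compartment]][output],
      error = function(e) e)
    if (inherits(yf, "error")) failed <- c(failed, as.character(f))
    else s_f[i] <- (yf / y0 - 1) / (f - 1)
  }
  if (length(failed)) {
    msg <- paste0("simulation failed for factor(s): ",
                  paste(failed, collapse = ", "), " of parameter '",
                  parameter, "'")
    if (allow_partial) warning(msg, "; sensitivity is the mean over the rest")
    else stop_domain("partial result: ", msg)
  }
  structure(list(parameter = parameter, output = output,
                 compartment = compartment, dose_mg_per_kg = dose_mg_per_kg,
                 sensitivity = mean(s_f, na.rm = TRUE),
                 per_factor = s_f, variation_factors = factors,
                 failed_factors = failed, baseline = unname(y0)),
            class = "sensitivity_result")
}

#' @export
print.sensitivity_result <- function(x, ...) {
  cat(sprintf("<sensitivity> %s -> %s (%s, %g mg/kg): S = %.4g over factors {%s}%s\n",
              x$parameter, x$output, x$compartment, x$dose_mg_per_kg,
              x$sensitivity, paste(x$variation_factors, collapse = ", "),
              if (length(x$failed_factors))
                paste0(" [failed: ", paste(x$failed_factors, collapse = ", "), "]")
              else ""))
  invisible(x)
}

#' Sensitivity screen over parameters, outputs, compartments and doses
#'
#' Computes one variation-factor sensitivity per (parameter, output,
#' compartment, dose) cell, sharing the perturbed simulations across
#' outputs and compartments. Rows are ranked by `|sensitivity|` descending
#' within each output (stable; ties broken alphabetically by parameter).
#'
#' Addressable parameters: `logP`, `fu_plasma`, `pKa`, `clearance`,
#' `hematocrit`, `molecular_weight`, `solubility`, `volume_<organ>` and
#' `flow_<organ>` (e.g. `volume_adipose`).
#'
#' @param spec a [model_spec()].
#' @param parameters character vector of parameter addresses; the default
#'   is the standard screening set.
#' @param outputs subset of `c("auc_0_inf", "clearance")`.
#' @param compartments profiles to analyze.
#' @param doses_mg_per_kg doses at which the screen is replicated.
#' @param factors variation factors.
#' @param config a [sim_config()].
#' @return data frame with one row per cell: parameter, output, compartment,
#'   dose, sensitivity, n_factors_used, rank (within output).
#' @export
sensitivity_screen <- function(spec,
                               parameters = c("logP", "fu_plasma", "pKa",
                                              "clearance", "hematocrit",
                                              "volume_adipose"),
                               outputs = c("auc_0_inf", "clearance"),
                               compartments = c("venous_plasma", "saliva"),
                               doses_mg_per_kg = c(0.1, 0.25, 0.5),
                               factors = DEFAULT_FACTORS,
                               config = sim_config()) {
  if (!length(parameters)) stop_domain("empty parameter set")
  if (any(factors <= 0) || any(factors == 1))
    stop_domain("variation factors must be > 0 and != 1")
  rows <- list()
  for (dose in doses_mg_per_kg) {
    base <- eval_spec(spec, dose, config, compartments)
    for (p in parameters) {
      per_factor <- vector("list", length(factors))
      failed <- character(0)
      for (i in seq_along(factors)) {
        f <- factors[i]
        yf <- tryCatch(
          eval_spec(perturb_spec(spec, p, f), dose, config, compartments),
          error = function(e) e)
        if (inherits(yf, "error")) failed <- c(failed, as.character(f))
        else per_factor[[i]] <- lapply(compartments, function(cm)
          (yf[[cm]] / base[[cm]] - 1) / (f - 1))
      }
      if (length(failed))
        warning("parameter '", p, "' at dose ", dose,
                ": factor(s) ", paste(failed, collapse = ", "),
                " failed; mean over the remaining factors")
      used <- !vapply(per_factor, is.null, logical(1))
      for (ci in seq_along(compartments)) {
        cm <- compartments[ci]
        mat <- do.call(rbind, lapply(per_factor[used], `[[`, ci))
        for (out in outputs) {
          rows[[length(rows) + 1L]] <- data.frame(
            parameter = p, output = out, compartment = cm,
            dose_mg_per_kg = dose,
            sensitivity = mean(mat[, out]),
            n_factors_used = sum(used), stringsAsFactors = FALSE)
        }
      }
    }
  }
  res <- do.call(rbind, rows)
  # stable rank: |S| descending, alphabetical parameter tie-break
  res <- res[order(res$output, res$compartment, res$dose_mg_per_kg,
                   -abs(res$sensitivity), res$parameter), ]
  res$rank <- stats::ave(abs(res$sensitivity),
                         res$output, res$compartment, res$dose_mg_per_kg,
                         FUN = function(x) seq_along(x))
  rownames(res) <- NULL
  res
}
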