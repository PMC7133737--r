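# Non-compartmental analysis of a concentration-time profile: terminal
# log-linear regression, linear-up/log-down quadrature with exponential tail
# extrapolation, and assembly of the standard IV-bolus parameter set
# (Cmax, Tmax, Ke, t1/2, AUC, AUMC, MRT, CL, Vd).
#
# Internal computation uses ml, hours and ng; CL is reported in ml/min/kg
# and Vd in L/kg with the conversion at the boundary.

as_profile <- function(profile) {
  profile <- as.data.frame(profile)
  if (!all(c("time_hr", "conc_ng_per_ml") %in% names(profile))) {
    if (ncol(profile) >= 2 && is.numeric(profile[[1]]) && is.numeric(profile[[2]]))
      names(profile)[1:2] <- c("time_hr", "conc_ng_per_ml")
    else
      stop_domain("profile must have columns time_hr and conc_ng_per_ml")
  }
  profile <- profile[order(profile$time_hr), c("time_hr", "conc_ng_per_ml")]
  if (any(diff(profile$time_hr) <= 0))
    stop_domain("profile times must be strictly increasing")
  if (any(profile$conc_ng_per_ml < 0))
    stop_domain("profile concentrations must be >= 0")
  profile
}

#' Terminal elimination rate constant by log-linear regression
#'
#' Fits `log(C)` against time over the last `n` points after Tmax for every
#' candidate `n >= 3`, selects the fit maximizing the adjusted R-squared
#' (ties within 1e-4 resolved toward more points, the standard NCA
#' best-fit convention), and returns `ke = -slope` with `t1/2 = ln 2 / ke`.
#' Zero concentrations are excluded from the log fit.
#'
#' On densely sampled profiles an unconstrained adjusted-R-squared search
#' degenerates: a short late window of a few points routinely out-scores any
#' long window by chance, making the estimator variance grow with sampling
#' density. Candidate windows are therefore additionally required to span at
#' least `min_span_fraction` of the post-Tmax observation interval.
#'
#' @param profile data frame with `time_hr`, `conc_ng_per_ml`.
#' @param min_points minimum number of terminal points (>= 3).
#' @param min_span_fraction minimum fraction (0-1) of the post-Tmax time
#'   span a candidate window must cover.
#' @return list with `ke_per_hr`, `t_half_hr`, `n_terminal_points`,
#'   `r_squared` (unadjusted, of the chosen fit), `adj_r_squared`, and
#'   `fit_times` (the time points used, for independent re-fitting).
#' @export
terminal_slope <- function(profile, min_points = 3, min_span_fraction = 0.2) {
  profile <- as_profile(profile)
  i_max <- which.max(profile$conc_ng_per_ml)[1]
  tail_df <- profile[seq_len(nrow(profile)) > i_max &
                       profile$conc_ng_per_ml > 0, , drop = FALSE]
  m <- nrow(tail_df)
  if (m < min_points)
    stop_domain("insufficient data: need >= ", min_points,
                " positive concentrations after Tmax, found ", m)

  # suffix regressions over the last n = min_points..m points, O(m) via
  # reversed cumulative sums
  x <- rev(tail_df$time_hr)
  y <- rev(log(tail_df$conc_ng_per_ml))
  n <- seq_len(m)
  Sx <- cumsum(x); Sy <- cumsum(y)
  Sxx <- cumsum(x^2); Syy <- cumsum(y^2); Sxy <- cumsum(x * y)
  sxx <- n * Sxx - Sx^2
  syy <- n * Syy - Sy^2
  sxy <- n * Sxy - Sx * Sy
  span <- x[1] - x               # suffix time span (x is reversed)
  total_span <- x[1] - x[m]
  ok <- n >= min_points & sxx > 0 &
    span >= min_span_fraction * total_span - 1e-12
  slope <- ifelse(ok, sxy / sxx, NA_real_)
  r2 <- ifelse(ok & syy > 0, sxy^2 / (sxx * syy), NA_real_)
  # numerically exact fits can leave r2 microscopically above 1
  r2 <- pmin(r2, 1)
  adj <- 1 - (1 - r2) * (n - 1) / (n - 2)

  cand <- which(ok & !is.na(adj) & slope < 0)
  if (!length(cand))
    stop_domain("no terminal phase: log-linear slope is non-negative")
  best <- max(adj[cand])
  sel <- max(cand[adj[cand] >= best - 1e-4])

  ke <- -slope[sel]
  list(ke_per_hr = ke, t_half_hr = log(2) / ke,
       n_terminal_points = sel, r_squared = r2[sel], adj_r_squared = adj[sel],
       fit_times = sort(x[seq_len(sel)]))
}

#' Area under the concentration-time and moment curves
#'
#' Linear-up/log-down trapezoidal quadrature for AUC and AUMC over the
#' observed times; when the terminal rate constant is supplied the
#' exponential tail is added: `C_last/ke` for AUC and
#' `C_last*t_last/ke + C_last/ke^2` for AUMC.
#'
#' @param profile data frame with `time_hr`, `conc_ng_per_ml`.
#' @param ke_per_hr terminal elimination rate constant; if `NULL` and the
#'   last concentration is positive, extrapolated quantities are `NA` with
#'   a warning.
#' @return list with `auc_0_t`, `auc_0_inf`, `aumc_0_t`, `aumc_0_inf`
#'   (ng*hr/ml and ng*hr^2/ml) and `extrapolated_fraction`.
#' @export
nca_auc <- function(profile, ke_per_hr = NULL) {
  profile <- as_profile(profile)
  t <- profile$time_hr
  c <- profile$conc_ng_per_ml
  t1 <- t[-length(t)]; t2 <- t[-1]
  c1 <- c[-length(c)]; c2 <- c[-1]
  dt <- t2 - t1
  logdown <- c2 < c1 & c2 > 0 & c1 > 0
  lam <- ifelse(logdown, log(c1 / c2) / dt, NA_real_)
  auc_seg <- ifelse(logdown, (c1 - c2) / lam, dt * (c1 + c2) / 2)
  aumc_seg <- ifelse(logdown,
                     (t1 * c1 - t2 * c2) / lam + (c1 - c2) / lam^2,
                     dt * (t1 * c1 + t2 * c2) / 2)
  auc_0_t <- sum(auc_seg)
  aumc_0_t <- sum(aumc_seg)

  c_last <- c[length(c)]
  t_last <- t[length(t)]
  if (is.null(ke_per_hr)) {
    if (c_last > 0) {
      warning("terminal rate constant unavailable; AUC extrapolation omitted")
      return(list(auc_0_t = auc_0_t, auc_0_inf = NA_real_,
                  aumc_0_t = aumc_0_t, aumc_0_inf = NA_real_,
                  extrapolated_fraction = NA_real_))
    }
    ke_per_hr <- Inf
  }
  check_number(ke_per_hr, "ke_per_hr", lower = 0, strict_lower = TRUE)
  auc_tail <- c_last / ke_per_hr
  aumc_tail <- c_last * t_last / ke_per_hr + c_last / ke_per_hr^2
  list(auc_0_t = auc_0_t, auc_0_inf = auc_0_t + auc_tail,
       aumc_0_t = aumc_0_t, aumc_0_inf = aumc_0_t + aumc_tail,
       extrapolated_fraction = auc_tail / (auc_0_t + auc_tail))
}

#' Full non-compartmental parameter set for an IV-bolus profile
#'
#' Computes Cmax/Tmax from the reporting grid (earliest-time tie-break; the
#' t = 0 point, where the venous pool holds the unmixed bolus, is excluded
#' by reporting convention when present), the terminal slope, AUC/AUMC with
#' tail extrapolation, and the derived identities `MRT = AUMC/AUC`,
#' `CL = dose/AUC` and `Vd = CL/ke`.
#'
#' @param profile data frame with `time_hr`, `conc_ng_per_ml`.
#' @param dose_mg_per_kg administered dose (mg/kg, > 0).
#' @param exclude_time_zero drop a leading t = 0 sample from the Cmax/Tmax
#'   search (default `TRUE`).
#' @param min_points minimum terminal points, see [terminal_slope()].
#' @return an object of class `nca_result`: `cmax_ng_ml`, `tmax_hr`,
#'   `ke_per_hr`, `t_half_hr`, `auc_0_t`, `auc_0_inf` (ng*hr/ml),
#'   `aumc_0_inf` (ng*hr^2/ml), `mrt_hr`, `cl_ml_min_kg`, `vd_l_kg`,
#'   `extrapolated_fraction`, `n_terminal_points`, `r_squared_terminal`.
#' @export
pk_summary <- function(profile, dose_mg_per_kg, exclude_time_zero = TRUE,
                       min_points = 3) {
  profile <- as_profile(profile)
  check_number(dose_mg_per_kg, "dose_mg_per_kg", lower = 0, strict_lower = TRUE)
  if (all(profile$conc_ng_per_ml == 0))
    stop_domain("insufficient data: profile is identically zero")

  obs <- profile
  if (exclude_time_zero && obs$time_hr[1] <= 0 && nrow(obs) > 1)
    obs <- obs[obs$time_hr > 0, , drop = FALSE]
  i_max <- which.max(obs$conc_ng_per_ml)[1]   # earliest-time tie-break
  cmax <- obs$conc_ng_per_ml[i_max]
  tmax <- obs$time_hr[i_max]

  ts <- terminal_slope(profile, min_points = min_points)
  area <- nca_auc(profile, ke_per_hr = ts$ke_per_hr)

  dose_ng_per_kg <- dose_mg_per_kg * 1e6
  cl_ml_hr_kg <- dose_ng_per_kg / area$auc_0_inf
  cl_ml_min_kg <- cl_ml_hr_kg / 60
  vd_l_kg <- cl_ml_hr_kg / ts$ke_per_hr / 1000

  structure(list(cmax_ng_ml = cmax, tmax_hr = tmax,
                 ke_per_hr = ts$ke_per_hr, t_half_hr = ts$t_half_hr,
                 auc_0_t = area$auc_0_t, auc_0_inf = area$auc_0_inf,
                 aumc_0_inf = area$aumc_0_inf,
                 mrt_hr = area$aumc_0_inf / area$auc_0_inf,
                 cl_ml_min_kg = cl_ml_min_kg, vd_l_kg = vd_l_kg,
                 extrapolated_fraction = area$extrapolated_fraction,
                 n_terminal_points = ts$n_terminal_points,
                 r_squared_terminal = ts$r_squared,
                 dose_mg_per_kg = dose_mg_per_kg),
            class = "nca_result")
}

#' @export
print.nca_result <- function(x, ...) {
  cat(sprintf(paste0(
    "<nca_result> Cmax %.4g ng/ml @ %.3g hr | ke %.4g /hr (t1/2 %.4g hr, R2 %.4f, n %d)\n",
    "  AUC0-inf %.6g ng*hr/ml (%.1f%% extrapolated) | MRT %.4g hr | CL %.4g ml/min/kg | Vd %.4g L/kg\n"),
    x$cmax_ng_ml, x$tmax_hr, x$ke_per_hr, x$t_half_hr, x$r_squared_terminal,
    x$n_terminal_points, x$auc_0_inf, 100 * x$extrapolated_fraction,
    x$mrt_hr, x$cl_ml_min_kg, x$vd_l_kg))
  invisible(x)
}

#' @export
as.data.frame.nca_result <- function(x, ...) {
  as.data.frame(unclass(x)[c("cmax_ng_ml", "tmax_hr", "ke_per_hr",
                             "t_half_hr", "auc_0_t", "auc_0_inf",
                             "aumc_0_inf", "mrt_hr", "cl_ml_min_kg",
                             "vd_l_kg", "extrapolated_fraction",
                             "n_terminal_points", "r_squared_terminal")])
}

#' Batch NCA over a tidy profile CSV
#'
#' Runs [pk_summary()] per individual on one compartment of a profile CSV
#' in the dialect written by [write_profiles_csv()].
#'
#' @param path input CSV path.
#' @param dose_mg_per_kg dose (mg/kg).
#' @param compartment compartment to analyze (default venous plasma).
#' @param out optional output CSV path for the result table.
#' @return data frame of NCA parameters, one row per individual.
#' @export
nca_from_csv <- function(path, dose_mg_per_kg, compartment = "plasma",
                         out = NULL) {
  data <- read_profiles_csv(path)
  if (compartment == "plasma") compartment <- "venous_plasma"
  data <- data[data$compartment == compartment, , drop = FALSE]
  if (!nrow(data)) stop_domain("no rows for compartment '", compartment, "'")
  res <- do.call(rbind, lapply(split(data, data$individual_id), function(d) {
    r <- as.data.frame(pk_summary(d[, c("time_hr", "conc_ng_per_ml")],
                                  dose_mg_per_kg))
    cbind(individual_id = d$individual_id[1], r)
  }))
  rownames(res) <- NULL
  if (!is.null(out)) write.csv(res, out, row.names = FALSE)
  res
}
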