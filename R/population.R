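# Virtual populations and batch simulation. Mouse populations vary body
# weight (uniform 12-30 g by default); human populations draw age (uniform
# 20-80 years) and sex (equal proportion) and map them to body weight
# through a piecewise-linear reference table anchored so the population
# mean weight is the 80.35 kg adult reference. Physiologies are produced by
# allometric scaling of the species reference.

# Reference body weight (kg) by age and sex; piecewise linear between nodes.
# The table is rescaled at load so that its expectation under uniform age
# 20-80 and equal sex is exactly the adult reference weight.
HUMAN_WEIGHT_TABLE <- local({
  tab <- list(age = c(20, 30, 40, 50, 60, 70, 80),
              male = c(83.2, 87.9, 89.6, 89.9, 88.2, 85.0, 80.9),
              female = c(71.8, 75.7, 78.2, 78.9, 77.9, 75.3, 72.0))
  trapz_mean <- function(w) {
    a <- tab$age
    sum((w[-1] + w[-length(w)]) / 2 * diff(a)) / (max(a) - min(a))
  }
  anchor <- 80.35 / ((trapz_mean(tab$male) + trapz_mean(tab$female)) / 2)
  tab$male <- tab$male * anchor
  tab$female <- tab$female * anchor
  tab
})

human_weight_for_age <- function(age_years, sex) {
  stopifnot(length(age_years) == length(sex))
  w <- numeric(length(age_years))
  for (s in c("male", "female")) {
    idx <- sex == s
    if (any(idx))
      w[idx] <- approx(HUMAN_WEIGHT_TABLE$age, HUMAN_WEIGHT_TABLE[[s]],
                       xout = age_years[idx], rule = 2)$y
  }
  w
}

#' Specify a virtual population
#'
#' @param species `"mouse"` or `"human"`.
#' @param n number of individuals (>= 1).
#' @param weight_range_kg mouse body-weight range; default `c(0.012, 0.030)`
#'   (12-30 g).
#' @param weight_distribution `"uniform"` (default) or `"normal"` (mean at
#'   the range midpoint, sd a quarter of the range, truncated to the range).
#' @param age_range_years human age range; default `c(20, 80)`.
#' @param sex_ratio_female fraction female (human); default 0.5 (equal
#'   proportion, assigned exactly).
#' @param seed RNG seed; the population is deterministic under it.
#' @return an object of class `population_spec`.
#' @export
population_spec <- function(species, n = 100,
                            weight_range_kg = c(0.012, 0.030),
                            weight_distribution = c("uniform", "normal"),
                            age_range_years = c(20, 80),
                            sex_ratio_female = 0.5, seed = 1L) {
  weight_distribution <- match.arg(weight_distribution)
  if (n < 1) stop_domain("population size must be >= 1")
  if (diff(weight_range_kg) < 0) stop_domain("weight range must have min <= max")
  if (diff(age_range_years) < 0) stop_domain("age range must have min <= max")
  check_number(sex_ratio_female, "sex_ratio_female", lower = 0, upper = 1)
  structure(list(species = species, n = as.integer(n),
                 weight_range_kg = weight_range_kg,
                 weight_distribution = weight_distribution,
                 age_range_years = age_range_years,
                 sex_ratio_female = sex_ratio_female,
                 seed = as.integer(seed)),
            class = "population_spec")
}

#' Generate a virtual population of physiologies
#'
#' @param spec a [population_spec()].
#' @return list of `physiology` objects with `individual_id` attributes.
#' @export
generate_population <- function(spec) {
  stopifnot(inherits(spec, "population_spec"))
  base <- get_species_physiology(spec$species)
  n <- spec$n
  is_mouse <- base$species == "mouse_nod_shiltj"
  draws <- with_seed(spec$seed, {
    if (is_mouse) {
      lo <- spec$weight_range_kg[1]; hi <- spec$weight_range_kg[2]
      w <- if (spec$weight_distribution == "uniform") runif(n, lo, hi)
           else pmin(pmax(stats::rnorm(n, (lo + hi) / 2, (hi - lo) / 4), lo), hi)
      list(weight = w, age = rep(NA_real_, n), sex = rep(NA_character_, n))
    } else {
      age <- runif(n, spec$age_range_years[1], spec$age_range_years[2])
      n_f <- round(spec$sex_ratio_female * n)
      sex <- sample(c(rep("female", n_f), rep("male", n - n_f)))
      list(weight = human_weight_for_age(age, sex), age = age, sex = sex)
    }
  })
  lapply(seq_len(n), function(i) {
    ph <- scale_physiology(base, draws$weight[i],
                           age_years = if (is_mouse) NULL else draws$age[i],
                           sex = if (is_mouse) NULL else draws$sex[i])
    attr(ph, "individual_id") <- sprintf("%s_%03d",
                                         if (is_mouse) "mouse" else "human", i)
    ph
  })
}

POP_COMPARTMENTS <- c("brain", "heart", "lung", "liver", "kidney", "spleen",
                      "venous_plasma", "saliva")

#' Simulate a population and summarize its pharmacokinetics
#'
#' Runs [simulate_pbpk()] and [pk_summary()] per individual and aggregates:
#' mean, SD and 5th/95th percentiles of every NCA parameter, plus per-time
#' concentration percentile bands for each requested compartment. Solver
#' failures are recorded per individual and excluded from the summary with
#' a warning.
#'
#' @param individuals list of `physiology` from [generate_population()].
#' @param compound a `compound`.
#' @param clearance a `clearance_spec`.
#' @param dose a [dose_event()].
#' @param config a [sim_config()].
#' @param compartments compartments to keep; default the highly perfused
#'   organs plus venous plasma and saliva.
#' @param nca_compartment compartment analyzed by NCA (default venous plasma).
#' @param ... further arguments passed to [build_model()] (e.g.
#'   `eliminating_organs`).
#' @return list with `profiles` (long data frame over individuals), `nca`
#'   (per-individual parameter table), `summary` (list of `nca_summary` and
#'   `concentration_bands` data frames) and `n_failed`.
#' @export
simulate_population <- function(individuals, compound, clearance, dose,
                                config = sim_config(),
                                compartments = POP_COMPARTMENTS,
                                nca_compartment = "venous_plasma", ...) {
  stopifnot(length(individuals) >= 1)
  profiles <- vector("list", length(individuals))
  nca <- vector("list", length(individuals))
  failed <- character(0)
  for (i in seq_along(individuals)) {
    ph <- individuals[[i]]
    id <- attr(ph, "individual_id") %||% sprintf("ind_%03d", i)
    res <- tryCatch({
      model <- build_model(ph, compound, clearance, ...)
      sim <- simulate_pbpk(model, dose, config, individual_id = id)
      keep <- sim$data[sim$data$compartment %in% compartments, , drop = FALSE]
      r <- pk_summary(get_profile(sim, nca_compartment), dose$amount_mg_per_kg)
      list(profiles = keep,
           nca = cbind(individual_id = id, body_weight_kg = ph$body_weight_kg,
                       as.data.frame(r)))
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failed <- c(failed, id)
    } else {
      profiles[[i]] <- res$profiles
      nca[[i]] <- res$nca
    }
  }
  if (length(failed))
    warning(length(failed), " individual(s) failed and were excluded: ",
            paste(failed, collapse = ", "))
  profiles <- do.call(rbind, profiles)
  nca <- do.call(rbind, nca)
  rownames(nca) <- NULL
  list(profiles = profiles, nca = nca,
       summary = summarize_population(nca, profiles),
       n_failed = length(failed))
}

#' Summarize per-individual NCA and concentration profiles
#'
#' @param nca per-individual NCA table from [simulate_population()].
#' @param profiles optional long profile data frame for concentration bands.
#' @return list of data frames `nca_summary` (mean, sd, p5, p95 per
#'   parameter) and `concentration_bands` (mean, p5, median, p95 per
#'   compartment and time; `NULL` when no profiles given).
#' @export
summarize_population <- function(nca, profiles = NULL) {
  params <- c("cmax_ng_ml", "tmax_hr", "t_half_hr", "ke_per_hr",
              "auc_0_inf", "mrt_hr", "cl_ml_min_kg", "vd_l_kg")
  nca_summary <- do.call(rbind, lapply(params, function(p) {
    x <- nca[[p]]
    data.frame(parameter = p, mean = mean(x), sd = sd(x),
               p5 = unname(quantile(x, 0.05, type = 7)),
               p95 = unname(quantile(x, 0.95, type = 7)),
               n = length(x), stringsAsFactors = FALSE)
  }))
  bands <- NULL
  if (!is.null(profiles) && nrow(profiles)) {
    key <- interaction(profiles$compartment, profiles$time_hr, drop = TRUE)
    agg <- lapply(split(profiles$conc_ng_per_ml, key), function(x)
      c(mean = mean(x), p5 = unname(quantile(x, 0.05)),
        p50 = unname(quantile(x, 0.5)), p95 = unname(quantile(x, 0.95))))
    first <- !duplicated(key)
    bands <- data.frame(compartment = profiles$compartment[first],
                        time_hr = profiles$time_hr[first],
                        do.call(rbind, agg)[as.character(unique(key)), ,
                                            drop = FALSE],
                        stringsAsFactors = FALSE)
    bands <- bands[order(bands$compartment, bands$time_hr), ]
    rownames(bands) <- NULL
  }
  list(nca_summary = nca_summary, concentration_bands = bands)
}
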