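#' Synthetic study designs and datasets
#'
#' `study_design()` describes one synthetic "observed" dataset: dose,
#' regimen, sampling grid, residual noise and replication.
#' `generate_profile()` simulates a scenario, samples it on the grid
#' and applies multiplicative lognormal noise
#' \eqn{C_{obs} = C e^{\varepsilon}},
#' \eqn{\varepsilon \sim N(0, \sigma^2)} with
#' \eqn{\sigma = \sqrt{\ln(1 + CV^2)}}, so the geometric mean of the
#' noise is 1.  When `n_replicates > 1` the replicates are averaged
#' geometrically, emulating the mean profiles that dominate published
#' PK data.
#'
#' @param population population label.
#' @param dose_per_kg mg/kg.
#' @param n_doses,interval regimen.
#' @param sampling_times sorted positive days.
#' @param noise_cv residual coefficient of variation (>= 0).
#' @param n_replicates number of noisy replicates averaged into the
#'   reported mean profile.
#' @param seed integer RNG seed.
#' @param study_id dataset identifier.
#' @return a `study_design`.
#' @export
study_design <- function(population, dose_per_kg, n_doses = 1L,
                         interval = NA_real_, sampling_times,
                         noise_cv = 0, n_replicates = 1L, seed = 1L,
                         study_id = NULL) {
  if (any(sampling_times <= 0) ||
      is.unsorted(sampling_times, strictly = TRUE))
    stop("sampling_times must be strictly increasing and positive")
  if (noise_cv < 0) stop("noise_cv must be >= 0")
  if (is.null(study_id))
    study_id <- sprintf("%s_%g", tolower(population), dose_per_kg)
  structure(
    list(population = population, dose_per_kg = dose_per_kg,
         n_doses = as.integer(n_doses), interval = interval,
         sampling_times = sampling_times, noise_cv = noise_cv,
         n_replicates = as.integer(n_replicates),
         seed = as.integer(seed), study_id = study_id),
    class = "study_design")
}

#' @rdname study_design
#' @param scenario a `population_scenario` used as the data-generating
#'   truth.
#' @param design a `study_design`.
#' @param ... passed to [scenario_model()].
#' @export
generate_profile <- function(scenario, design, ...) {
  stopifnot(inherits(design, "study_design"))
  model <- scenario_model(scenario, ...)
  reg <- dosing_regimen(design$dose_per_kg, n_doses = design$n_doses,
                        interval = design$interval)
  horizon <- if (design$n_doses > 1L)
    (design$n_doses - 1L) * design$interval else 0
  if (max(design$sampling_times) > horizon + 365)
    stop("sampling beyond the simulation horizon")
  sim <- simulate_regimen(model, reg,
                          output_times = design$sampling_times)
  conc <- apply_lognormal_noise(sim$plasma_conc, design$noise_cv,
                                design$n_replicates, design$seed)
  concentration_profile(
    study_id = design$study_id, population = design$population,
    dose_per_kg = design$dose_per_kg, times = design$sampling_times,
    concentrations = conc, n_doses = design$n_doses,
    interval = design$interval, drug = scenario$drug$name)
}

#' Apply multiplicative lognormal residual noise
#'
#' Noise model of the synthetic-data generator, exposed so noisy
#' replicates can be drawn from a precomputed noise-free profile
#' without re-simulating: each replicate multiplies the true value by
#' \eqn{e^{\varepsilon}}, \eqn{\varepsilon \sim N(0, \sigma^2)},
#' \eqn{\sigma = \sqrt{\ln(1+CV^2)}}; replicates are combined by
#' geometric mean.
#'
#' @param conc true concentrations.
#' @param noise_cv coefficient of variation (0 returns `conc`).
#' @param n_replicates replicates averaged geometrically.
#' @param seed RNG seed.
#' @return noisy concentrations, same length as `conc`.
#' @export
apply_lognormal_noise <- function(conc, noise_cv, n_replicates = 1L,
                                  seed = 1L) {
  if (noise_cv < 0) stop("noise_cv must be >= 0")
  if (noise_cv == 0) return(conc)
  set.seed(as.integer(seed))
  sdlog <- sqrt(log(1 + noise_cv^2))
  eps <- matrix(rnorm(length(conc) * n_replicates, sd = sdlog),
                nrow = length(conc))
  conc * exp(rowMeans(eps))
}

# Sampling grids emulating published bevacizumab studies: dense over
# the first two days, then roughly weekly.  Exact literature grids are
# not reproducible without digitization.
single_dose_grid <- function(horizon = 70) {
  g <- c(1 / 24, 0.25, 1, 2, 4, 7, 14, 21, 28, 42, 56, 70)
  g[g <= horizon]
}

repeated_dose_grid <- function(interval = 14, n_doses = 4L,
                               horizon = 70) {
  starts <- (seq_len(n_doses) - 1L) * interval
  g <- sort(unique(c(1 / 24, 1, 2, 4, 7,
                     as.vector(outer(c(1 / 24, 1, 7),
                                     starts[-1], `+`)),
                     starts[-1] + interval / 2,
                     seq(max(starts) + interval, horizon, by = 7))))
  g[g <= horizon]
}

#' Generate the full paper-shaped synthetic corpus
#'
#' Emulates the structure of the published bevacizumab datasets:
#' NHP 4 mg/kg single dose (wild-type and Fc-variant), healthy
#' volunteers 0.5/1/3 mg/kg single dose, cancer patients
#' 0.3/1/3/5/10 mg/kg repeated dosing every 14 days (4 doses) --- ten
#' datasets in total.  Truth scenarios are the refined models
#' (`NHP-bev`/`NHP-xtend`, `HV-refined`, `Patients-refined`) unless
#' overridden.
#'
#' @param seed integer master seed; per-dataset seeds are derived from
#'   it.
#' @param noise_cv residual CV applied to every dataset.
#' @param n_replicates replicates per dataset (geometric mean
#'   reported).
#' @param dir optional directory; when given, one CSV per dataset is
#'   written.
#' @param scenarios optional named list overriding the truth scenarios
#'   (`NHP`, `NHP_xtend`, `HV`, `Patients`).
#' @param ... passed to [scenario_model()].
#' @return (invisibly when writing) list of
#'   [concentration_profile()] objects.
#' @export
generate_study_set <- function(seed = 1L, noise_cv = 0.1,
                               n_replicates = 1L, dir = NULL,
                               scenarios = NULL, ...) {
  sc <- list(NHP = build_scenario("NHP-bev"),
             NHP_xtend = build_scenario("NHP-xtend"),
             HV = build_scenario("HV-refined"),
             Patients = build_scenario("Patients-refined"))
  if (!is.null(scenarios)) sc <- modifyList(sc, scenarios)
  nhp_grid <- single_dose_grid(70)
  hv_grid <- c(single_dose_grid(70), 80)
  pt_grid <- repeated_dose_grid(14, 4L, 70)
  plan <- list(
    list(sc = "NHP", pop = "NHP", dose = 4, n = 1L, iv = NA,
         grid = nhp_grid, id = "nhp_bev_4"),
    list(sc = "NHP_xtend", pop = "NHP", dose = 4, n = 1L, iv = NA,
         grid = nhp_grid, id = "nhp_xtend_4"),
    list(sc = "HV", pop = "HV", dose = 0.5, n = 1L, iv = NA,
         grid = hv_grid, id = "hv_0.5"),
    list(sc = "HV", pop = "HV", dose = 1, n = 1L, iv = NA,
         grid = hv_grid, id = "hv_1"),
    list(sc = "HV", pop = "HV", dose = 3, n = 1L, iv = NA,
         grid = hv_grid, id = "hv_3"))
  for (d in c(0.3, 1, 3, 5, 10)) {
    plan[[length(plan) + 1L]] <-
      list(sc = "Patients", pop = "Patients", dose = d, n = 4L,
           iv = 14, grid = pt_grid, id = sprintf("pt_%g", d))
  }
  seed <- as.integer(seed)
  out <- vector("list", length(plan))
  for (i in seq_along(plan)) {
    p <- plan[[i]]
    des <- study_design(p$pop, p$dose, n_doses = p$n,
                        interval = p$iv, sampling_times = p$grid,
                        noise_cv = noise_cv,
                        n_replicates = n_replicates,
                        seed = (seed * 131L + i) %% .Machine$integer.max,
                        study_id = p$id)
    out[[i]] <- generate_profile(sc[[p$sc]], des, ...)
  }
  names(out) <- vapply(plan, `[[`, character(1), "id")
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    for (p in out)
      write_profiles(p, file.path(dir, paste0(p$study_id, ".csv")))
    return(invisible(out))
  }
  out
}
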