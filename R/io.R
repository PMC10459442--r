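#' Concentration-time profiles
#'
#' The unit of observed and predicted data: a time series of plasma
#' concentrations with study metadata.  Times are days (strictly
#' increasing), concentrations ug/mL.
#'
#' @param study_id text identifier.
#' @param population population label (e.g. `"NHP"`, `"HV"`,
#'   `"Patients"`).
#' @param dose_per_kg mg/kg.
#' @param times days, strictly increasing.
#' @param concentrations ug/mL, non-negative.
#' @param sd optional standard deviations, ug/mL.
#' @param n_doses,interval regimen metadata (defaults: single dose).
#' @param drug drug label.
#' @param validate_positive require strictly positive concentrations
#'   (needed on fitting/evaluation paths).
#' @return a `concentration_profile`.
#' @export
concentration_profile <- function(study_id, population, dose_per_kg,
                                  times, concentrations, sd = NULL,
                                  n_doses = 1L, interval = NA_real_,
                                  drug = "bevacizumab",
                                  validate_positive = FALSE) {
  times <- as.numeric(times)
  concentrations <- as.numeric(concentrations)
  if (length(times) != length(concentrations))
    stop("times and concentrations must have equal length")
  if (anyDuplicated(times)) stop("duplicate times in profile")
  if (is.unsorted(times, strictly = TRUE))
    stop("times must be strictly increasing")
  if (any(concentrations < 0))
    stop("concentrations must be non-negative")
  if (validate_positive && any(concentrations <= 0))
    stop("concentrations must be strictly positive on this path")
  if (!is.null(sd) && length(sd) != length(times))
    stop("sd must match times in length")
  structure(
    list(study_id = study_id, population = population,
         drug = drug, dose_per_kg = dose_per_kg,
         n_doses = as.integer(n_doses), interval = interval,
         times = times, concentrations = concentrations, sd = sd,
         units = list(time = "day", concentration = "ug/mL")),
    class = "concentration_profile")
}

#' @export
print.concentration_profile <- function(x, ...) {
  cat(sprintf(
    "<concentration_profile> %s [%s, %s] %.3g mg/kg x%d: %d points, %.3g-%.3g days\n",
    x$study_id, x$population, x$drug, x$dose_per_kg, x$n_doses,
    length(x$times), min(x$times), max(x$times)))
  invisible(x)
}

#' Regimen carried by a profile's metadata
#' @param profile a `concentration_profile`.
#' @param infusion_duration infusion length, days.
#' @return a [dosing_regimen()].
#' @export
profile_regimen <- function(profile, infusion_duration = 0.0625) {
  dosing_regimen(profile$dose_per_kg, n_doses = profile$n_doses,
                 interval = profile$interval,
                 infusion_duration = infusion_duration)
}

profile_columns <- c("study_id", "population", "dose_mg_kg",
                     "conc_ug_ml")

#' Read concentration profiles from CSV
#'
#' Expected columns: `study_id`, `population`, `dose_mg_kg`, a time
#' column (`time_day`, or `time_h` which is converted by division by
#' 24), `conc_ug_ml`, and optionally `sd_ug_ml`, `drug`, `n_doses`,
#' `interval_day`.  One profile is returned per `study_id`.  Malformed
#' data (missing columns, unsorted or duplicated times, negative
#' concentrations) is rejected with an error naming the offence.
#'
#' @param path CSV file path.
#' @return list of [concentration_profile()] objects.
#' @export
read_profiles <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(profile_columns, names(df))
  if (length(missing))
    stop("profile CSV lacks required columns: ",
         paste(missing, collapse = ", "))
  if ("time_day" %in% names(df)) {
    df$.time <- as.numeric(df$time_day)
  } else if ("time_h" %in% names(df)) {
    df$.time <- as.numeric(df$time_h) / 24
  } else {
    stop("profile CSV needs a time_day or time_h column")
  }
  if (any(!is.finite(df$.time)))
    stop("non-numeric times in rows: ",
         paste(which(!is.finite(df$.time)), collapse = ", "))
  if (any(df$conc_ug_ml < 0))
    stop("negative concentrations in rows: ",
         paste(which(df$conc_ug_ml < 0), collapse = ", "))
  lapply(split(df, df$study_id), function(g) {
    g <- g[order(seq_len(nrow(g))), ]  # preserve file order
    if (anyDuplicated(g$.time))
      stop("duplicated times in study ", g$study_id[1])
    if (is.unsorted(g$.time, strictly = TRUE))
      stop("unsorted times in study ", g$study_id[1])
    concentration_profile(
      study_id = g$study_id[1], population = g$population[1],
      dose_per_kg = g$dose_mg_kg[1],
      times = g$.time, concentrations = g$conc_ug_ml,
      sd = if ("sd_ug_ml" %in% names(g)) g$sd_ug_ml else NULL,
      n_doses = if ("n_doses" %in% names(g)) g$n_doses[1] else 1L,
      interval = if ("interval_day" %in% names(g)) g$interval_day[1]
                 else NA_real_,
      drug = if ("drug" %in% names(g)) g$drug[1] else "bevacizumab")
  })
}

#' Write concentration profiles to CSV
#' @param profiles a profile or list of profiles.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_profiles <- function(profiles, path) {
  if (inherits(profiles, "concentration_profile"))
    profiles <- list(profiles)
  num <- function(x) sprintf("%.17g", x)  # lossless double round-trip
  rows <- lapply(profiles, function(p) {
    data.frame(study_id = p$study_id, population = p$population,
               drug = p$drug, dose_mg_kg = num(p$dose_per_kg),
               n_doses = p$n_doses, interval_day = num(p$interval),
               time_day = num(p$times), conc_ug_ml = num(p$concentrations),
               sd_ug_ml = if (is.null(p$sd)) NA_character_
                          else num(p$sd))
  })
  write.csv(do.call(rbind, rows), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Validate a run configuration
#'
#' Schema check for CLI/simulation configurations: known keys only,
#' scenario label recognized, regimen fields consistent.
#'
#' @param config a named list (e.g. parsed from JSON).
#' @return the validated config with defaults filled in.
#' @export
validate_run_config <- function(config) {
  known <- c("scenario", "dose_mg_kg", "n_doses", "interval_day",
             "infusion_day", "times", "seed", "out")
  unknown <- setdiff(names(config), known)
  if (length(unknown))
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "))
  if (is.null(config$scenario)) stop("config requires a scenario label")
  defaults <- list(n_doses = 1L, interval_day = NA_real_,
                   infusion_day = 0.0625, seed = 1L,
                   times = seq(0, 70, by = 0.5))
  config <- modifyList(defaults, config)
  if (is.null(config$dose_mg_kg) || config$dose_mg_kg < 0)
    stop("config requires a non-negative dose_mg_kg")
  config
}
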