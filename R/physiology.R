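#' Species physiologies for the reduced whole-body model
#'
#' Organ-level anatomical and physiological parameters (volumes, plasma
#' and lymph flows, endosomal FcRn content, pore fractions, relative
#' target expression) for adult human and cynomolgus monkey.  The organ
#' tables are literature-typical values bundled as JSON fixtures under
#' `inst/extdata/`; they stand in for the proprietary software databases
#' commonly used for whole-body PBPK and are not an exact copy of any
#' single published table.
#'
#' @param species `"human"` or `"cynomolgus"`.
#' @return A `physiology_spec`: a list with `species`, `body_weight`
#'   (kg), `total_plasma_volume` (L), `total_lymph_flow` (L/day),
#'   `uptake_clearance_per_L` (endosomal uptake clearance per litre of
#'   endosomal space, L/day/L) and `organs`, a data frame with one row
#'   per organ and columns `name`, `plasma_volume`, `interstitial_volume`,
#'   `endosomal_volume`, `cellular_volume` (L), `blood_flow`,
#'   `lymph_flow` (L/day, plasma-equivalent), `fcrn_concentration`
#'   (nmol/L endosomal), `reflection_sigma` (vascular reflection
#'   coefficient used by the single-sigma exchange mode),
#'   `small_pore_fraction`, `large_pore_fraction` and
#'   `expression_weight` (relative target expression, >= 0).
#' @export
#' @examples
#' phys <- load_physiology("human")
#' nrow(phys$organs)
load_physiology <- function(species) {
  supported <- c("human", "cynomolgus")
  if (length(species) != 1L || !species %in% supported) {
    stop("unknown species '", paste(species, collapse = ","),
         "'; supported species: ", paste(supported, collapse = ", "))
  }
  path <- system.file("extdata", paste0("physiology_", species, ".json"),
                      package = "mabpbpk", mustWork = TRUE)
  parse_physiology(jsonlite::read_json(path, simplifyVector = TRUE))
}

parse_physiology <- function(x) {
  organs <- as.data.frame(x$organs, stringsAsFactors = FALSE)
  spec <- structure(
    list(species = x$species,
         body_weight = x$body_weight,
         total_plasma_volume = x$total_plasma_volume,
         total_lymph_flow = x$total_lymph_flow,
         uptake_clearance_per_L = x$uptake_clearance_per_L,
         organs = organs),
    class = "physiology_spec")
  validate_physiology(spec)
  spec
}

#' Validate a physiology specification
#'
#' Checks the structural invariants: non-negative volumes and flows,
#' lymph flow below blood flow, pore fractions summing to one, organ
#' lymph flows summing to the total lymph flow, and organ plasma volumes
#' not exceeding the total plasma volume (the remainder is the central
#' venous/arterial pool).
#'
#' @param spec a `physiology_spec`.
#' @return `spec`, invisibly; errors describe the violated invariant.
#' @export
validate_physiology <- function(spec) {
  org <- spec$organs
  req <- c("name", "plasma_volume", "interstitial_volume",
           "endosomal_volume", "cellular_volume", "blood_flow",
           "lymph_flow", "fcrn_concentration", "reflection_sigma",
           "small_pore_fraction", "large_pore_fraction",
           "expression_weight")
  missing <- setdiff(req, names(org))
  if (length(missing))
    stop("organ table lacks columns: ", paste(missing, collapse = ", "))
  num <- org[setdiff(req, "name")]
  if (any(vapply(num, function(v) any(!is.finite(v) | v < 0), logical(1))))
    stop("organ parameters must be finite and non-negative")
  if (any(org$lymph_flow >= org$blood_flow))
    stop("lymph flow must be smaller than blood flow for every organ")
  if (any(abs(org$small_pore_fraction + org$large_pore_fraction - 1) > 1e-9))
    stop("small and large pore fractions must sum to 1")
  if (abs(sum(org$lymph_flow) - spec$total_lymph_flow) >
        1e-6 * spec$total_lymph_flow)
    stop("organ lymph flows must sum to total_lymph_flow")
  if (sum(org$plasma_volume) > spec$total_plasma_volume)
    stop("organ plasma volumes exceed total plasma volume")
  if (spec$body_weight <= 0) stop("body_weight must be positive")
  invisible(spec)
}

#' Scale a physiology to a different body weight
#'
#' Conventional allometry: volumes scale linearly with the body-weight
#' ratio, flows with the ratio to the power 0.75.  Dimensionless organ
#' properties (reflection coefficients, pore fractions, expression
#' weights) and concentrations (FcRn) are unchanged, as is the
#' endosomal uptake clearance per litre of endosomal space.
#'
#' @param spec a `physiology_spec`.
#' @param body_weight target body weight in kg (> 0).
#' @return A rescaled `physiology_spec`.
#' @export
scale_physiology <- function(spec, body_weight) {
  stopifnot(inherits(spec, "physiology_spec"))
  if (!is.numeric(body_weight) || length(body_weight) != 1L ||
      !is.finite(body_weight) || body_weight <= 0)
    stop("body_weight must be a positive number")
  rv <- body_weight / spec$body_weight
  rf <- rv^0.75
  org <- spec$organs
  for (col in c("plasma_volume", "interstitial_volume",
                "endosomal_volume", "cellular_volume"))
    org[[col]] <- org[[col]] * rv
  for (col in c("blood_flow", "lymph_flow"))
    org[[col]] <- org[[col]] * rf
  out <- spec
  out$body_weight <- body_weight
  out$total_plasma_volume <- spec$total_plasma_volume * rv
  out$total_lymph_flow <- spec$total_lymph_flow * rf
  out$organs <- org
  validate_physiology(out)
  out
}

#' Central plasma pool volume (total plasma minus organ vascular plasma)
#' @param spec a `physiology_spec`.
#' @return volume in L.
#' @export
central_plasma_volume <- function(spec) {
  spec$total_plasma_volume - sum(spec$organs$plasma_volume)
}

#' @export
print.physiology_spec <- function(x, ...) {
  cat(sprintf("<physiology_spec> %s, %.3g kg, %d organs\n",
              x$species, x$body_weight, nrow(x$organs)))
  cat(sprintf("  plasma %.3g L (central pool %.3g L), lymph %.3g L/day\n",
              x$total_plasma_volume, central_plasma_volume(x),
              x$total_lymph_flow))
  invisible(x)
}

#' Serialize / parse a physiology specification as JSON
#' @param spec a `physiology_spec`.
#' @param path file path.
#' @return `read_physiology` returns a `physiology_spec`.
#' @export
write_physiology <- function(spec, path) {
  validate_physiology(spec)
  jsonlite::write_json(unclass(spec), path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' @rdname write_physiology
#' @export
read_physiology <- function(path) {
  parse_physiology(jsonlite::read_json(path, simplifyVector = TRUE))
}
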