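#' Drug, target and dosing definitions
#'
#' `drug_properties()` describes the antibody: physicochemistry plus
#' FcRn binding.  Only the equilibrium constant `kd_fcrn` is typically
#' known; the association rate `kon_fcrn` is a literature-typical
#' fixture (default 1 per nmol/L per day, i.e. about 1.2e4 1/M/s) and
#' the dissociation rate is derived as `koff_fcrn = kon_fcrn * kd_fcrn`.
#'
#' @param name drug label.
#' @param molecular_weight g/mol (IgG default 150 kDa).
#' @param hydrodynamic_radius nm (IgG default 5.34 nm).
#' @param kd_fcrn equilibrium dissociation constant with FcRn, nmol/L.
#' @param kon_fcrn FcRn association rate, 1/(nmol/L)/day.
#' @return A `drug_properties` list with the derived `koff_fcrn` (1/day).
#' @export
#' @examples
#' drug_properties(kd_fcrn = 450)
drug_properties <- function(name = "bevacizumab",
                            molecular_weight = 150000,
                            hydrodynamic_radius = 5.34,
                            kd_fcrn = 450,
                            kon_fcrn = 1.0) {
  stopifnot(molecular_weight > 0, hydrodynamic_radius > 0,
            kon_fcrn >= 0)
  if (!is.numeric(kd_fcrn) || kd_fcrn <= 0)
    stop("kd_fcrn must be positive")
  structure(
    list(name = name,
         molecular_weight = molecular_weight,
         hydrodynamic_radius = hydrodynamic_radius,
         kd_fcrn = kd_fcrn,
         kon_fcrn = kon_fcrn,
         koff_fcrn = kon_fcrn * kd_fcrn),
    class = "drug_properties")
}

#' Soluble-target (TMDD) parameters
#'
#' Receptor turnover and drug binding constants for a soluble target
#' such as VEGF-A.  Only `koff` and the equilibrium constant are
#' measured in vitro; the association rate is derived as
#' `kon = koff / kd_target`.  The zero-order synthesis rate in each
#' compartment follows `ksyn = kdeg * R0` so that the drug-free system
#' is at steady state.
#'
#' @param kd_target equilibrium dissociation constant, nmol/L (> 0).
#' @param koff first-order dissociation rate, 1/day.
#' @param kdeg first-order degradation rate of free target, 1/day.
#' @param kint first-order internalization rate of the complex, 1/day.
#' @param r0_reference reference (plasma) target concentration at
#'   steady state, nmol/L.  Zero switches the TMDD mechanism off while
#'   keeping the states in place.
#' @return A `target_properties` list including the derived `kon`
#'   (1/(nmol/L)/day).
#' @export
#' @examples
#' target_properties(kd_target = 0.058, koff = 2.7, kdeg = 0.18,
#'                   kint = 0.043, r0_reference = 0.3)
target_properties <- function(kd_target, koff, kdeg = 0, kint = 0,
                              r0_reference = 0) {
  if (!is.numeric(kd_target) || kd_target <= 0)
    stop("kd_target must be positive")
  stopifnot(koff >= 0, kdeg >= 0, kint >= 0, r0_reference >= 0)
  structure(
    list(kd_target = kd_target,
         koff = koff,
         kon = kon_from(koff, kd_target),
         kdeg = kdeg,
         kint = kint,
         r0_reference = r0_reference),
    class = "target_properties")
}

#' Association rate from dissociation rate and equilibrium constant
#'
#' `kon = koff / KD`.
#'
#' @param koff 1/day.
#' @param kd_target nmol/L, strictly positive.
#' @return kon in 1/(nmol/L)/day.
#' @export
#' @examples
#' kon_from(2.7, 0.058)   # human VEGF-A constants
kon_from <- function(koff, kd_target) {
  if (!is.numeric(kd_target) || any(kd_target <= 0))
    stop("kd_target must be positive")
  koff / kd_target
}

#' Intravenous dosing regimen
#'
#' @param dose_per_kg dose in mg/kg (> 0, or 0 for a null regimen).
#' @param n_doses number of administrations (integer >= 1).
#' @param interval dosing interval in days (required when `n_doses > 1`).
#' @param infusion_duration infusion length in days; default 90 minutes.
#'   Zero means bolus.
#' @return A `dosing_regimen` list; route is fixed to intravenous.
#' @export
dosing_regimen <- function(dose_per_kg, n_doses = 1L, interval = NA_real_,
                           infusion_duration = 0.0625) {
  if (!is.numeric(dose_per_kg) || dose_per_kg < 0)
    stop("dose_per_kg must be non-negative")
  n_doses <- as.integer(n_doses)
  if (is.na(n_doses) || n_doses < 1L) stop("n_doses must be >= 1")
  if (n_doses > 1L && (!is.finite(interval) || interval <= 0))
    stop("interval must be positive when n_doses > 1")
  if (infusion_duration < 0) stop("infusion_duration must be >= 0")
  structure(
    list(dose_per_kg = dose_per_kg, n_doses = n_doses,
         interval = interval, infusion_duration = infusion_duration,
         route = "intravenous"),
    class = "dosing_regimen")
}

# Endosomal sorting fixtures shared by all models.  These are not
# printed in typical mAb PBPK reports; they were calibrated once (see
# scripts/calibrate_endosomal.R) so that a cynomolgus model with
# kd_fcrn = 450 nmol/L shows an IgG-like terminal half-life and the
# characteristic blunted (non-equilibrium) response of half-life to
# FcRn affinity.  k_rec 160/day corresponds to a ~9 min endosomal
# transit; k_deg_endo 5/day to a ~3 h endosomal residence before
# lysosomal degradation.
#' Endosomal sorting rate constants (package fixtures)
#' @return list with `k_deg_endo`, `k_rec` (1/day) and
#'   `f_recycle_plasma` (fraction of recycled complex returned to the
#'   vascular side).
#' @export
endosomal_defaults <- function() {
  list(k_deg_endo = 5, k_rec = 160, f_recycle_plasma = 0.7)
}
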