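#' Interspecies and population scaling rules
#'
#' `scale_kd_fcrn_to_human()` applies the IgG1 convention that the
#' FcRn dissociation constant is about 2-fold higher in humans than in
#' cynomolgus monkey.  `apply_fc_variant()` divides the FcRn KD by the
#' in vitro affinity-improvement fold of an Fc-engineered variant.
#' `scale_target_to_patients()` multiplies the reference target
#' concentration, applied in every expressing compartment, to reflect
#' elevated target levels (e.g. VEGF-A 2- to 10-fold higher in cancer
#' patients than in healthy volunteers).
#'
#' @param kd_nhp,kd FcRn dissociation constant, nmol/L (> 0).
#' @param factor,affinity_fold,fold positive scaling factors.
#' @param r0_hv reference target concentration in healthy volunteers,
#'   nmol/L.
#' @return scaled value, same units as input.
#' @export
#' @examples
#' scale_kd_fcrn_to_human(450)   # 900
#' apply_fc_variant(450, 11)     # ~41
scale_kd_fcrn_to_human <- function(kd_nhp, factor = 2) {
  if (kd_nhp <= 0) stop("kd_nhp must be positive")
  kd_nhp * factor
}

#' @rdname scale_kd_fcrn_to_human
#' @export
apply_fc_variant <- function(kd, affinity_fold) {
  if (affinity_fold <= 0) stop("affinity_fold must be positive")
  kd / affinity_fold
}

#' @rdname scale_kd_fcrn_to_human
#' @export
scale_target_to_patients <- function(r0_hv, fold) {
  if (fold <= 0) stop("fold must be positive")
  r0_hv * fold
}

scenario_labels <- c("NHP-bev", "NHP-xtend", "HV-apriori", "HV-refined",
                     "Patients-apriori", "Patients-refined")

#' Build a population scenario
#'
#' Returns the full parameterization (drug, target, physiology,
#' per-parameter provenance) for each step of the NHP -> healthy
#' volunteer -> cancer patient translation workflow of a
#' bevacizumab-like antibody:
#'
#' * `NHP-bev`: cynomolgus, KD-FcRn 450 nmol/L (fitted in vivo value),
#'   NHP VEGF-A binding (KD 0.032 nmol/L, koff 3.5/day) without
#'   turnover (reference VEGF-A concentration 0: binding negligible).
#' * `NHP-xtend`: as above with KD-FcRn 41 nmol/L (11-fold higher
#'   FcRn affinity Fc variant).
#' * `HV-apriori`: human physiology, KD-FcRn 900 (2 x NHP), human
#'   VEGF-A binding (KD 0.058, koff 3.5), VEGF-A 1.5 nmol/L, no
#'   turnover/internalization (TMDD mechanism not yet introduced).
#' * `HV-refined`: KD-FcRn 940, koff 2.7/day, kdeg 0.18/day,
#'   kint 0.043/day, VEGF-A 0.3 nmol/L.
#' * `Patients-apriori`: HV-refined with VEGF-A scaled by
#'   `patient_fold` (2-10; default 10, i.e. 3 nmol/L).
#' * `Patients-refined`: VEGF-A 3.86 nmol/L (fitted), other
#'   parameters as HV-refined.
#'
#' @param label one of
#'   `r paste0('"', paste(scenario_labels, collapse = '", "'), '"')`.
#' @param patient_fold VEGF-A elevation fold for `Patients-apriori`.
#' @return a `population_scenario`: list with `label`, `drug`,
#'   `target`, `physiology` and a named `provenance` character vector
#'   (`"fitted"`, `"literature"` or `"scaled"` per parameter).
#' @export
build_scenario <- function(label, patient_fold = 10) {
  if (length(label) != 1L || !label %in% scenario_labels)
    stop("unknown scenario '", paste(label, collapse = ","),
         "'; available: ", paste(scenario_labels, collapse = ", "))
  nhp_target <- function(r0) target_properties(
    kd_target = 0.032, koff = 3.5, kdeg = 0, kint = 0, r0_reference = r0)
  s <- switch(
    label,
    "NHP-bev" = list(
      physiology = load_physiology("cynomolgus"),
      drug = drug_properties(name = "bevacizumab", kd_fcrn = 450),
      target = nhp_target(0),
      provenance = c(kd_fcrn = "fitted", kd_target = "literature",
                     koff = "literature", r0_reference = "literature")),
    "NHP-xtend" = list(
      physiology = load_physiology("cynomolgus"),
      drug = drug_properties(name = "xtend-bevacizumab", kd_fcrn = 41),
      target = nhp_target(0),
      provenance = c(kd_fcrn = "scaled", kd_target = "literature",
                     koff = "literature", r0_reference = "literature")),
    "HV-apriori" = list(
      physiology = load_physiology("human"),
      drug = drug_properties(kd_fcrn = scale_kd_fcrn_to_human(450)),
      target = target_properties(kd_target = 0.058, koff = 3.5,
                                 kdeg = 0, kint = 0, r0_reference = 1.5),
      provenance = c(kd_fcrn = "scaled", kd_target = "literature",
                     koff = "literature", r0_reference = "literature")),
    "HV-refined" = list(
      physiology = load_physiology("human"),
      drug = drug_properties(kd_fcrn = 940),
      target = target_properties(kd_target = 0.058, koff = 2.7,
                                 kdeg = 0.18, kint = 0.043,
                                 r0_reference = 0.3),
      provenance = c(kd_fcrn = "fitted", kd_target = "literature",
                     koff = "literature", kdeg = "fitted",
                     kint = "fitted", r0_reference = "fitted")),
    "Patients-apriori" = list(
      physiology = load_physiology("human"),
      drug = drug_properties(kd_fcrn = 940),
      target = target_properties(
        kd_target = 0.058, koff = 2.7, kdeg = 0.18, kint = 0.043,
        r0_reference = scale_target_to_patients(0.3, patient_fold)),
      provenance = c(kd_fcrn = "scaled", kd_target = "literature",
                     koff = "literature", kdeg = "scaled",
                     kint = "scaled", r0_reference = "scaled")),
    "Patients-refined" = list(
      physiology = load_physiology("human"),
      drug = drug_properties(kd_fcrn = 940),
      target = target_properties(kd_target = 0.058, koff = 2.7,
                                 kdeg = 0.18, kint = 0.043,
                                 r0_reference = 3.86),
      provenance = c(kd_fcrn = "scaled", kd_target = "literature",
                     koff = "literature", kdeg = "scaled",
                     kint = "scaled", r0_reference = "fitted")))
  structure(c(list(label = label), s), class = "population_scenario")
}

#' @export
print.population_scenario <- function(x, ...) {
  cat(sprintf(
    "<population_scenario> %s: KD-FcRn %.4g nmol/L, VEGF-A %.4g nmol/L (%s)\n",
    x$label, x$drug$kd_fcrn, x$target$r0_reference,
    x$physiology$species))
  invisible(x)
}

#' Build the whole-body model for a scenario
#' @param scenario a `population_scenario`.
#' @param ... passed to [build_model()].
#' @return a `mab_model`.
#' @export
scenario_model <- function(scenario, ...) {
  build_model(scenario$physiology, scenario$drug, scenario$target, ...)
}

#' Modify scenario parameters
#'
#' Returns a copy of the scenario with named parameters replaced.
#' Supported names: `kd_fcrn` (koff_fcrn re-derived), `kd_target` (kon
#' re-derived), `koff` (kon re-derived), `kdeg`, `kint`,
#' `r0_reference`.
#'
#' @param scenario a `population_scenario`.
#' @param values named numeric vector or list.
#' @param provenance provenance tag recorded for the touched
#'   parameters.
#' @return the updated scenario.
#' @export
set_scenario_params <- function(scenario, values,
                                provenance = "fitted") {
  values <- as.list(values)
  allowed <- c("kd_fcrn", "kd_target", "koff", "kdeg", "kint",
               "r0_reference")
  bad <- setdiff(names(values), allowed)
  if (length(bad))
    stop("unknown parameters: ", paste(bad, collapse = ", "),
         "; supported: ", paste(allowed, collapse = ", "))
  drug <- scenario$drug
  tgt <- scenario$target
  if (!is.null(values$kd_fcrn))
    drug <- drug_properties(name = drug$name,
                            molecular_weight = drug$molecular_weight,
                            hydrodynamic_radius = drug$hydrodynamic_radius,
                            kd_fcrn = values$kd_fcrn,
                            kon_fcrn = drug$kon_fcrn)
  tv <- list(kd_target = tgt$kd_target, koff = tgt$koff,
             kdeg = tgt$kdeg, kint = tgt$kint,
             r0_reference = tgt$r0_reference)
  tv <- modifyList(tv, values[intersect(names(values), names(tv))])
  tgt <- do.call(target_properties, tv)
  out <- scenario
  out$drug <- drug
  out$target <- tgt
  out$provenance[names(values)] <- provenance
  out
}

#' Serialize / parse a scenario as JSON
#' @param scenario a `population_scenario`.
#' @param path file path.
#' @return `read_scenario` returns a `population_scenario`.
#' @export
write_scenario <- function(scenario, path) {
  x <- list(label = scenario$label,
            drug = unclass(scenario$drug),
            target = unclass(scenario$target),
            physiology = unclass(scenario$physiology),
            provenance = as.list(scenario$provenance))
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' @rdname write_scenario
#' @export
read_scenario <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  drug <- do.call(drug_properties,
                  x$drug[c("name", "molecular_weight",
                           "hydrodynamic_radius", "kd_fcrn", "kon_fcrn")])
  target <- do.call(target_properties,
                    x$target[c("kd_target", "koff", "kdeg", "kint",
                               "r0_reference")])
  structure(
    list(label = x$label, physiology = parse_physiology(x$physiology),
         drug = drug, target = target,
         provenance = unlist(x$provenance)),
    class = "population_scenario")
}
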