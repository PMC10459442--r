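# Shared fixtures.  Everything is built in code; no binary data.

# Loose-but-accurate solver settings for tests where sub-0.1% accuracy
# is irrelevant (recovery studies, smoke tests).  The headline
# invariant tests (mass balance, linearity) use the package defaults.
fast_solver <- list(rtol = 1e-4, atol = 1e-6, h_init = 1e-3)

toy_organ <- function(lymph_flow = 1, sigma = 0.95) {
  data.frame(name = "toy", plasma_volume = 0.1,
             interstitial_volume = 0.5, endosomal_volume = 1e-3,
             cellular_volume = 1, blood_flow = 100,
             lymph_flow = lymph_flow, fcrn_concentration = 1000,
             reflection_sigma = sigma, small_pore_fraction = 0.95,
             large_pore_fraction = 0.05, expression_weight = 1)
}

# A two-organ physiology small enough for oracle-level comparisons.
tiny_physiology <- function() {
  organs <- data.frame(
    name = c("liver", "muscle"),
    plasma_volume = c(0.05, 0.08),
    interstitial_volume = c(0.2, 0.9),
    endosomal_volume = c(5e-4, 8e-4),
    cellular_volume = c(0.5, 3),
    blood_flow = c(120, 60),
    lymph_flow = c(0.12, 0.08),
    fcrn_concentration = c(1000, 1000),
    reflection_sigma = c(0.85, 0.95),
    small_pore_fraction = c(0.95, 0.95),
    large_pore_fraction = c(0.05, 0.05),
    expression_weight = c(1, 0.5))
  structure(list(species = "human", body_weight = 5,
                 total_plasma_volume = 0.4,
                 total_lymph_flow = 0.2,
                 uptake_clearance_per_L = 240,
                 organs = organs),
            class = "physiology_spec")
}

tiny_model <- function(target = NULL, ...) {
  build_model(tiny_physiology(), drug_properties(kd_fcrn = 450),
              target = target, ...)
}

example_target <- function(r0 = 1) {
  target_properties(kd_target = 0.058, koff = 2.7, kdeg = 0.18,
                    kint = 0.043, r0_reference = r0)
}

# Pure-R reference RHS for the whole-body model, composed from the
# exported per-mechanism operations (two_pore_flux, fcrn_endosome_rhs,
# tmdd_rhs) plus the flow bookkeeping.  Written independently of the
# compiled code; used as the oracle in test-pbpk-core.R.
reference_rhs <- function(model, y, inf_rate = 0) {
  stopifnot(model$fcrn_dynamic)          # oracle uses the dynamic form
  phys <- model$physiology
  org <- phys$organs
  drug <- model$drug
  tgt <- model$target
  endo <- endosomal_defaults()
  vc <- central_plasma_volume(phys)
  nm <- model$state_names
  dy <- setNames(numeric(length(y)), nm)
  cc <- y[["central.plasma"]] / vc
  sigL <- model$params$sigma_lymph
  clup_rate <- phys$uptake_clearance_per_L
  for (i in seq_len(nrow(org))) {
    o <- org[i, ]
    s <- function(part) paste0(o$name, ".", part)
    cp <- y[[s("plasma")]] / o$plasma_volume
    ci <- y[[s("interstitial")]] / o$interstitial_volume
    dy[["central.plasma"]] <- dy[["central.plasma"]] +
      (o$blood_flow - o$lymph_flow) * cp - o$blood_flow * cc +
      o$lymph_flow * (1 - sigL) * ci
    f <- two_pore_flux(cp, ci, o, drug, mode = model$flux_mode)
    er <- fcrn_endosome_rhs(
      c(free = y[[s("endosomal")]], fcrn = y[[s("fcrn")]],
        complex = y[[s("fcrn_complex")]]),
      o, drug,
      rates = c(endo, list(cl_up = clup_rate * o$endosomal_volume,
                           c_plasma = cp, c_interstitial = ci)))
    dy[[s("plasma")]] <- o$blood_flow * cc -
      (o$blood_flow - o$lymph_flow) * cp - f -
      clup_rate * o$endosomal_volume * cp + er$to_plasma
    dy[[s("interstitial")]] <- f - o$lymph_flow * (1 - sigL) * ci -
      clup_rate * o$endosomal_volume * ci + er$to_interstitial
    dy[[s("endosomal")]] <- er$free
    dy[[s("fcrn")]] <- er$fcrn
    dy[[s("fcrn_complex")]] <- er$complex
    dy[["eliminated.endosomal"]] <-
      dy[["eliminated.endosomal"]] + er$degraded
  }
  dy[["central.plasma"]] <- dy[["central.plasma"]] + inf_rate
  if (!is.null(tgt)) {
    r0map <- distribute_target(
      tgt$r0_reference, setNames(org$expression_weight, org$name))
    tm <- tmdd_rhs(cc, y[["central.R"]] / vc, y[["central.DR"]] / vc,
                   tgt, r0map$plasma)
    dy[["central.R"]] <- tm$dR * vc
    dy[["central.DR"]] <- tm$dDR * vc
    dy[["central.plasma"]] <- dy[["central.plasma"]] + tm$dD * vc
    dy[["eliminated.internalized"]] <-
      dy[["eliminated.internalized"]] +
      tgt$kint * y[["central.DR"]]
    for (nm_o in names(r0map$interstitial)) {
      o <- org[org$name == nm_o, ]
      vi <- o$interstitial_volume
      tm <- tmdd_rhs(y[[paste0(nm_o, ".interstitial")]] / vi,
                     y[[paste0(nm_o, ".R")]] / vi,
                     y[[paste0(nm_o, ".DR")]] / vi,
                     tgt, r0map$interstitial[[nm_o]])
      dy[[paste0(nm_o, ".R")]] <- tm$dR * vi
      dy[[paste0(nm_o, ".DR")]] <- tm$dDR * vi
      dy[[paste0(nm_o, ".interstitial")]] <-
        dy[[paste0(nm_o, ".interstitial")]] + tm$dD * vi
      dy[["eliminated.internalized"]] <-
        dy[["eliminated.internalized"]] +
        tgt$kint * y[[paste0(nm_o, ".DR")]]
    }
  }
  dy
}
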