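# One-off calibration of the endosomal fixtures.  Run from the repo
# root after editing scripts/make_physiology.R; the resulting rounded
# values are frozen there and in R/drug.R.
#
# 1. Sorting-rate fixtures (analytic).  With clamped free FcRn the
#    fraction of endosomal drug that is degraded rather than recycled
#    is, per uptaken molecule,
#        P(KD) = kde * (koff + krec) / (kde * (koff + krec) + kc * krec)
#    with koff = kon * KD and capture rate kc = kon * [FcRn].  Organ
#    clearance is proportional to P, so the terminal half-life ratio of
#    two FcRn affinities is ~ P(KD1)/P(KD2), and the local sensitivity
#    of clearance to KD is d ln P / d ln KD = (koff/(koff+krec))(1-P).
#    The fixtures kon = 1 /(nmol/L)/day (~1.2e4 1/M/s),
#    [FcRn] = 1000 nmol/L, kde = 5/day, krec = 160/day (~9 min
#    endosomal transit) give the non-equilibrium behaviour reported for
#    IgG Fc variants: a ~3-fold half-life change for an 11-fold
#    affinity change (equilibrium models predict ~11-fold).
P <- function(kd, kon = 1, fcrn = 1000, kde = 5, krec = 160) {
  koff <- kon * kd
  kde * (koff + krec) / (kde * (koff + krec) + kon * fcrn * krec)
}
cat(sprintf("P(450)/P(41)   = %.3f (expect ~3, window 2-5)\n",
            P(450) / P(41)))
cat(sprintf("P(450)/P(45)   = %.3f (10-fold affinity, expect < 5)\n",
            P(450) / P(45)))
cat(sprintf("dlnP/dlnKD@940 = %.3f (FcRn sensitivity of clearance)\n",
            940 / (940 + 160) * (1 - P(940))))

# 2. Species uptake clearance per litre of endosomal space, calibrated
#    so that (a) the cynomolgus model with KD-FcRn 450 nmol/L shows an
#    IgG-like terminal half-life of ~10 days and (b) the human model
#    with the refined KD-FcRn 940 nmol/L shows the ~21-day terminal
#    half-life reported for bevacizumab.
suppressMessages(library(mabpbpk))
thalf_for <- function(species, kd, clup) {
  phys <- load_physiology(species)
  phys$uptake_clearance_per_L <- clup
  m <- build_model(phys, drug_properties(kd_fcrn = kd))
  tt <- seq(0, 70, by = 0.5)
  sim <- simulate_regimen(m, dosing_regimen(4), output_times = tt)
  terminal_half_life(sim$profile)
}
cal <- function(species, kd, target) {
  r <- uniroot(function(cl) thalf_for(species, kd, cl) - target,
               c(50, 3000), tol = 1)
  cat(sprintf("%s: uptake clearance %.0f L/day/L -> t1/2 %.2f d\n",
              species, r$root, thalf_for(species, kd, r$root)))
  r$root
}
cal("cynomolgus", 450, 10)
cal("human", 940, 21)
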