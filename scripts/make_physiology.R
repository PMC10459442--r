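# Builds the bundled physiology fixtures (inst/extdata/*.json).
# Organ values are literature-typical whole-body PBPK numbers for a
# 71 kg adult human; the cynomolgus table is derived from the human one
# by allometry (volumes ~ BW, flows ~ BW^0.75) at 6.2 kg.  The
# species-level endosomal uptake clearance per litre of endosomal space
# is calibrated by scripts/calibrate_endosomal.R and frozen here.
# Run from the repository root:  Rscript scripts/make_physiology.R

human <- list(
  species = "human",
  body_weight = 71,
  total_plasma_volume = 3.1,
  total_lymph_flow = 2.91,
  uptake_clearance_per_L = 241,   # L/day per L endosome (calibrated)
  organs = data.frame(
    name = c("lung", "liver", "kidney", "heart", "spleen", "gut",
             "muscle", "skin", "adipose", "brain", "rest"),
    plasma_volume = c(0.15, 0.30, 0.06, 0.015, 0.03, 0.15,
                      0.40, 0.12, 0.08, 0.03, 0.15),
    interstitial_volume = c(0.30, 0.60, 0.20, 0.05, 0.05, 0.45,
                            6.00, 1.70, 2.00, 0.20, 1.00),
    endosomal_volume = c(0.0020, 0.0040, 0.0010, 0.0003, 0.0005,
                         0.0020, 0.0060, 0.0030, 0.0020, 0.0005,
                         0.0020),
    cellular_volume = c(0.70, 1.20, 0.25, 0.25, 0.15, 1.00,
                        24.0, 2.60, 11.0, 1.20, 3.00),
    blood_flow = c(430, 800, 550, 150, 80, 600,
                   380, 120, 110, 350, 250),
    lymph_flow = c(0.10, 0.80, 0.20, 0.05, 0.05, 0.50,
                   0.45, 0.30, 0.20, 0.01, 0.25),
    fcrn_concentration = rep(1000, 11),
    reflection_sigma = c(0.90, 0.85, 0.90, 0.95, 0.85, 0.90,
                         0.95, 0.95, 0.95, 0.99, 0.95),
    small_pore_fraction = rep(0.95, 11),
    large_pore_fraction = rep(0.05, 11),
    expression_weight = c(0.8, 0.6, 0.9, 0.6, 0.4, 0.6,
                          0.5, 0.6, 0.5, 0.0, 0.4)))

bw_ratio <- 6.2 / 71
cyno <- human
cyno$species <- "cynomolgus"
cyno$body_weight <- 6.2
cyno$total_plasma_volume <- human$total_plasma_volume * bw_ratio
cyno$total_lymph_flow <- human$total_lymph_flow * bw_ratio^0.75
cyno$uptake_clearance_per_L <- 954    # L/day per L endosome (calibrated)
for (col in c("plasma_volume", "interstitial_volume",
              "endosomal_volume", "cellular_volume"))
  cyno$organs[[col]] <- human$organs[[col]] * bw_ratio
for (col in c("blood_flow", "lymph_flow"))
  cyno$organs[[col]] <- human$organs[[col]] * bw_ratio^0.75

for (x in list(human, cyno)) {
  stopifnot(abs(sum(x$organs$lymph_flow) - x$total_lymph_flow) <
              1e-6 * x$total_lymph_flow,
            sum(x$organs$plasma_volume) < x$total_plasma_volume)
  jsonlite::write_json(
    x, file.path("inst", "extdata",
                 paste0("physiology_", x$species, ".json")),
    auto_unbox = TRUE, digits = NA, dataframe = "columns", pretty = TRUE)
}
cat("wrote physiology fixtures\n")
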