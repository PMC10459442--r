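test_that("translation arithmetic is exact", {
  expect_equal(scale_kd_fcrn_to_human(450), 900)
  expect_equal(scale_kd_fcrn_to_human(940, factor = 1), 940)
  expect_equal(scale_kd_fcrn_to_human(940), 1880)
  expect_equal(apply_fc_variant(450, 11), 450 / 11)
  expect_equal(round(apply_fc_variant(450, 11)), 41)
  expect_equal(apply_fc_variant(7, 1), 7)
  # in vitro Biacore ratio rounds to the 11-fold affinity gain
  expect_equal(round(2460 / 218), 11)
  expect_equal(2460 / 218, 11.28, tolerance = 1e-3)
  expect_equal(scale_target_to_patients(0.3, 10), 3)
  expect_equal(scale_target_to_patients(0.3, 2), 0.6)
  expect_equal(scale_target_to_patients(0.42, 1), 0.42)
  expect_error(scale_kd_fcrn_to_human(-1), "positive")
  expect_error(apply_fc_variant(450, 0), "positive")
})

test_that("scenarios carry the published parameter sets", {
  nhp <- build_scenario("NHP-bev")
  expect_equal(nhp$drug$kd_fcrn, 450)
  expect_equal(nhp$target$kd_target, 0.032)
  expect_equal(nhp$target$koff, 3.5)
  expect_identical(nhp$physiology$species, "cynomolgus")

  xt <- build_scenario("NHP-xtend")
  expect_equal(xt$drug$kd_fcrn, 41)

  hva <- build_scenario("HV-apriori")
  expect_equal(hva$drug$kd_fcrn, 900)
  expect_equal(hva$target$r0_reference, 1.5)
  expect_equal(hva$target$kdeg, 0)       # TMDD not yet introduced

  hvr <- build_scenario("HV-refined")
  expect_equal(hvr$drug$kd_fcrn, 940)
  expect_equal(hvr$target$kdeg, 0.18)
  expect_equal(hvr$target$kint, 0.043)
  expect_equal(hvr$target$koff, 2.7)
  expect_equal(hvr$target$r0_reference, 0.3)

  pta <- build_scenario("Patients-apriori")
  expect_equal(pta$target$r0_reference, 3)
  expect_equal(build_scenario("Patients-apriori",
                              patient_fold = 2)$target$r0_reference,
               0.6)
  ptr <- build_scenario("Patients-refined")
  expect_equal(ptr$target$r0_reference, 3.86)
  expect_equal(ptr$drug$kd_fcrn, 940)

  expect_error(build_scenario("Mouse"), "NHP-bev")
  # every parameter carries a provenance tag
  for (lbl in c("NHP-bev", "HV-refined", "Patients-refined")) {
    sc <- build_scenario(lbl)
    expect_true(all(sc$provenance %in%
                      c("fitted", "literature", "scaled")))
  }
})

test_that("a priori HV differs from NHP only by physiology, doubled
           KD-FcRn and human target constants", {
  nhp <- build_scenario("NHP-bev")
  hv <- build_scenario("HV-apriori")
  expect_equal(hv$drug$kd_fcrn, 2 * nhp$drug$kd_fcrn)
  same <- setdiff(names(nhp$drug), c("kd_fcrn", "koff_fcrn"))
  expect_equal(nhp$drug[same], hv$drug[same])
  expect_identical(hv$physiology$species, "human")
  # the human target constants replace the NHP in vitro values
  expect_equal(hv$target$kd_target, 0.058)
  expect_equal(hv$target$koff, 3.5)
  expect_equal(hv$target[c("kdeg", "kint")],
               nhp$target[c("kdeg", "kint")])
})

test_that("scenarios round-trip through JSON serialization", {
  sc <- build_scenario("Patients-refined")
  path <- withr::local_tempfile(fileext = ".json")
  write_scenario(sc, path)
  back <- read_scenario(path)
  expect_identical(back$label, sc$label)
  expect_equal(back$drug, sc$drug)
  expect_equal(back$target, sc$target)
  expect_equal(back$physiology$organs, sc$physiology$organs,
               tolerance = 1e-14)
})

test_that("set_scenario_params re-derives dependent rates", {
  sc <- build_scenario("HV-refined")
  sc2 <- set_scenario_params(sc, list(kd_fcrn = 470, kd_target = 0.1))
  expect_equal(sc2$drug$koff_fcrn, 470 * sc$drug$kon_fcrn)
  expect_equal(sc2$target$kon, sc$target$koff / 0.1)
  expect_error(set_scenario_params(sc, list(nonsense = 1)), "unknown")
})
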