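# A small NHP dataset generated from known truth; reused across tests.
nhp_truth_data <- local({
  des <- study_design("NHP", 4, sampling_times = c(0.25, 1, 3, 7, 14,
                                                   28, 42, 60),
                      noise_cv = 0, study_id = "nhp_fit")
  function() generate_profile(build_scenario("NHP-bev"), des,
                              solver = fast_solver)
})

test_that("validation rejects malformed fit requests", {
  sc <- build_scenario("NHP-bev")
  ds <- nhp_truth_data()
  short <- ds; short$times <- short$times[1:2]
  short$concentrations <- short$concentrations[1:2]
  expect_error(fit_scenario(sc, short, free = "kd_fcrn"), "3 points")
  zero <- ds; zero$concentrations[3] <- 0
  expect_error(fit_scenario(sc, zero, free = "kd_fcrn"),
               "non-positive")
  expect_error(fit_scenario(sc, ds, free = character(0)), "at least")
  expect_error(fit_scenario(sc, ds, free = c("kon", "koff",
                                             "kd_target")),
               "unidentifiable")
  expect_error(fit_scenario(sc, ds, free = "banana"), "fittable")
})

test_that("zero-noise data: truth start gives near-zero objective and
           a perturbed start recovers the truth within 2%", {
  ds <- nhp_truth_data()
  sc_truth <- build_scenario("NHP-bev")          # kd_fcrn = 450
  f0 <- fit_scenario(sc_truth, ds, free = "kd_fcrn",
                     solver = fast_solver)
  expect_lt(f0$objective, 1e-4)
  expect_equal(unname(f0$estimates), 450, tolerance = 0.02)

  sc_off <- set_scenario_params(sc_truth, list(kd_fcrn = 3 * 450))
  f1 <- fit_scenario(sc_off, ds, free = "kd_fcrn",
                     solver = fast_solver)
  expect_equal(unname(f1$estimates), 450, tolerance = 0.02)
  expect_true(f1$converged)
  expect_identical(f1$n_points, length(ds$times))
  # reported objective is the best visited point
  expect_equal(f1$objective, min(f1$trace$objective))
})

test_that("the fit is invariant to dataset ordering", {
  ds <- nhp_truth_data()
  first <- ds; first$times <- ds$times[1:4]
  first$concentrations <- ds$concentrations[1:4]
  first$study_id <- "a"
  second <- ds; second$times <- ds$times[5:8]
  second$concentrations <- ds$concentrations[5:8]
  second$study_id <- "b"
  sc <- set_scenario_params(build_scenario("NHP-bev"),
                            list(kd_fcrn = 900))
  f_ab <- fit_scenario(sc, list(first, second), free = "kd_fcrn",
                       solver = fast_solver)
  f_ba <- fit_scenario(sc, list(second, first), free = "kd_fcrn",
                       solver = fast_solver)
  expect_equal(f_ab$estimates, f_ba$estimates, tolerance = 1e-10)
})

test_that("stage ordering contract of the sequential workflow", {
  ds <- list(nhp_truth_data())
  expect_error(sequential_refinement(ds, stages = c("Patients", "HV")),
               "order")
  expect_error(sequential_refinement(ds, stages = "Monkeys"),
               "unknown stages")
  # missing dose groups are reported with the stage name
  expect_error(sequential_refinement(ds, stages = c("NHP", "HV"),
                                     solver = fast_solver),
               "HV")
})

test_that("a single-stage workflow reduces to one fit", {
  ds <- list(nhp_truth_data())
  r <- sequential_refinement(ds, stages = "NHP", solver = fast_solver)
  expect_named(r$fits, "NHP")
  expect_s3_class(r$fits$NHP, "fit_result")
  expect_equal(unname(r$fits$NHP$estimates["kd_fcrn"]), 450,
               tolerance = 0.02)
  expect_identical(r$scenario$provenance[["kd_fcrn"]], "fitted")
})
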