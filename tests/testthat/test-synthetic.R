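test_that("noise-free generation reproduces the simulation exactly", {
  sc <- build_scenario("NHP-bev")
  des <- study_design("NHP", 4, sampling_times = c(1, 7, 21),
                      noise_cv = 0)
  p <- generate_profile(sc, des, solver = fast_solver)
  sim <- simulate_regimen(scenario_model(sc, solver = fast_solver),
                          dosing_regimen(4), output_times = c(1, 7, 21))
  expect_identical(p$concentrations, sim$plasma_conc)
  expect_identical(p$population, "NHP")
})

test_that("generation is deterministic under a seed and responds to
           seed changes", {
  sc <- build_scenario("NHP-bev")
  des1 <- study_design("NHP", 4, sampling_times = c(1, 7, 21),
                       noise_cv = 0.2, seed = 42)
  p1 <- generate_profile(sc, des1, solver = fast_solver)
  p2 <- generate_profile(sc, des1, solver = fast_solver)
  expect_identical(p1$concentrations, p2$concentrations)
  des2 <- des1; des2$seed <- 43L
  p3 <- generate_profile(sc, des2, solver = fast_solver)
  expect_false(any(p1$concentrations == p3$concentrations))
})

test_that("lognormal noise model: geometric-mean unbiasedness and CV
           calibration", {
  conc <- c(50, 20, 5, 1)
  # geometric mean of 1000 replicates stays within 2% of truth
  noisy <- apply_lognormal_noise(conc, noise_cv = 0.2,
                                 n_replicates = 1000, seed = 3)
  expect_lt(max(abs(noisy / conc - 1)), 0.02)
  # empirical CV of single replicates converges to the design CV
  draws <- vapply(1:1000, function(s)
    apply_lognormal_noise(1, 0.2, 1L, seed = s), numeric(1))
  expect_lt(abs(sd(draws) / mean(draws) - 0.2), 0.05 * 0.2 + 0.01)
  expect_identical(apply_lognormal_noise(conc, 0), conc)
})

test_that("study designs validate their grids", {
  expect_error(study_design("HV", 1, sampling_times = c(2, 1)),
               "increasing")
  expect_error(study_design("HV", 1, sampling_times = c(0, 1)),
               "positive")
  expect_error(study_design("HV", 1, sampling_times = c(1, 2),
                            noise_cv = -0.1), ">= 0")
  des <- study_design("HV", 1, sampling_times = c(1, 500))
  expect_error(generate_profile(build_scenario("HV-refined"), des,
                                solver = fast_solver), "horizon")
})

test_that("the synthetic corpus has the published study structure and
           round-trips through CSV", {
  corpus <- generate_study_set(seed = 5, noise_cv = 0.1,
                               solver = fast_solver)
  expect_length(corpus, 10L)
  pops <- vapply(corpus, `[[`, character(1), "population")
  expect_identical(as.integer(table(pops)[c("HV", "NHP", "Patients")]),
                   c(3L, 2L, 5L))
  doses <- vapply(corpus, `[[`, numeric(1), "dose_per_kg")
  expect_setequal(doses[pops == "Patients"], c(0.3, 1, 3, 5, 10))
  expect_setequal(doses[pops == "HV"], c(0.5, 1, 3))
  # repeated-dose metadata for patients, single dose elsewhere
  expect_true(all(vapply(corpus[pops == "Patients"], `[[`,
                         integer(1), "n_doses") == 4L))
  expect_true(all(vapply(corpus[pops != "Patients"], `[[`,
                         integer(1), "n_doses") == 1L))
  expect_identical(corpus$nhp_xtend_4$drug, "xtend-bevacizumab")

  dir <- withr::local_tempdir()
  write_profiles(corpus, file.path(dir, "corpus.csv"))
  back <- read_profiles(file.path(dir, "corpus.csv"))
  expect_length(back, 10L)
  for (id in names(corpus)) {
    expect_identical(back[[id]]$times, corpus[[id]]$times, info = id)
    expect_identical(back[[id]]$concentrations,
                     corpus[[id]]$concentrations, info = id)
    expect_identical(back[[id]]$n_doses, corpus[[id]]$n_doses)
  }
})
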