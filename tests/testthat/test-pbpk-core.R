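test_that("two-pore exchange mode simulates and conserves mass", {
  m <- tiny_model(flux_mode = "two_pore")
  sim <- simulate_regimen(m, dosing_regimen(4),
                          output_times = seq(0, 28, 1))
  expect_lt(max(abs(sim$ledger$balance_error)), 1e-6)
  expect_gt(max(sim$plasma_conc), 0)
  # the exchange mode genuinely changes tissue kinetics
  s1 <- simulate_regimen(tiny_model(), dosing_regimen(4),
                         output_times = seq(0, 28, 1))
  is_cols <- grepl("interstitial$", colnames(sim$states))
  expect_gt(max(abs(sim$states[, is_cols] - s1$states[, is_cols])), 0.01)
})

test_that("compiled RHS matches the R oracle composed from the
           exported mechanism operations", {
  for (tgt in list(NULL, example_target(r0 = 1.2))) {
    for (mode in c("single_sigma", "two_pore")) {
      m <- tiny_model(target = tgt, fcrn_dynamic = TRUE,
                      flux_mode = mode)
      set.seed(99)
      y <- abs(rnorm(length(m$state_names), sd = 3))
      names(y) <- m$state_names
      for (inf in c(0, 250)) {
        ref <- reference_rhs(m, y, inf)
        got <- as.numeric(mabpbpk:::.cpp_model_rhs(y, m$params, inf))
        expect_equal(got, unname(ref), tolerance = 1e-10,
                     info = paste(mode, "target:", !is.null(tgt),
                                  "inf:", inf))
      }
    }
  }
})

test_that("state vector dimensions follow the layout contract", {
  m0 <- tiny_model()                       # no target
  n_org <- nrow(tiny_physiology()$organs)
  expect_length(m0$state_names, 1 + 5 * n_org + 2)
  # both tiny organs express -> target adds 2 * (2 + 1) states
  m1 <- tiny_model(target = example_target())
  expect_length(m1$state_names, 1 + 5 * n_org + 2 + 2 * (n_org + 1))
  # deterministic build
  expect_identical(tiny_model()[c("state_names", "params")],
                   tiny_model()[c("state_names", "params")])
  # target with all-zero expression weights is rejected
  phys <- tiny_physiology()
  phys$organs$expression_weight <- 0
  expect_error(build_model(phys, drug_properties(kd_fcrn = 450),
                           example_target()), "zero")
})

test_that("zero dose gives an identically zero profile", {
  m <- tiny_model()
  sim <- simulate_regimen(m, dosing_regimen(0), output_times = 0:10)
  expect_identical(max(abs(sim$plasma_conc)), 0)
  expect_identical(max(abs(sim$ledger$balance_error)), 0)
})

test_that("the target-free system is linear in dose", {
  m <- tiny_model()
  tt <- seq(0, 28, by = 1)
  s1 <- simulate_regimen(m, dosing_regimen(1), output_times = tt)
  s10 <- simulate_regimen(m, dosing_regimen(10), output_times = tt)
  expect_lt(max(abs(s10$plasma_conc / 10 - s1$plasma_conc) /
                  pmax(s1$plasma_conc, 1e-12)), 1e-6)
  expect_lt(abs(auc_trapezoid(tt, s10$plasma_conc) /
                  (10 * auc_trapezoid(tt, s1$plasma_conc)) - 1), 1e-6)
})

test_that("mass balance closes within 1e-6 for all regimen shapes", {
  regs <- list(dosing_regimen(4),                          # infusion
               dosing_regimen(4, infusion_duration = 0),   # bolus
               dosing_regimen(2, n_doses = 3, interval = 7))
  for (tgt in list(NULL, example_target(r0 = 2))) {
    m <- tiny_model(target = tgt)
    for (reg in regs) {
      sim <- simulate_regimen(m, reg, output_times = seq(0, 28, 0.5))
      expect_lt(max(abs(sim$ledger$balance_error)), 1e-6)
      expect_true(all(sim$states > -1e-9))
    }
  }
})

test_that("plasma concentration unit conversion is exact", {
  # 1 nmol/L <-> 0.15 ug/mL at MW 150 kDa
  expect_equal(mabpbpk:::nmolL_to_ugml(1, 150000), 0.15)
  expect_equal(mabpbpk:::ugml_to_nmolL(0.15, 150000), 1)
  expect_equal(mabpbpk:::mg_to_nmol(1, 150000), 20 / 3)
})

test_that("solver accuracy: default tolerances agree with a tightened
           run", {
  m <- tiny_model(target = example_target(r0 = 1))
  tt <- c(1, 7, 21)
  s1 <- simulate_regimen(m, dosing_regimen(1), output_times = tt)
  m2 <- tiny_model(target = example_target(r0 = 1),
                   solver = list(rtol = 1e-10, atol = 1e-12,
                                 h_init = 1e-5))
  s2 <- simulate_regimen(m2, dosing_regimen(1), output_times = tt)
  expect_equal(s1$plasma_conc, s2$plasma_conc, tolerance = 1e-7)
})

test_that("weaker FcRn binding strictly shortens the half-life and the
           response is blunted (non-equilibrium)", {
  tt <- seq(0, 70, by = 1)
  t_half <- vapply(c(45, 450, 4500), function(kd) {
    m <- build_model(tiny_physiology(), drug_properties(kd_fcrn = kd))
    terminal_half_life(
      simulate_regimen(m, dosing_regimen(4), output_times = tt)$profile)
  }, numeric(1))
  expect_true(all(diff(t_half) < 0))
  # a 10-fold affinity gain (kd 450 -> 45) moves the half-life by
  # less than 5-fold: the non-equilibrium blunting property
  expect_lt(t_half[1] / t_half[2], 5)
  expect_gt(t_half[1] / t_half[2], 1.5)
})

test_that("terminal_half_life matches closed forms and is scale
           invariant", {
  tt <- seq(10, 60, by = 2)
  p <- concentration_profile("x", "HV", 1, tt, 100 * exp(-0.1 * tt))
  expect_equal(terminal_half_life(p), log(2) / 0.1, tolerance = 1e-9)
  p2 <- p; p2$concentrations <- 17 * p$concentrations
  expect_equal(terminal_half_life(p2), terminal_half_life(p))
  # biexponential with known terminal rate 0.05/day
  cc <- 50 * exp(-0.8 * tt) + 20 * exp(-0.05 * tt)
  p3 <- concentration_profile("y", "HV", 1, tt, cc)
  expect_equal(terminal_half_life(p3), log(2) / 0.05, tolerance = 0.01)
  # non-monotone terminal phase errors
  cc[length(cc)] <- cc[length(cc)] * 3
  p4 <- concentration_profile("z", "HV", 1, tt, cc)
  expect_error(terminal_half_life(p4), "monoton")
  expect_error(terminal_half_life(
    concentration_profile("w", "HV", 1, c(1, 2), c(2, 1))), "3 p")
})

test_that("dynamic-FcRn mode conserves total FcRn through a
           simulation", {
  m <- tiny_model(fcrn_dynamic = TRUE)
  sim <- simulate_regimen(m, dosing_regimen(10),
                          output_times = seq(0, 21, 0.5))
  tot <- sim$states[, grepl("\\.fcrn$", m$state_names)] +
    sim$states[, grepl("\\.fcrn_complex$", m$state_names)]
  rng <- apply(tot, 2, function(x) diff(range(x)) / max(x))
  expect_lt(max(rng), 1e-7)
})
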