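test_that("one-compartment oracle: S(clearance -> AUC) is the closed
           form", {
  oc <- one_compartment_model(cl = 2, v = 5)
  reg <- dosing_regimen(100, n_doses = 10L, interval = 7)
  r <- local_sensitivity(oc, reg, "cl", perturbation = 0.10)
  s_auc <- r$s_value[r$metric == "auc_tau_ss"]
  expect_equal(s_auc, (1 / 1.1 - 1) / 0.1, tolerance = 1e-6)
  expect_equal(s_auc, -0.909091, tolerance = 1e-6)
  # closed-form metrics
  m <- steady_state_metrics(oc, reg)
  expect_equal(m$auc_tau_ss, 100 / 2)
  expect_equal(m$cmax_ss, (100 / 5) / (1 - exp(-2 / 5 * 7)))
  expect_error(local_sensitivity(oc, reg, "nope"), "unknown")
})

test_that("delta-robustness and central differences on the oracle", {
  oc <- one_compartment_model(cl = 1.3, v = 4)
  reg <- dosing_regimen(10, n_doses = 5L, interval = 10)
  s05 <- local_sensitivity(oc, reg, "v", perturbation = 0.05)
  s10 <- local_sensitivity(oc, reg, "v", perturbation = 0.10)
  expect_lt(max(abs(s05$s_value - s10$s_value) /
                  pmax(abs(s10$s_value), 1e-9)), 0.15)
  ctr <- local_sensitivity(oc, reg, "cl", method = "central")
  expect_equal(ctr$s_value[ctr$metric == "auc_tau_ss"],
               (1 / 1.1 - 1 / 0.9) / 0.2, tolerance = 1e-6)
})

test_that("panel deduplicates parameters and returns the tidy grid", {
  oc <- one_compartment_model(cl = 1, v = 3)
  res <- sensitivity_panel(oc, doses = c(1, 5),
                           parameters = c("cl", "cl", "v"),
                           n_doses = 4L, interval = 7)
  expect_s3_class(res, "data.frame")
  expect_identical(nrow(res), 2L * 2L * 2L)  # dose x param x metric
  expect_setequal(unique(res$parameter), c("cl", "v"))
})

test_that("steady-state AUC equals the single-dose AUC when the
           interval dwarfs the half-life", {
  sc <- build_scenario("NHP-bev")
  reg <- dosing_regimen(4, n_doses = 10L, interval = 120)
  m <- steady_state_metrics(sc, reg, grid_per_interval = 241L,
                            solver = fast_solver)
  single <- simulate_regimen(
    scenario_model(sc, solver = fast_solver), dosing_regimen(4),
    output_times = seq(0, 120, length.out = 241))
  auc1 <- auc_trapezoid(single$times, single$plasma_conc)
  expect_lt(abs(m$auc_tau_ss / auc1 - 1), 0.005)
  expect_lte(m$n_intervals, 3L)
})

test_that("a low-dose target depresses steady-state exposure below the
           linear model", {
  sc <- build_scenario("Patients-refined")
  lin <- set_scenario_params(sc, list(r0_reference = 1e-9))
  reg <- dosing_regimen(0.3, n_doses = 6L, interval = 14)
  m_t <- steady_state_metrics(sc, reg, n_intervals = 6L,
                              solver = fast_solver)
  m_l <- steady_state_metrics(lin, reg, n_intervals = 6L,
                              solver = fast_solver)
  expect_lt(m_t$auc_tau_ss, 0.9 * m_l$auc_tau_ss)
})

test_that("failure to reach steady state within the cap is an error
           with trend diagnostics", {
  sc <- build_scenario("HV-refined")   # half-life ~3 weeks, tau 1 day
  reg <- dosing_regimen(1, n_doses = 50L, interval = 1)
  expect_error(
    steady_state_metrics(sc, reg, max_doses = 3L,
                         grid_per_interval = 21L,
                         solver = fast_solver),
    "did not converge within 3")
})

test_that("sign contracts and zero-S for inactive parameters", {
  # kint with the target switched off: perturbation is a no-op -> S = 0
  sc0 <- set_scenario_params(build_scenario("HV-refined"),
                             list(r0_reference = 1e-12, kint = 0))
  reg <- dosing_regimen(1)
  r <- local_sensitivity(sc0, reg, "kint", solver = fast_solver)
  expect_identical(r$s_value, c(0, 0))
  # weaker FcRn binding reduces exposure
  r_kd <- local_sensitivity(build_scenario("HV-refined"), reg,
                            "kd_fcrn", solver = fast_solver,
                            single_dose_horizon = 60)
  expect_lt(r_kd$s_value[r_kd$metric == "auc_tau_ss"], 0)
})
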