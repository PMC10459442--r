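prof <- function(tt, cc) concentration_profile("p", "HV", 1, tt, cc)

test_that("trapezoidal AUC matches hand-computed cases", {
  expect_equal(auc_trapezoid(prof(c(0, 5), c(10, 10))), 50)
  expect_equal(auc_trapezoid(prof(c(0, 2), c(10, 0))), 10)
  tt <- c(0, 1, 3, 7); cc <- c(0, 12, 6, 2)
  by_hand <- 0.5 * (0 + 12) * 1 + 0.5 * (12 + 6) * 2 + 0.5 * (6 + 2) * 4
  expect_equal(auc_trapezoid(prof(tt, cc)), by_hand)
  expect_error(auc_trapezoid(c(0, 0, 1), c(1, 2, 3)), "duplicate")
  expect_error(auc_trapezoid(c(1), c(2)), "2 points")
})

test_that("trapezoid agrees with a fine-grid quadrature oracle on a
           smooth profile", {
  tt <- seq(0, 30, length.out = 600)
  cc <- 80 * exp(-0.15 * tt) + 20 * exp(-0.02 * tt)
  exact <- 80 / 0.15 * (1 - exp(-0.15 * 30)) +
    20 / 0.02 * (1 - exp(-0.02 * 30))
  expect_equal(auc_trapezoid(tt, cc), exact, tolerance = 1e-3)
  # log-down variant is exact for a mono-exponential segment
  tt2 <- c(0, 10); cc2 <- c(100, 100 * exp(-1))
  expect_equal(auc_trapezoid(tt2, cc2, method = "log_down"),
               100 * (1 - exp(-1)) / 0.1, tolerance = 1e-12)
})

test_that("AFE and AAFE reproduce the defining formulas", {
  expect_equal(afe(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(aafe(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(afe(c(2, 0.5), c(1, 1)), 1)       # logs cancel
  expect_equal(aafe(c(2, 0.5), c(1, 1)), 2)      # |logs| add
  expect_equal(afe(c(2, 2, 2), c(1, 1, 1)), 2)
  expect_equal(aafe(10, 1), 10)
  expect_error(afe(c(1, -1), c(1, 1)), "positive")
  expect_error(aafe(1:3, 1:2), "equal length")
})

test_that("AFE/AAFE invariants hold for random inputs", {
  set.seed(77)
  for (i in 1:30) {
    n <- sample(2:40, 1)
    pred <- rlnorm(n); obs <- rlnorm(n)
    a <- afe(pred, obs); aa <- aafe(pred, obs)
    expect_gte(aa, 1)
    expect_gte(a, 1 / aa - 1e-12)
    expect_lte(a, aa + 1e-12)
  }
})

test_that("accuracy classification boundaries are as published", {
  expect_identical(as.character(classify(1.0)), "very_accurate")
  expect_identical(as.character(classify(c(0.80, 1.25))),
                   rep("very_accurate", 2))
  expect_identical(as.character(classify(c(0.79, 1.26, 0.50, 2.00))),
                   rep("acceptable", 4))
  expect_identical(as.character(classify(1.94)), "acceptable")
  expect_identical(as.character(classify(c(0.49, 2.01))),
                   rep("inaccurate", 2))
  expect_error(classify(0), "positive")
})

test_that("prediction evaluation composes the metrics", {
  tt <- c(1, 2, 7, 14, 28)
  obs <- prof(tt, c(30, 25, 15, 8, 3))
  same <- evaluate_prediction(obs, obs)
  expect_equal(same$pe_auc, 1)
  expect_equal(same$pe_cmax, 1)
  expect_equal(same$afe, 1)
  expect_equal(same$aafe, 1)
  expect_identical(as.character(same$class_auc), "very_accurate")

  twice <- prof(tt, 2 * obs$concentrations)
  r <- evaluate_prediction(twice, obs)
  expect_equal(unlist(r[c("pe_auc", "pe_cmax", "afe", "aafe")]),
               c(pe_auc = 2, pe_cmax = 2, afe = 2, aafe = 2))
  expect_identical(as.character(r$class_auc), "acceptable")

  bias <- prof(tt, 1.3 * obs$concentrations)
  expect_equal(evaluate_prediction(bias, obs)$afe, 1.3,
               tolerance = 1e-9)
  # time grids must match
  shifted <- prof(tt + 0.5, obs$concentrations)
  expect_error(evaluate_prediction(shifted, obs), "observed times")
})
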