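test_that("noiseless exponential data are recovered to machine precision", {
  t <- c(0, 10, 20)
  fit <- fit_monoexponential(t, 10 * exp(-0.1 * t))
  expect_equal(fit$A0, 10, tolerance = 1e-10)
  expect_equal(fit$lambda, 0.1, tolerance = 1e-10)
  expect_equal(fit$tia, 100, tolerance = 1e-10)
  expect_equal(fit$half_life_h, log(2) / 0.1, tolerance = 1e-10)
  expect_equal(unname(coef(fit)), c(10, 0.1), tolerance = 1e-10)
  expect_equal(predict(fit, 5), 10 * exp(-0.5), tolerance = 1e-10)
})

test_that("bone-metastasis worked example yields the two TIAs", {
  tac <- tac_fixture()
  f1 <- fit_monoexponential(data = tac[tac$method == "proposed", ])
  f2 <- fit_monoexponential(data = tac[tac$method == "recovery", ])
  expect_equal(f1$tia, 1143, tolerance = 0.001)
  expect_equal(f2$tia, 1574, tolerance = 0.001)
  # effectively identical clearance between quantification methods
  expect_equal(f1$half_life_h, f2$half_life_h, tolerance = 0.05)
  # delta-method u(TIA) is of the order of the reported +/-13 and +/-26
  expect_gt(f1$u_tia, 13 / 3); expect_lt(f1$u_tia, 13 * 3)
  expect_gt(f2$u_tia, 26 / 3); expect_lt(f2$u_tia, 26 * 3)
})

test_that("TIA uncertainty follows the delta method on (lnA0, lambda)", {
  fit <- fit_monoexponential(c(0, 10, 20, 30), 10 * exp(-0.1 * c(0, 10, 20, 30)))
  fit$covariance <- matrix(0, 2, 2)
  expect_equal(tia_uncertainty(fit), 0)
  # uncorrelated u(lnA0) = u(lambda)/lambda = 1%, TIA = 1000
  fit$tia <- 1000; fit$lambda <- 0.1
  fit$covariance <- diag(c(0.01^2, (0.001)^2))
  expect_equal(tia_uncertainty(fit), 1000 * sqrt(2) * 0.01, tolerance = 1e-12)
  fit$covariance <- matrix(NA_real_, 2, 2)
  expect_error(tia_uncertainty(fit), "covariance")
})

test_that("TIA scales with activity and is unit-consistent in time", {
  set.seed(8)
  t <- c(24, 72, 140)
  A <- 12 * exp(-0.012 * t) * exp(rnorm(3, 0, 0.03))
  f <- fit_monoexponential(t, A)
  fk <- fit_monoexponential(t, 3.7 * A)
  expect_equal(fk$tia, 3.7 * f$tia, tolerance = 1e-10)
  # hours -> days: lambda scales by 24, TIA in MBq.day = TIA_h / 24
  fd <- fit_monoexponential(t / 24, A)
  expect_equal(fd$lambda, f$lambda * 24, tolerance = 1e-10)
  expect_equal(fd$tia, f$tia / 24, tolerance = 1e-10)
})

test_that("replicates with 2% lognormal noise recover the TIA median-unbiasedly", {
  truth <- fit_monoexponential(c(43.0, 115.1, 163.7), c(7.88, 3.58, 2.02))
  reps <- simulate(truth, nsim = 200, seed = 17, cv = 0.02)
  tias <- apply(reps, 2, function(a)
    fit_monoexponential(truth$time, a)$tia)
  expect_lt(abs(median(tias) / truth$tia - 1), 0.01)
})

test_that("weighted fitting is available and respects the weights", {
  tac <- tac_fixture()
  p <- tac[tac$method == "proposed", ]
  fw <- fit_monoexponential(data = p, weighting = "relative")
  fu <- fit_monoexponential(data = p)
  expect_false(identical(fw$tia, fu$tia))
  expect_error(fit_monoexponential(p$time_h, p$activity_MBq,
                                   weighting = "relative"),
               "u_activity")
})

test_that("degenerate time-activity inputs are rejected", {
  expect_error(fit_monoexponential(c(1, 1), c(2, 3)), "distinct")
  expect_error(fit_monoexponential(c(1, 2), c(2, -3)), "positive")
  expect_error(fit_monoexponential(1, 2), "two")
  expect_error(fit_monoexponential(c(1, 2), c(2, 3)), "decay")
})

test_that("absorbed dose is TIA x S with quadrature uncertainty", {
  fit <- fit_monoexponential(c(0, 10, 20), 10 * exp(-0.1 * c(0, 10, 20)))
  d <- absorbed_dose(fit, 0.05)
  expect_equal(d$dose, 5, tolerance = 1e-9)
  expect_equal(d$u_dose / d$dose, fit$u_tia / fit$tia, tolerance = 1e-9)
  d2 <- absorbed_dose(fit, 0.05, u_dose_factor = 0.005)
  expect_equal((d2$u_dose / d2$dose)^2,
               (fit$u_tia / fit$tia)^2 + 0.1^2, tolerance = 1e-9)
  expect_error(absorbed_dose(fit, 0), "> 0")
})

test_that("electron-local-deposition sphere factor has the right physics", {
  expect_equal(sphere_dose_factor(2.6), 0.0426, tolerance = 2e-3)
  expect_equal(sphere_dose_factor(5.2), sphere_dose_factor(2.6) / 2,
               tolerance = 1e-12)
  expect_equal(sphere_dose_factor(1, electron_energy_mev = 0), 0)
  expect_gt(sphere_dose_factor(2.6, photon_absorbed_fraction = 0.05),
            sphere_dose_factor(2.6))
  expect_error(sphere_dose_factor(0), "> 0")
})

test_that("tabulated dose factors interpolate log-log", {
  tab <- data.frame(mass_g = c(1, 10, 100),
                    factor_Gy_per_MBqh = 0.1107 / c(1, 10, 100))
  # a 1/m law is linear in log-log: interpolation is exact anywhere inside
  expect_equal(dose_factor_from_table(tab, 3.7), 0.1107 / 3.7, tolerance = 1e-9)
  expect_error(dose_factor_from_table(tab, 1000), "range")
})
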