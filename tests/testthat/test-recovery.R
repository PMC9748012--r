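test_that("per-insert recovery factor is C/(Q A)", {
  expect_equal(recovery_factor(28.9 * 0.3, 0.3, cal_exact), 1)
  expect_equal(recovery_factor(4.335, 0.3, cal_exact), 0.5, tolerance = 1e-12)
  # linear in counts
  expect_equal(recovery_factor(2.1675, 0.3, cal_exact), 0.25, tolerance = 1e-12)
  expect_error(recovery_factor(1, 0, cal_exact), "> 0")
})

test_that("noiseless logistic data recover the generating parameters", {
  v <- c(0.5, 1, 2, 5, 10, 50, 100)
  obs <- data.frame(volume = v, recovery = 1 - 1 / (1 + (v / 5)^1.5))
  fit <- fit_recovery_curve(obs)
  expect_equal(fit$b1, 5, tolerance = 1e-6)
  expect_equal(fit$b2, 1.5, tolerance = 1e-6)
  # derived route through count rates and a calibration
  obs2 <- simulate_recovery_observations(b1 = 5, b2 = 1.5, noise_cv = 0)
  fit2 <- fit_recovery_curve(obs2[c("volume", "count_rate", "activity")], cal_paper)
  expect_equal(fit2$b1, 5, tolerance = 1e-6)
  expect_equal(fit2$b2, 1.5, tolerance = 1e-6)
})

test_that("logistic curve properties: half recovery at b1, monotone, bounded", {
  v <- c(0.5, 1, 2, 5, 10, 50, 100)
  for (b2 in c(0.5, 1, 1.7, 3)) {
    obs <- data.frame(volume = v, recovery = 1 - 1 / (1 + (v / 4)^b2))
    fit <- fit_recovery_curve(obs)
    expect_equal(recovery_at(fit, fit$b1)$recovery, 0.5, tolerance = 1e-9)
  }
  fit <- fit_recovery_curve(data.frame(volume = v,
                                       recovery = 1 - 1 / (1 + (v / 5)^1.5)))
  grid <- recovery_at(fit, exp(seq(log(1e-3), log(1e5), length.out = 200)))
  expect_true(all(grid$recovery > 0 & grid$recovery < 1))
  expect_true(all(diff(grid$recovery) > 0))
  expect_lt(abs(recovery_at(fit, 1000 * fit$b1)$recovery - 1), 1e-4)
})

test_that("recovery uncertainty combines parameter and volume terms", {
  v <- c(0.5, 1, 2, 5, 10, 50, 100)
  fit <- fit_recovery_curve(data.frame(volume = v,
                                       recovery = 1 - 1 / (1 + (v / 5)^1.5)))
  fit$covariance[] <- 0    # isolate the volume term
  r <- recovery_at(fit, volume = 5, u_volume = 0.5)
  expect_equal(r$u_recovery, 1.5 / (4 * 5) * 0.5, tolerance = 1e-6)  # |dR/dv| u(v)
  expect_equal(recovery_at(fit, 5, 0)$u_recovery, 0)
  # relative uncertainty blows up towards v -> 0 for fixed absolute u(v)
  rel <- function(vol) {
    x <- recovery_at(fit, vol, u_volume = 0.2)
    x$u_recovery / x$recovery
  }
  expect_true(rel(0.2) > rel(1) && rel(1) > rel(5) && rel(5) > rel(50))
  expect_error(recovery_at(fit, -1), "> 0")
})

test_that("RC quantification divides by the recovery at the delineated volume", {
  v <- c(0.5, 1, 2, 5, 10, 50, 100)
  fit <- fit_recovery_curve(data.frame(volume = v,
                                       recovery = 1 - 1 / (1 + (v / 5)^1.5)))
  fit$covariance[] <- 0
  est <- quantify_rc(14.45, 0, cal_exact, fit, volume = 5)   # R = 0.5 here
  expect_equal(est$activity, 1, tolerance = 1e-6)
  expect_equal(est$method, "recovery_coefficient")
  # small-volume case: u(R)/R dominates u(A)/A
  r_small <- recovery_at(fit, 0.33, u_volume = 0.17)
  est2 <- quantify_rc(1, 0, cal_exact, fit, volume = 0.33, u_volume = 0.17)
  expect_gte(est2$u_activity / est2$activity,
             r_small$u_recovery / r_small$recovery * (1 - 1e-12))
})

test_that("fit errors are informative for degenerate inputs", {
  expect_error(fit_recovery_curve(data.frame(volume = c(1, 1, 1),
                                             recovery = c(0.1, 0.2, 0.3))),
               "distinct")
  expect_error(fit_recovery_curve(data.frame(volume = c(1, 2),
                                             recovery = c(0.1, 0.2))),
               "3 observations")
  expect_error(fit_recovery_curve(data.frame(volume = 1:5), cal_paper), "columns")
})
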