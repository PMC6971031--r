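test_that("noise-free model data are recovered exactly", {
  tau_d <- seq(0, 10e-3, by = 1e-5)
  ## constant + single exponential, order 3
  y3 <- 0.4 + 1.3 * exp(-1800 * tau_d)
  f3 <- fit_decay(tau_d, y3, order = 3)
  expect_equal(unname(coef(f3)), c(0.4, 1.3, 1800), tolerance = 1e-6)
  expect_equal(f3$adj_r2, 1, tolerance = 1e-9)
  ## bi-exponential with rate ratio 10, order 5
  y5 <- 0.2 + 0.6 * exp(-300 * tau_d) + 1.1 * exp(-3000 * tau_d)
  f5 <- fit_decay(tau_d, y5, order = 5)
  expect_equal(unname(coef(f5)[c("I_c", "I_slow", "xi_slow",
                                 "I_fast", "xi_fast")]),
               c(0.2, 0.6, 300, 1.1, 3000), tolerance = 1e-3)
  ## labeling convention enforced
  expect_gte(unname(coef(f5)["xi_fast"]), unname(coef(f5)["xi_slow"]))
  ## order-3 fit on bi-exponential data scores strictly lower
  f3on5 <- fit_decay(tau_d, y5, order = 3)
  expect_lt(f3on5$adj_r2, f5$adj_r2)
  ## orders 1 and 2
  f1 <- fit_decay(tau_d, 2.5 * exp(-1200 * tau_d), order = 1)
  expect_equal(unname(coef(f1)["xi"]), 1200, tolerance = 1e-6)
  f2 <- fit_decay(tau_d, 0.8 * exp(-900 * tau_d), order = 2)
  expect_equal(unname(coef(f2)), c(0.8, 900), tolerance = 1e-6)
  ## near-equal rates collapse to order 3 with a flag
  ydeg <- 0.1 + 0.5 * exp(-1000 * tau_d) + 0.5 * exp(-1010 * tau_d)
  fdeg <- fit_decay(tau_d, ydeg, order = 5)
  expect_true(fdeg$degenerate)
  expect_equal(fdeg$order, 3)
  ## data shortage errors
  expect_error(fit_decay(tau_d[1:10], y5[1:10], order = 5), "3 data points")
})

test_that("decay fits are honest statistical objects", {
  set.seed(2)
  tau_d <- seq(0, 10e-3, by = 1e-5)
  y <- 0.4 + 1.3 * exp(-1800 * tau_d) + stats::rnorm(length(tau_d), 0, 0.01)
  f <- fit_decay(tau_d, y, order = 3)
  ## CIs cover the truth
  expect_true(all(f$ci[, "lower"] <= c(0.4, 1.3, 1800) * 1.02))
  expect_true(all(f$ci[, "upper"] >= c(0.4, 1.3, 1800) * 0.98))
  ## methods are consistent
  expect_equal(fitted(f) + residuals(f), f$y)
  expect_equal(predict(f, f$tau_d), fitted(f))
  s <- summary(f)
  expect_s3_class(s, "summary.decay_fit")
  expect_equal(s$table$estimate, unname(coef(f)))
})

test_that("adjusted R2 follows its formula", {
  y <- c(1, 2, 3, 4, 5, 6)
  fit_perfect <- y
  expect_equal(adjusted_r2(y, fit_perfect, 2), 1)
  ## worked case against a hand calculation
  fitv <- c(1.1, 1.9, 3.2, 3.8, 5.1, 5.9)
  r2 <- 1 - sum((y - fitv)^2) / sum((y - mean(y))^2)
  expect_equal(adjusted_r2(y, fitv, 2), 1 - (1 - r2) * 5 / 3)
  ## a useless extra parameter lowers the adjusted value
  expect_lt(adjusted_r2(y, fitv, 3), adjusted_r2(y, fitv, 2))
  expect_error(adjusted_r2(y[1:3], fitv[1:3], 2), "n > p")
})

test_that("early-lag fitting isolates the fast component", {
  tau_d <- seq(0, 10e-3, by = 1e-5)
  ## mono-exponential: early-lag and full-window fits agree to 1%
  ym <- 0.3 + 1 * exp(-2500 * tau_d)
  ff <- fit_decay(tau_d, ym, order = 3)
  fe <- early_lag_fit(tau_d, ym, order = 3)
  expect_equal(unname(coef(fe)["xi"]), unname(coef(ff)["xi"]),
               tolerance = 0.01)
  ## bi-exponential: early-lag rate is closer to the fast rate
  yb <- 0.2 + 0.6 * exp(-300 * tau_d) + 1.1 * exp(-3000 * tau_d)
  ff3 <- fit_decay(tau_d, yb, order = 3)
  fe3 <- early_lag_fit(tau_d, yb, order = 3)
  expect_lt(abs(coef(fe3)["xi"] - 3000), abs(coef(ff3)["xi"] - 3000))
  ## over-long window is rejected
  expect_error(early_lag_fit(tau_d, yb, lag_window = 1), "extent")
})

test_that("decay-rate regression recovers BFI from an exact line", {
  op <- op_intralipid()
  tof <- seq(100, 800, by = 50)
  tau_d <- seq(0, 10e-3, by = 1e-5)
  xi <- decay_rate_line(tof, 1.18e-8, op, tau_s0 = 0)
  g1 <- analytic_tof_g1(tof, tau_d, I_static = 0, I_slow = 0, xi_slow = 0,
                        I_fast = 1, xi_fast = xi)
  fits <- fit_decay_tof(g1, order = 2, window = 10e-3)
  dl <- decay_rate_regression(fits, op)
  expect_equal(dl$bfi, 1.18e-8, tolerance = 1e-6)
  expect_lt(abs(dl$tau_s0), 1e-3)
  ## all-equal rates: zero slope, zero BFI
  g1c <- analytic_tof_g1(tof, tau_d, 0, 0, 0, 1, 2000)
  dlc <- decay_rate_regression(fit_decay_tof(g1c, order = 2), op)
  expect_equal(dlc$bfi, 0)
  expect_error(decay_rate_regression(fits[1:2], op), "3")
})

test_that("TPSF optics fitting round-trips within the validated bound", {
  op <- op_intralipid()
  grid <- seq(2, 3000, by = 2)
  irf <- irf_gaussian(21.9, tof_step_ps = 2)
  tpb <- convolve_irf(tpsf_semi_infinite(grid, 0.76, op), irf,
                      tof_ps = grid)
  fit <- fit_tpsf_optics(grid, tpb, irf, rho = 0.76, fit_range = c(100, NA))
  expect_equal(fit$optics$mu_sp, 10, tolerance = 0.005)
  expect_equal(fit$optics$mu_a, 0.045, tolerance = 0.02)
  ## amplitude freedom: scaling the data leaves the optics unchanged
  fit7 <- fit_tpsf_optics(grid, 7 * tpb, irf, rho = 0.76,
                          fit_range = c(100, NA))
  expect_equal(coef(fit7)[c("mu_a", "mu_sp")],
               coef(fit)[c("mu_a", "mu_sp")], tolerance = 1e-6)
  ## null separation and 7.6 mm recoveries agree within 10%
  tpb0 <- convolve_irf(tpsf_semi_infinite(grid, 0, op), irf, tof_ps = grid)
  fit0 <- fit_tpsf_optics(grid, tpb0, irf, rho = 0, fit_range = c(100, NA))
  expect_equal(fit0$optics$mu_sp, fit$optics$mu_sp, tolerance = 0.1)
  ## an injected TOF offset is absorbed by the free offset parameter
  shifted <- stats::approx(grid + 30, tpb, xout = grid, rule = 2)$y
  fsh <- fit_tpsf_optics(grid, pmax(shifted, 1e-300), irf, rho = 0.76,
                         fit_range = c(150, 2500))
  expect_equal(fsh$t0_ps, 30, tolerance = 0.1)
  expect_equal(fsh$optics$mu_sp, 10, tolerance = 0.005)
})
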