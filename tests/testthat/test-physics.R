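test_that("msd laws match their closed forms and limits", {
  ## direct substitution
  expect_equal(msd(msd_model("brownian", D_B = 1), 1), 6)
  expect_equal(msd(msd_model("random_flow", v = 2), 3), 36)
  ## msd(0) = 0 for every kind
  models <- list(
    msd_model("brownian", D_B = 1e-8),
    msd_model("random_flow", v = 0.1),
    msd_model("hydrodynamic", D_B = 1e-8, tau_C = 1e-4),
    msd_model("hybrid", D_B = 1e-8, v = 0.1))
  for (m in models) expect_identical(msd(m, 0), 0)
  ## nonnegative and nondecreasing on a grid
  tau <- 10^seq(-6, -1, length.out = 40)
  for (m in models) {
    v <- msd(m, tau)
    expect_true(all(v >= 0))
    expect_true(all(diff(v) >= 0))
  }
  ## hydrodynamic ballistic limit: ~ 3 D_B tau^2 / tau_C for tau << tau_C
  m <- msd_model("hydrodynamic", D_B = 2e-8, tau_C = 1e-3)
  tau <- 1e-5  # tau_C / 100
  expect_equal(msd(m, tau), 3 * 2e-8 * tau^2 / 1e-3, tolerance = 1e-2)
  ## hydrodynamic -> brownian as tau_C -> 0
  m <- msd_model("hydrodynamic", D_B = 2e-8, tau_C = 1e-12)
  expect_equal(msd(m, 1e-3), 6 * 2e-8 * 1e-3, tolerance = 1e-6)
  ## hybrid limits
  expect_equal(msd(msd_model("hybrid", D_B = 3e-8, v = 0), 1e-3),
               msd(msd_model("brownian", D_B = 3e-8), 1e-3),
               tolerance = 1e-12)
  expect_equal(msd(msd_model("hybrid", D_B = 0, v = 0.05), 1e-3),
               msd(msd_model("random_flow", v = 0.05), 1e-3),
               tolerance = 1e-12)
  ## domain errors
  expect_error(msd(models[[1]], -1), "tau_d")
  expect_error(msd_model("hydrodynamic", D_B = 1e-8), "tau_C")
})

test_that("DLS autocorrelation obeys its closed form", {
  m <- msd_model("brownian", D_B = 1e-8)
  tau <- 10^seq(-5, -2, length.out = 20)
  ## all-static limit
  expect_equal(g1_dls(1, 1e5, m, tau), rep(1, 20))
  ## eta_c = 0 reduces to exp(-q^2 D_B tau)
  expect_equal(g1_dls(0, 1e5, m, tau), exp(-1e10 * 1e-8 * tau))
  ## hand-evaluated point: q^2 D_B tau = ln 2 -> 0.5 + 0.25
  q <- 1e5; tau1 <- log(2) / (q^2 * 1e-8)
  expect_equal(g1_dls(0.5, q, m, tau1), 0.75)
  ## bounds and lag-0 value
  v <- g1_dls(0.3, q, m, tau)
  expect_true(all(v > 0 & v <= 1))
  expect_equal(g1_dls(0.3, q, m, 0), 1)
})

test_that("DWS autocorrelation decays per the decay-rate line", {
  op <- op_intralipid()
  m <- msd_model("brownian", D_B = 1.18e-8, alpha = 1)
  tau <- seq(0, 2e-4, by = 1e-6)
  ## unity at zero lag for any TOF
  expect_equal(g1_dws(c(0, 100, 1000), 0, op, m), rep(1, 3))
  ## independently evaluated decay rate at 200 ps
  ## (2 k^2 alpha D_B mu_s' c tau_s / n_r with c = 2.998e10 cm/s)
  k <- 2 * pi * 1.33 / 855e-7
  xi_oracle <- 2 * k^2 * 1.18e-8 * 10 * 2.998e10 * 200e-12 / 1.33
  expect_equal(xi_oracle, 10163.6, tolerance = 1e-4)
  ## -d ln g1 / d tau_d equals the line at tau_s0 = 0
  g <- g1_dws(200, tau, op, m)
  slope_num <- -diff(log(g))[1] / diff(tau)[1]
  expect_equal(slope_num, decay_rate_line(200, 1.18e-8, op), tolerance = 1e-9)
  expect_equal(slope_num, xi_oracle, tolerance = 1e-3)
  ## monotone decreasing in both arguments, in (0, 1]
  g2 <- g1_dws(400, tau, op, m)
  expect_true(all(diff(g) < 0))
  expect_true(all(g2[-1] < g[-1]))
  expect_true(all(g > 0 & g <= 1))
})

test_that("decay-rate line and BFI-from-slope are exact inverses", {
  op <- op_intralipid()
  ## tau_s = tau_s0 gives zero rate
  expect_equal(decay_rate_line(30, 1e-8, op, tau_s0 = 30), 0)
  ## round trip across random parameter draws
  set.seed(42)
  for (i in 1:25) {
    bfi <- 10^stats::runif(1, -10, -6)
    opx <- optical_properties(mu_a = stats::runif(1, 0, 0.5),
                              mu_sp = stats::runif(1, 3, 25),
                              n_r = stats::runif(1, 1.3, 1.45),
                              lambda0 = stats::runif(1, 700, 900))
    xi <- decay_rate_line(c(100, 400), bfi, opx)
    slope <- diff(xi) / 300  # per ps
    expect_equal(bfi_from_slope(slope, opx), bfi, tolerance = 1e-9)
  }
  ## linearity: doubled slope doubles BFI
  expect_equal(bfi_from_slope(2 * 1.5, op), 2 * bfi_from_slope(1.5, op))
  ## decay_line object round trip
  dl <- decay_line(1.2, 15, op)
  expect_equal(unname(coef(dl)["bfi"]), bfi_from_slope(1.2, op))
  expect_equal(predict(dl, 15), 0)
})

test_that("semi-infinite TPSF behaves like time-domain diffusion", {
  op <- op_intralipid()
  ts <- seq(10, 4000, by = 5)
  v <- tpsf_semi_infinite(ts, 0.76, op)
  expect_true(all(v > 0))
  ## absorption factorizes: ratio mu_a = a vs 0 is exp(-a c t / n)
  op0 <- optical_properties(mu_a = 0, mu_sp = 10, n_r = 1.33, lambda0 = 855)
  v0 <- tpsf_semi_infinite(ts, 0.76, op0)
  expect_equal(v / v0, exp(-0.045 * C_VACUUM_CM_S / 1.33 * ts / 1e12),
               tolerance = 1e-12)
  ## late-TOF log slope approaches -mu_a c / n_r
  tlate <- c(2e5, 2.001e5)  # ps
  sl <- diff(log(tpsf_semi_infinite(tlate, 0.76, op))) /
    (diff(tlate) / 1e12)
  expect_equal(sl, -0.045 * C_VACUUM_CM_S / 1.33, tolerance = 2e-2)
  ## peak TOF agrees with a brute-force grid maximization
  fine <- seq(1, 1000, by = 0.05)
  pk_grid <- fine[which.max(tpsf_semi_infinite(fine, 0.76, op))]
  pk_opt <- stats::optimize(function(t) -tpsf_semi_infinite(t, 0.76, op),
                            c(1, 1000))$minimum
  expect_equal(pk_opt, pk_grid, tolerance = 1e-3)
  ## vanishes at both ends
  expect_lt(tpsf_semi_infinite(0.1, 0.76, op), 1e-300)
  expect_lt(tpsf_semi_infinite(1e7, 0.76, op), 1e-300)
  expect_error(tpsf_semi_infinite(-5, 0.76, op), "tau_s")
})

test_that("IRF widths follow Fourier scaling of the apodization window", {
  ## rectangular window: sinc^2 intensity, FWHM = 0.886 / dnu
  r <- irf_profile(64.7, "rectangular")
  expect_equal(irf_fwhm(r), 0.886 / 64.7e9 * 1e12, tolerance = 1e-3)
  ## Hann window: about 1.44 / dnu
  h <- irf_profile(64.7, "hann")
  expect_equal(irf_fwhm(h), 1.44 / 64.7e9 * 1e12, tolerance = 1e-2)
  ## halving the tuning range doubles the FWHM
  h2 <- irf_profile(64.7 / 2, "hann", tof_span_ps = 300)
  expect_equal(irf_fwhm(h2), 2 * irf_fwhm(h), tolerance = 1e-3)
  ## profiles are normalized and nonnegative
  expect_true(all(h$profile >= 0))
  expect_equal(sum(h$profile), 1, tolerance = 1e-12)
  expect_error(irf_profile(64.7, "flattop"), "arg")
  ## gaussian constructor hits the requested width
  expect_equal(irf_fwhm(irf_gaussian(21.9)), 21.9, tolerance = 1e-4)
})

test_that("IRF convolution preserves mass and commutes with shifts", {
  set.seed(7)
  x <- c(rep(0, 30), stats::rgamma(80, 3, 0.1), rep(0, 40))
  ## delta IRF is the identity
  delta <- irf_gaussian(1e-6, tof_step_ps = 1, tof_span_ps = 10)
  expect_equal(convolve_irf(x, delta), x, tolerance = 1e-9)
  ## unit-sum IRF preserves the total when support fits
  irf <- irf_gaussian(8, tof_step_ps = 1, tof_span_ps = 30)
  y <- convolve_irf(x, irf)
  expect_true(all(y >= -1e-12))
  expect_equal(sum(y), sum(x), tolerance = 1e-9)
  ## shifting the IRF by m bins shifts the output by m bins
  irf_sh <- irf
  irf_sh$tof_ps <- irf$tof_ps + 5
  y_sh <- convolve_irf(x, irf_sh)
  expect_equal(y_sh[6:length(y)], y[1:(length(y) - 5)], tolerance = 1e-9)
  ## grid mismatch errors
  expect_error(convolve_irf(x, irf, tof_ps = (seq_along(x) - 1) * 2),
               "spacing")
})

test_that("optical property invariants are enforced", {
  expect_error(optical_properties(-0.1, 10), "mu_a")
  expect_error(optical_properties(0.1, 0), "mu_sp")
  expect_error(optical_properties(0.1, 10, mu_s = 100, g = 0.5), "mu_sp")
  op <- optical_properties(0.1, 10, mu_s = 100, g = 0.9)
  expect_equal(op$mu_s * (1 - op$g), op$mu_sp)
  ## g derived from mu_s when omitted
  op2 <- optical_properties(0.1, 10, mu_s = 50)
  expect_equal(op2$g, 0.8)
})
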