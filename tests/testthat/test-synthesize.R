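test_that("motion synthesis follows the bulk Doppler phase formula", {
  cfg <- short_config(duration = 0.05, alpha_sd = 10 * pi / 180)
  ## zero velocity leaves the phase flat
  m0 <- synthesize_motion(cfg, velocity_rw_std = 0, seed = 1)
  expect_true(all(m0$theta == 0))
  expect_true(all(m0$df == 0))
  ## phase increments: (4 pi / lambda) (dz (1 + cos a) + dx sin a) / 2
  m <- synthesize_motion(cfg, velocity_rw_std = 0.5, lateral_rw_std = 0.3,
                         seed = 2)
  lam_um <- cfg$lambda0 * 1e-3
  dtheta_expected <- (4 * pi / lam_um) *
    (m$dz * (1 + cos(cfg$alpha_sd)) + m$dx * sin(cfg$alpha_sd)) / 2
  expect_equal(diff(m$theta), dtheta_expected[-1], tolerance = 1e-12)
  ## Doppler frequency is the phase increment rate over 2 pi
  expect_equal(m$df, dtheta_expected / (2 * pi * cfg$dt), tolerance = 1e-12)
  ## pure lateral motion at alpha_SD = 0 produces no phase
  cfg0 <- short_config(duration = 0.05, alpha_sd = 0)
  ml <- synthesize_motion(cfg0, velocity_rw_std = 0, lateral_rw_std = 1,
                          seed = 3)
  expect_true(all(ml$theta == 0))
  ## axial-only at alpha_SD = 0: dtheta = 4 pi dz / lambda per step
  ma <- synthesize_motion(cfg0, velocity_rw_std = 0.5, seed = 4)
  expect_equal(diff(ma$theta), (4 * pi / lam_um) * ma$dz[-1],
               tolerance = 1e-12)
})

test_that("synthesized components have the prescribed autocorrelations", {
  cfg <- short_config(duration = 2.5, tof_grid_ps = c(200))
  xi <- 2000
  comps <- component_spec(cfg$tof_grid_ps, I_fast = 1, xi_fast = xi)
  ser <- synthesize_gamma(comps, cfg, snr_db = Inf, seed = 6)
  g1 <- estimate_g1(ser, tau_d_max = 2e-3)
  ## AR(1) theory: autocorrelation exp(-xi tau) within estimator error
  an <- exp(-xi * g1$tau_d)
  ## rough standard error for an exponential-decay estimator over T = 2.5 s
  se <- sqrt(1 / (2.5 * xi))
  expect_lt(max(abs(g1$G1[1, ] / g1$G1[1, 1] - an)), 3 * se)
  ## fitted rate close to injected (single block, estimator noise)
  f <- fit_decay(g1$tau_d, g1$G1[1, ], order = 2)
  expect_equal(unname(coef(f)["xi"]), xi, tolerance = 0.1)
})

test_that("static bins are constant and motion rotates them", {
  cfg <- short_config(duration = 0.05, tof_grid_ps = c(100))
  comps <- component_spec(cfg$tof_grid_ps, I_static = 4)
  ## static-only, noise-free: |Gamma| constant
  ser <- synthesize_gamma(comps, cfg, snr_db = Inf, seed = 8)
  expect_equal(max(Mod(ser$gamma)) - min(Mod(ser$gamma)), 0, tolerance = 1e-12)
  ## with noise the modulus stays nearly constant
  ser_n <- synthesize_gamma(comps, cfg, snr_db = 40, seed = 8)
  expect_lt(stats::sd(Mod(ser_n$gamma)) / mean(Mod(ser_n$gamma)), 0.05)
  ## a linear bulk phase rotates the windowed autocorrelation at the
  ## injected Doppler frequency
  f0 <- 800
  mot <- synthesize_motion(cfg, velocity_rw_std = 0, seed = 1)
  mot$theta <- 2 * pi * f0 * mot$t_d
  ser_m <- synthesize_gamma(comps, cfg, motion = mot, snr_db = Inf, seed = 8)
  g1w <- window_autocorrelation(ser_m, center_t = 0.025, tof_select = 100)
  step_phase <- Arg(g1w[-1] / g1w[-length(g1w)])
  expect_equal(mean(step_phase) / (2 * pi * ser_m$dt), f0, tolerance = 1e-6)
})

test_that("IRF blur of component profiles conserves amplitude", {
  tof <- seq(0, 500, by = 2)
  irf <- irf_gaussian(21.9, tof_step_ps = 2)
  ## a static spike (the backscattered reference) becomes an IRF-shaped
  ## profile; amplitudes supported away from the grid edges are conserved
  spike <- numeric(length(tof)); spike[tof == 150] <- 5
  fast_prof <- 0.3 * exp(-((tof - 250) / 60)^2)
  comps <- component_spec(tof, I_static = spike, I_fast = fast_prof,
                          xi_fast = seq(100, 3000, length.out = length(tof)))
  blurred <- blur_with_irf(comps, irf)
  expect_equal(sum(blurred$I_static), 5, tolerance = 1e-9)
  expect_equal(sum(blurred$I_fast), sum(comps$I_fast), tolerance = 1e-6)
  ## blurred static profile matches the IRF shape around 150 ps
  i_pk <- which.max(blurred$I_static)
  expect_equal(tof[i_pk], 150)
  prof <- blurred$I_static / max(blurred$I_static)
  irf_on_grid <- stats::approx(irf$tof_ps + 150, irf$profile / max(irf$profile),
                               xout = tof, yleft = 0, yright = 0)$y
  expect_lt(max(abs(prof - irf_on_grid)), 1e-9)
  ## rates are carried over by amplitude-weighted interpolation:
  ## uniform amplitudes leave an interior constant rate unchanged
  comps2 <- component_spec(tof, I_fast = 1, xi_fast = 500)
  b2 <- blur_with_irf(comps2, irf)
  interior <- tof > 80 & tof < 220
  expect_equal(b2$xi_fast[interior], rep(500, sum(interior)),
               tolerance = 1e-6)
  ## delta IRF is the identity
  delta <- irf_gaussian(1e-6, tof_step_ps = 2, tof_span_ps = 10)
  b3 <- blur_with_irf(comps, delta)
  expect_equal(b3$I_static, comps$I_static, tolerance = 1e-9)
})

test_that("the same seed reproduces the same underlying processes", {
  cfg <- short_config(duration = 0.02)
  comps <- component_spec(cfg$tof_grid_ps, I_static = 1, I_fast = 0.5,
                          xi_fast = 1500)
  a <- synthesize_gamma(comps, cfg, snr_db = 40, seed = 9)
  b <- synthesize_gamma(comps, cfg, snr_db = 40, seed = 9)
  expect_identical(a$gamma, b$gamma)
  ## motion multiplies the same motion-free field by a pure phase
  mot <- synthesize_motion(cfg, velocity_rw_std = 0.3, seed = 10)
  cm <- synthesize_gamma(comps, cfg, motion = mot, snr_db = 40, seed = 9)
  expect_equal(cm$gamma, sweep(a$gamma, 2, exp(1i * mot$theta), `*`),
               tolerance = 1e-12)
})
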