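test_that("photon walk honors absorption, dynamics, and reproducibility", {
  op0 <- optical_properties(mu_a = 0, mu_sp = 10, n_r = 1.33, lambda0 = 855)
  lay <- medium_layer(Inf, op0, dynamic_fraction = 0, g_dynamic = 0.9,
                      g_static = 0)
  geo <- detection_geometry(rho = 0, radius = 0.5)
  ens <- simulate_paths(list(lay), geo, 3000, seed = 1, max_tof_ps = 800)
  ## no absorption: every exit weight is 1
  expect_true(all(ens$weight == 1))
  ## no dynamic scattering: no dynamic events anywhere
  expect_true(all(ens$n_dynamic == 0))
  expect_true(all(ens$q2_sum == 0))
  ## TOF consistent with per-layer path length
  expect_equal(ens$tof_ps,
               ens$path_length[, 1] * 1.33 / C_VACUUM_CM_S * 1e12,
               tolerance = 1e-9)
  ## same seed reproduces identically; different seed does not
  ens_b <- simulate_paths(list(lay), geo, 3000, seed = 1, max_tof_ps = 800)
  expect_identical(ens$tof_ps, ens_b$tof_ps)
  ens_c <- simulate_paths(list(lay), geo, 3000, seed = 2, max_tof_ps = 800)
  expect_false(identical(ens$tof_ps, ens_c$tof_ps))
})

test_that("detected mean TOF matches the diffusion TPSF at 7.6 mm", {
  op <- op_intralipid()
  lay <- medium_layer(Inf, op, dynamic_fraction = 1, g_dynamic = 0,
                      g_static = 0,
                      msd = msd_model("brownian", D_B = 1.18e-8))
  ens <- simulate_paths(list(lay), detection_geometry(rho = 0.76,
                                                      radius = 0.05),
                        4e5, seed = 3, max_tof_ps = 2000)
  expect_gt(length(ens$tof_ps), 500)
  ## TPSF-weighted mean TOF in the diffusive regime (>= 200 ps), with the
  ## index-matched boundary (A = 1) matching the simulation's free surface
  ts <- seq(200, 2000, by = 1)
  w <- tpsf_semi_infinite(ts, 0.76, op, A = 1)
  mean_analytic <- sum(ts * w) / sum(w)
  keep <- ens$tof_ps >= 200
  mean_mc <- sum(ens$tof_ps[keep] * ens$weight[keep]) /
    sum(ens$weight[keep])
  expect_equal(mean_mc, mean_analytic, tolerance = 0.05)
})

test_that("path filtering by dynamic deflection angle is monotone", {
  op <- optical_properties(mu_a = 0.1, mu_sp = 10, n_r = 1.4, lambda0 = 855)
  lay <- medium_layer(Inf, op, dynamic_fraction = 0.02, g_dynamic = 0.975,
                      g_static = 0.9,
                      msd = msd_model("brownian", D_B = 1e-6, alpha = 0.02))
  ens <- simulate_paths(list(lay), detection_geometry(rho = 0, radius = 0.3),
                        3e4, seed = 5, max_tof_ps = 1200)
  ## threshold pi keeps everything
  expect_identical(filter_paths(ens, pi)$tof_ps, ens$tof_ps)
  ## threshold 0 keeps only paths without dynamic events
  f0 <- filter_paths(ens, 0)
  expect_true(all(f0$n_dynamic == 0))
  ## retained fraction is nonincreasing with TOF (coarse bins)
  f <- filter_paths(ens, pi / 6)
  edges <- seq(0, 1200, by = 300)
  hall <- hist(ens$tof_ps, breaks = edges, plot = FALSE)$counts
  hfil <- hist(f$tof_ps, breaks = edges, plot = FALSE)$counts
  frac <- hfil / pmax(hall, 1)
  expect_true(all(diff(frac) <= 0.02))  # small slack for counting noise
  ## snake paths persist to intermediate TOF
  expect_gt(frac[2], 0)
})

test_that("phase function samplers hit their mean cosines", {
  set.seed(11)
  n <- 1e6
  ## isotropic: uniform cosine on [-1, 1]
  s0 <- phase_function_sampler("henyey_greenstein", g = 0)
  x <- s0(n)
  expect_equal(mean(x), 0, tolerance = 3 / sqrt(n / 3))
  expect_equal(mean(x^2), 1 / 3, tolerance = 0.003)
  ## RBC-like anisotropy
  s1 <- phase_function_sampler("henyey_greenstein", g = 0.975)
  x1 <- s1(n)
  se1 <- stats::sd(x1) / sqrt(n)
  expect_lt(abs(mean(x1) - 0.975), 3 * se1)
  ## two-term mixture has the mixture-weighted analytic mean
  s2 <- phase_function_sampler("two_term_hg",
                               params = list(g1 = 0.95, g2 = -0.3, w = 0.9))
  x2 <- s2(n)
  mu <- 0.9 * 0.95 + 0.1 * (-0.3)
  expect_lt(abs(mean(x2) - mu), 3 * stats::sd(x2) / sqrt(n))
  expect_error(phase_function_sampler("henyey_greenstein", g = 1.2), "g")
})

test_that("MC autocorrelation matches DWS theory in a homogeneous medium", {
  fx <- make_fixture("mc_homogeneous", seed = 17, n_photons = 1.5e5)
  tau_d <- seq(0, 10e-3, by = 1e-4)
  g1 <- autocorrelation_from_paths(fx$ensemble, tau_d, tof_bin_ps = 22)
  ## lag-0 slice equals the binned TPSF in every populated bin
  ok <- !is.na(g1$tpsf)
  expect_equal(g1$G1[ok, 1], g1$tpsf[ok])
  m <- msd_model("brownian", D_B = 1.18e-8, alpha = 1)
  ## pointwise agreement at TOFs >= 5 mean free times, within 3 MC SE
  mft_ps <- 1e12 * 1.33 / (fx$layers[[1]]$mu_s * C_VACUUM_CM_S)
  for (ts in c(300, 450, 600)) {
    i <- which.min(abs(g1$tof_ps - ts))
    expect_gt(g1$tof_ps[i], 5 * mft_ps)
    mc <- g1$G1[i, ] / g1$tpsf[i]
    an <- g1_dws(g1$tof_ps[i], tau_d, fx$optics, m)
    ## binomial-style SE bound for a weighted mean of factors in [0, 1]
    se <- 1 / sqrt(g1$n_paths[i])
    expect_lt(max(abs(mc - an)), 3 * se + 0.01)
  }
  ## an all-static medium keeps G1 equal to the TPSF at all lags
  g1s <- autocorrelation_from_paths(
    fx$ensemble, tau_d, tof_bin_ps = 22,
    msd_models = list(msd_model("brownian", D_B = 0)))
  expect_equal(g1s$G1[ok, ], matrix(g1s$tpsf[ok], sum(ok), length(tau_d)))
})

test_that("two-layer media with a slow superficial layer are biphasic", {
  fx <- make_fixture("two_layer_head", seed = 5, n_photons = 2e5)
  tau_d <- seq(0, 4e-3, by = 2e-5)
  g1 <- autocorrelation_from_paths(fx$ensemble, tau_d, tof_bin_ps = 44)
  fits <- fit_decay_tof(g1, order = 2, window = 2e-3,
                        tof_range = c(80, 1400))
  df <- as.data.frame(fits)
  early <- df[df$tau_s <= 400, ]
  late <- df[df$tau_s >= 800, ]
  slope_early <- stats::coef(stats::lm(xi ~ tau_s, early))[2]
  slope_late <- stats::coef(stats::lm(xi ~ tau_s, late))[2]
  expect_gt(slope_late, 2 * slope_early)
})
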