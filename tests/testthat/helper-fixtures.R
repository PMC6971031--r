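## Shared fixtures, built in code.

## reference optical properties of the Intralipid phantom scene
op_intralipid <- function() {
  optical_properties(mu_a = 0.045, mu_sp = 10, n_r = 1.33, lambda0 = 855)
}

## analytic constant + bi-exponential autocorrelation surface as a tof_g1
analytic_tof_g1 <- function(tof_ps, tau_d, I_static, I_slow, xi_slow,
                            I_fast, xi_fast) {
  n <- length(tof_ps)
  rec <- function(x) rep_len(x, n)
  G1 <- outer(rec(I_static), rep(1, length(tau_d))) +
    rec(I_slow) * exp(-outer(rec(xi_slow), tau_d)) +
    rec(I_fast) * exp(-outer(rec(xi_fast), tau_d))
  structure(
    list(tof_ps = tof_ps, tau_d = tau_d, G1 = G1, tpsf = G1[, 1],
         n_paths = NULL, source = "analytic", seed = NULL, averaging = NULL),
    class = "tof_g1")
}

## short acquisition for cheap synthesis tests
short_config <- function(duration = 0.25, tof_grid_ps = c(100, 200, 300),
                         alpha_sd = 0) {
  acquisition_config(block_duration = duration, tof_grid_ps = tof_grid_ps,
                     alpha_sd = alpha_sd)
}
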