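#' Read and write pipeline containers
#'
#' Single-file containers carrying any of the package's stage outputs
#' (coherence series, autocorrelation surfaces, path ensembles, fit tables)
#' together with a run manifest (stage name, seed, configuration hash,
#' package version, timestamp). Complex arrays round-trip losslessly.
#' Containers are versioned; reading a file with an unknown schema raises
#' an explicit error naming the offending field.
#'
#' @param obj object to store.
#' @param path file path.
#' @param stage stage name recorded in the manifest.
#' @param seed seed recorded in the manifest.
#' @param config optional configuration object; a stable hash of it is
#'   recorded.
#' @param manifest optional existing manifest to extend (pipeline
#'   provenance accumulates across stages).
#' @return `write_container()` returns `path` invisibly;
#'   `read_container()` returns the stored object with the manifest in
#'   attribute `"manifest"`.
#' @export
write_container <- function(obj, path, stage = "unnamed", seed = NULL,
                            config = NULL, manifest = NULL) {
  entry <- list(stage = stage, seed = seed,
                config_hash = if (!is.null(config)) config_hash(config),
                version = as.character(utils::packageVersion("inirs")),
                timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  manifest <- c(manifest, list(entry))
  payload <- list(schema = "inirs-container", schema_version = 1L,
                  class = class(obj), object = obj, manifest = manifest)
  saveRDS(payload, path)
  invisible(path)
}

#' @rdname write_container
#' @export
read_container <- function(path) {
  payload <- readRDS(path)
  if (!is.list(payload) || !identical(payload$schema, "inirs-container")) {
    stop("not an inirs container: missing 'schema'")
  }
  if (!identical(payload$schema_version, 1L)) {
    stop("unsupported container schema_version: ",
         format(payload$schema_version))
  }
  for (field in c("class", "object", "manifest")) {
    if (is.null(payload[[field]])) {
      stop("malformed container: missing '", field, "'")
    }
  }
  obj <- payload$object
  attr(obj, "manifest") <- payload$manifest
  obj
}

## Stable hash of a configuration object: canonical deparse (names sorted
## recursively) digested with md5.
config_hash <- function(config) {
  canon <- function(x) {
    if (is.list(x) && !is.null(names(x))) {
      x <- x[order(names(x))]
      lapply(x, canon)
    } else x
  }
  txt <- paste(deparse(canon(unclass(config))), collapse = "\n")
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(txt, tf)
  unname(tools::md5sum(tf))
}

#' Export a motion trace as CSV
#'
#' Columns: `t_d` (s), `df` (Hz), `theta_bps` (rad), `Z_um`, `dV_um_s`.
#'
#' @param track data frame with `t` and `df` from [doppler_track()].
#' @param path output CSV path.
#' @param lambda0 wavelength in nm for the displacement/velocity columns.
#' @return the exported data frame, invisibly.
#' @export
export_motion_csv <- function(track, path, lambda0 = 855) {
  dt <- if (nrow(track) > 1) track$t[2] - track$t[1] else 1
  theta <- cumsum(2 * pi * track$df * dt)
  theta <- theta - theta[1]
  out <- data.frame(t_d = track$t, df = track$df, theta_bps = theta,
                    Z_um = phase_to_displacement(theta, lambda0),
                    dV_um_s = doppler_velocity(track$df, lambda0))
  utils::write.csv(out, path, row.names = FALSE)
  invisible(out)
}

#' Generate seeded end-to-end fixtures
#'
#' Small preset scenes used by tests and examples:
#' \describe{
#'   \item{intralipid}{uniformly dynamic aqueous phantom (mu_s' = 10/cm,
#'     mu_a = 0.045/cm, n_r = 1.33): no static component, one dynamic
#'     component whose rates follow the Brownian decay-rate line with
#'     BFI = 1.18e-8 cm^2/s.}
#'   \item{forearm_like}{tissue-like scene: static + slow + fast components
#'     with bulk motion.}
#'   \item{two_layer_head}{Monte Carlo two-layer medium: low-flow
#'     superficial layer over a high-flow deep layer.}
#'   \item{mc_homogeneous}{homogeneous all-dynamic isotropic Monte Carlo
#'     medium (DWS oracle conditions).}
#' }
#'
#' @param preset one of the names above.
#' @param seed integer seed; identical seeds give identical fixtures.
#' @param n_photons photon count for the Monte Carlo presets.
#' @param block_duration block length in s for the synthetic presets
#'   (default 2.5).
#' @return a list with the generated objects and the ground truth used.
#' @export
make_fixture <- function(preset = c("intralipid", "forearm_like",
                                    "two_layer_head", "mc_homogeneous"),
                         seed = 1, n_photons = 2e5, block_duration = 2.5) {
  preset <- match.arg(preset)
  switch(preset,
    intralipid = {
      op <- optical_properties(mu_a = 0.045, mu_sp = 10, n_r = 1.33,
                               lambda0 = 855)
      cfg <- acquisition_config(block_duration = block_duration,
                                tof_grid_ps = seq(66, 550, by = 22),
                                alpha_sd = 0)
      bfi <- 1.18e-8
      xi <- decay_rate_line(cfg$tof_grid_ps, bfi, op)
      I <- tpsf_semi_infinite(cfg$tof_grid_ps, 0, op)
      I <- I / max(I)
      comps <- component_spec(cfg$tof_grid_ps, I_static = 0,
                              I_fast = I, xi_fast = xi)
      series <- synthesize_gamma(comps, cfg, motion = NULL, seed = seed)
      list(series = series, components = comps, config = cfg, optics = op,
           truth = list(bfi = bfi, tau_s0 = 0))
    },
    forearm_like = {
      op <- optical_properties(mu_a = 0.15, mu_sp = 7, n_r = 1.4,
                               lambda0 = 855)
      cfg <- acquisition_config(block_duration = block_duration,
                                tof_grid_ps = seq(22, 660, by = 22))
      bfi <- 1.5e-9
      xi_fast <- decay_rate_line(cfg$tof_grid_ps, bfi, op, tau_s0 = 0)
      I_tot <- tpsf_semi_infinite(cfg$tof_grid_ps, 0, op)
      I_tot <- I_tot / max(I_tot)
      ## at null separation the backscattered static component is far
      ## stronger than the diffuse light and approximates the IRF in TOF;
      ## diffuse static light decays with TOF, fast dominates late, slow
      ## sits in between
      backscatter <- 12 * exp(-((cfg$tof_grid_ps - 44) / 28)^2)
      w_static <- exp(-cfg$tof_grid_ps / 80)
      w_slow <- 0.35 * exp(-cfg$tof_grid_ps / 250)
      w_fast <- 1 - pmin(w_static + w_slow, 0.95)
      comps <- component_spec(
        cfg$tof_grid_ps,
        I_static = backscatter + I_tot * w_static,
        I_slow = I_tot * w_slow, xi_slow = xi_fast / 8,
        I_fast = I_tot * w_fast, xi_fast = xi_fast)
      motion <- synthesize_motion(cfg, velocity_rw_std = 0.2, seed = seed + 1)
      series <- synthesize_gamma(comps, cfg, motion = motion, seed = seed)
      list(series = series, components = comps, config = cfg, optics = op,
           motion = motion, truth = list(bfi = bfi, tau_s0 = 0))
    },
    two_layer_head = {
      op_sup <- optical_properties(mu_a = 0.1, mu_sp = 8, n_r = 1.4,
                                   lambda0 = 855)
      op_deep <- optical_properties(mu_a = 0.15, mu_sp = 10, n_r = 1.4,
                                    lambda0 = 855)
      bfi_sup <- 1e-9; bfi_deep <- 8e-9; frac <- 0.02
      lay <- list(
        medium_layer(0.5, op_sup, dynamic_fraction = frac,
                     g_dynamic = 0.975, g_static = 0.9,
                     msd = msd_model("brownian", D_B = bfi_sup / frac,
                                     alpha = frac)),
        medium_layer(Inf, op_deep, dynamic_fraction = frac,
                     g_dynamic = 0.975, g_static = 0.9,
                     msd = msd_model("brownian", D_B = bfi_deep / frac,
                                     alpha = frac)))
      ens <- simulate_paths(lay, detection_geometry(rho = 0, radius = 0.3),
                            n_photons = n_photons, seed = seed)
      list(ensemble = ens, layers = lay,
           truth = list(bfi_superficial = bfi_sup, bfi_deep = bfi_deep))
    },
    mc_homogeneous = {
      op <- optical_properties(mu_a = 0.045, mu_sp = 10, n_r = 1.33,
                               lambda0 = 855)
      bfi <- 1.18e-8
      lay <- medium_layer(Inf, op, dynamic_fraction = 1, g_dynamic = 0,
                          g_static = 0,
                          msd = msd_model("brownian", D_B = bfi, alpha = 1))
      ens <- simulate_paths(list(lay),
                            detection_geometry(rho = 0, radius = 0.3),
                            n_photons = n_photons, seed = seed)
      list(ensemble = ens, layers = list(lay), optics = op,
           truth = list(bfi = bfi, tau_s0 = 0))
    })
}
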