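#' Layer of a scattering medium for the correlation Monte Carlo
#'
#' Each scattering event in a layer is dynamic (moving scatterer, e.g. a red
#' blood cell) with probability `dynamic_fraction` and static otherwise.
#' Dynamic and static events may have different scattering anisotropies;
#' the layer scattering coefficient is derived from `mu_sp` and the
#' event-probability-weighted composite anisotropy
#' `g_comp = dynamic_fraction * g_dynamic + (1 - dynamic_fraction) * g_static`
#' via `mu_s = mu_sp / (1 - g_comp)`.
#'
#' @param thickness layer thickness in cm; `Inf` for the terminal
#'   semi-infinite layer.
#' @param optics an [optical_properties()] (its `mu_sp`, `mu_a`, `n_r`,
#'   `lambda0` are used).
#' @param dynamic_fraction probability that a scattering event is dynamic,
#'   in [0, 1].
#' @param g_dynamic anisotropy of dynamic scatterers (RBC-like: ~0.975).
#' @param g_static anisotropy of static scatterers.
#' @param msd an [msd_model()] describing the motion of dynamic scatterers
#'   in this layer.
#' @param phase_dynamic phase function for dynamic events:
#'   `list(kind = "hg")` (default, uses `g_dynamic`) or
#'   `list(kind = "two_term_hg", g1 = , g2 = , w = )` for the mixture
#'   `w HG(g1) + (1 - w) HG(g2)`.
#' @return an object of class `medium_layer`.
#' @export
medium_layer <- function(thickness, optics, dynamic_fraction = 1,
                         g_dynamic = 0, g_static = 0,
                         msd = msd_model("brownian", D_B = 1e-8),
                         phase_dynamic = list(kind = "hg")) {
  stopifnot(inherits(optics, "inirs_optics"), inherits(msd, "inirs_msd"))
  if (thickness <= 0) stop("thickness must be > 0")
  if (dynamic_fraction < 0 || dynamic_fraction > 1) {
    stop("dynamic_fraction must lie in [0, 1]")
  }
  if (abs(g_dynamic) >= 1 || abs(g_static) >= 1) stop("|g| must be < 1")
  g_comp <- dynamic_fraction * g_dynamic + (1 - dynamic_fraction) * g_static
  structure(
    list(thickness = thickness, optics = optics,
         dynamic_fraction = dynamic_fraction,
         g_dynamic = g_dynamic, g_static = g_static,
         mu_s = optics$mu_sp / (1 - g_comp),
         msd = msd, phase_dynamic = phase_dynamic),
    class = "medium_layer"
  )
}

#' Detection geometry for the Monte Carlo
#'
#' Photons are launched as a pencil beam normal to the surface at the
#' origin. A photon is detected when it exits the top surface with radial
#' distance within `radius` of the source-detector separation `rho` and
#' polar exit angle within the acceptance half-angle. Cylindrical symmetry
#' is exploited: the detector is the annulus `[rho - radius, rho + radius]`,
#' which is statistically equivalent to an off-axis disk for
#' azimuthally symmetric media and collects far more photons.
#'
#' @param rho source-detector separation in cm (0 for the null-separation
#'   backscattering geometry).
#' @param radius detector radius in cm, > 0.
#' @param acceptance acceptance half-angle in rad, in (0, pi/2].
#' @return an object of class `detection_geometry`.
#' @export
detection_geometry <- function(rho = 0, radius = 0.1, acceptance = pi / 2) {
  if (rho < 0) stop("rho must be >= 0")
  if (radius <= 0) stop("radius must be > 0")
  if (acceptance <= 0 || acceptance > pi / 2) {
    stop("acceptance must lie in (0, pi/2]")
  }
  structure(list(rho = rho, radius = radius, acceptance = acceptance),
            class = "detection_geometry")
}

#' Simulate photon paths through a layered dynamic medium
#'
#' Runs the correlation-transport photon random walk and returns, for every
#' detected photon, its time of flight, absorption survival weight, number
#' of dynamic scattering events, largest dynamic deflection angle, and the
#' per-layer accumulated squared momentum transfer and path length. The
#' per-layer sum of `q_i^2 = 2 k^2 (1 - cos theta_i)` over dynamic events is
#' the sufficient statistic for the path's field decorrelation under the
#' independent-scatterer assumption.
#'
#' @param layers a list of [medium_layer()]s, top first; the last layer may
#'   have infinite thickness.
#' @param geometry a [detection_geometry()].
#' @param n_photons number of photons to launch, >= 1.
#' @param seed integer seed for the simulation's random number generator.
#' @param max_tof_ps paths exceeding this time of flight are terminated.
#' @param weight_cutoff,roulette_survival Russian-roulette parameters.
#' @return an object of class `path_ensemble`: a list with vectors
#'   `tof_ps`, `weight`, `n_dynamic`, `max_dynamic_angle`, matrices
#'   `q2_sum` and `path_length` (one column per layer), the generating
#'   `layers`, `geometry`, `seed`, and `n_launched`.
#' @export
simulate_paths <- function(layers, geometry, n_photons, seed,
                           max_tof_ps = 2000, weight_cutoff = 1e-6,
                           roulette_survival = 0.1) {
  if (inherits(layers, "medium_layer")) layers <- list(layers)
  stopifnot(length(layers) >= 1, inherits(geometry, "detection_geometry"))
  if (n_photons < 1) stop("n_photons must be >= 1")
  lambda0 <- layers[[1]]$optics$lambda0
  lm <- t(vapply(layers, function(l) {
    c(l$thickness, l$optics$mu_a, l$mu_s, l$g_static, l$g_dynamic,
      l$dynamic_fraction, l$optics$n_r)
  }, numeric(7)))
  pm <- t(vapply(layers, function(l) {
    pd <- l$phase_dynamic
    if (identical(pd$kind, "two_term_hg")) c(1, pd$g1, pd$g2, pd$w)
    else c(0, 0, 0, 0)
  }, numeric(4)))
  res <- mc_simulate_cpp(lm, pm, lambda0, geometry$rho, geometry$radius,
                         geometry$acceptance, as.integer(n_photons),
                         as.numeric(seed), max_tof_ps,
                         weight_cutoff, roulette_survival)
  structure(
    c(res, list(layers = layers, geometry = geometry, seed = seed,
                n_launched = n_photons, max_tof_ps = max_tof_ps)),
    class = "path_ensemble"
  )
}

#' @export
print.path_ensemble <- function(x, ...) {
  cat(sprintf(
    "Photon path ensemble: %d detected / %d launched (%d layer%s)\n",
    length(x$tof_ps), x$n_launched, length(x$layers),
    if (length(x$layers) > 1) "s" else ""))
  if (length(x$tof_ps)) {
    cat(sprintf("  TOF range %.0f-%.0f ps, mean dynamic events %.1f\n",
                min(x$tof_ps), max(x$tof_ps), mean(x$n_dynamic)))
  }
  invisible(x)
}

#' TOF-resolved field autocorrelation from a path ensemble
#'
#' Each path contributes the decorrelation factor
#' `prod_layers exp(-q2_sum_layer * <dr^2(tau_d)>_layer / 6)`; the
#' TOF-resolved autocorrelation in a TOF bin is the absorption-weighted mean
#' of path factors times the bin intensity, so that `G1(tau_s, 0)` equals
#' the binned TPSF exactly. Empty TOF bins are returned as `NA`.
#'
#' @param ensemble a [simulate_paths()] result.
#' @param tau_d lag-time grid in seconds.
#' @param tof_bin_ps TOF bin width in ps (default 22, mirroring the
#'   instrument resolution), or an explicit vector of bin edges.
#' @param msd_models optional list of [msd_model()]s, one per layer,
#'   overriding the models stored in the ensemble's layers.
#' @return an object of class `tof_g1` with fields `tof_ps` (bin centers),
#'   `tau_d`, `G1` (bins x lags), `tpsf`, `n_paths`, and metadata.
#' @export
autocorrelation_from_paths <- function(ensemble, tau_d, tof_bin_ps = 22,
                                       msd_models = NULL) {
  stopifnot(inherits(ensemble, "path_ensemble"))
  L <- length(ensemble$layers)
  if (is.null(msd_models)) {
    msd_models <- lapply(ensemble$layers, `[[`, "msd")
  }
  stopifnot(length(msd_models) == L)
  if (length(tof_bin_ps) == 1L) {
    edges <- seq(0, ensemble$max_tof_ps + tof_bin_ps, by = tof_bin_ps)
  } else {
    edges <- tof_bin_ps
  }
  if (min(ensemble$tof_ps) < edges[1] || max(ensemble$tof_ps) > edges[length(edges)]) {
    stop("tof bins do not cover the ensemble TOF range")
  }
  centers <- (edges[-1] + edges[-length(edges)]) / 2
  bin <- findInterval(ensemble$tof_ps, edges, rightmost.closed = TRUE)
  nb <- length(centers)
  nl <- length(tau_d)
  G1 <- matrix(NA_real_, nb, nl)
  tpsf <- rep(NA_real_, nb)
  npaths <- tabulate(bin, nbins = nb)
  ## per-path decay factors: exp(-sum_l q2_sum[, l] * msd_l(tau_d) / 6)
  ## accumulate weighted sums per bin for each lag
  wsum <- tapply(ensemble$weight, factor(bin, levels = seq_len(nb)), sum)
  wsum[is.na(wsum)] <- 0
  msd_tab <- vapply(msd_models, msd, numeric(nl), tau_d = tau_d) # nl x L
  if (is.null(dim(msd_tab))) msd_tab <- matrix(msd_tab, nrow = nl)
  for (j in seq_len(nl)) {
    expo <- as.vector(ensemble$q2_sum %*% msd_tab[j, ]) / 6
    f <- ensemble$weight * exp(-expo)
    s <- tapply(f, factor(bin, levels = seq_len(nb)), sum)
    s[is.na(s)] <- 0
    G1[, j] <- ifelse(npaths > 0, as.numeric(s), NA_real_)
  }
  tpsf <- ifelse(npaths > 0, as.numeric(wsum), NA_real_)
  ## normalize to intensity per unit launched photon
  G1 <- G1 / ensemble$n_launched
  tpsf <- tpsf / ensemble$n_launched
  structure(
    list(tof_ps = centers, tau_d = tau_d, G1 = G1, tpsf = tpsf,
         n_paths = npaths, source = "montecarlo",
         seed = ensemble$seed, averaging = NULL),
    class = "tof_g1"
  )
}

#' Filter paths by their largest dynamic deflection angle
#'
#' Retains only the paths whose every dynamic scattering event deflected the
#' photon by at most `max_dynamic_angle`; static events are unrestricted.
#' Used to isolate "dynamical snake paths" — paths that are only gently
#' deflected by moving scatterers and therefore decorrelate slowly.
#'
#' @param ensemble a [simulate_paths()] result.
#' @param max_dynamic_angle threshold in rad, in [0, pi].
#' @return a `path_ensemble` containing the retained paths.
#' @export
filter_paths <- function(ensemble, max_dynamic_angle) {
  stopifnot(inherits(ensemble, "path_ensemble"))
  if (max_dynamic_angle < 0 || max_dynamic_angle > pi) {
    stop("max_dynamic_angle must lie in [0, pi]")
  }
  keep <- ensemble$max_dynamic_angle <= max_dynamic_angle
  out <- ensemble
  for (f in c("tof_ps", "weight", "n_dynamic", "max_dynamic_angle")) {
    out[[f]] <- ensemble[[f]][keep]
  }
  out$q2_sum <- ensemble$q2_sum[keep, , drop = FALSE]
  out$path_length <- ensemble$path_length[keep, , drop = FALSE]
  out
}

#' Scattering phase function samplers
#'
#' Returns a function drawing deflection cosines from the requested phase
#' function: Henyey-Greenstein with anisotropy `g`, or the two-term HG
#' mixture `w HG(g1) + (1 - w) HG(g2)` (mean cosine
#' `w g1 + (1 - w) g2`).
#'
#' @param kind `"henyey_greenstein"` or `"two_term_hg"`.
#' @param g anisotropy for the single-term HG, |g| < 1.
#' @param params for `"two_term_hg"`: `list(g1 = , g2 = , w = )`.
#' @return a function `function(n)` returning `n` sampled cosines.
#' @export
phase_function_sampler <- function(kind = c("henyey_greenstein",
                                            "two_term_hg"),
                                   g = 0, params = NULL) {
  kind <- match.arg(kind)
  sample_hg <- function(n, g) {
    u <- stats::runif(n)
    if (abs(g) < 1e-8) return(2 * u - 1)
    f <- (1 - g^2) / (1 - g + 2 * g * u)
    pmin(1, pmax(-1, (1 + g^2 - f^2) / (2 * g)))
  }
  if (kind == "henyey_greenstein") {
    if (abs(g) >= 1) stop("|g| must be < 1")
    function(n) sample_hg(n, g)
  } else {
    if (is.null(params$g1) || is.null(params$g2) || is.null(params$w)) {
      stop("two_term_hg requires params g1, g2, w")
    }
    if (abs(params$g1) >= 1 || abs(params$g2) >= 1 ||
        params$w < 0 || params$w > 1) {
      stop("invalid two_term_hg parameters")
    }
    function(n) {
      pick <- stats::runif(n) < params$w
      out <- numeric(n)
      out[pick] <- sample_hg(sum(pick), params$g1)
      out[!pick] <- sample_hg(sum(!pick), params$g2)
      out
    }
  }
}
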