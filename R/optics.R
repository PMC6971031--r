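#' Optical properties of a turbid medium
#'
#' Bundles the absorption coefficient, reduced scattering coefficient,
#' optional scattering coefficient and anisotropy, refractive index, and
#' center wavelength that parameterize light transport models. The group
#' refractive index is assumed equal to the phase index.
#'
#' @param mu_a absorption coefficient (1/cm), >= 0.
#' @param mu_sp reduced scattering coefficient mu_s' (1/cm), > 0.
#' @param mu_s scattering coefficient (1/cm), optional. If supplied together
#'   with `g` it must satisfy `mu_sp = mu_s * (1 - g)`.
#' @param g scattering anisotropy (mean cosine of the single-scattering
#'   deflection angle), in (-1, 1). Optional; if `mu_s` is given without `g`,
#'   `g` is derived from `mu_sp` and `mu_s`.
#' @param n_r refractive index, >= 1. Defaults to 1.4, typical for soft
#'   tissue; use 1.33 for aqueous phantoms such as Intralipid.
#' @param lambda0 center wavelength in nm.
#' @return an object of class `inirs_optics`.
#' @examples
#' optical_properties(mu_a = 0.045, mu_sp = 10, n_r = 1.33, lambda0 = 855)
#' @export
optical_properties <- function(mu_a, mu_sp, mu_s = NULL, g = NULL,
                               n_r = 1.4, lambda0 = 855) {
  stopifnot(is.numeric(mu_a), length(mu_a) == 1L, is.finite(mu_a),
            is.numeric(mu_sp), length(mu_sp) == 1L, is.finite(mu_sp))
  if (mu_a < 0) stop("mu_a must be >= 0")
  if (mu_sp <= 0) stop("mu_sp must be > 0")
  if (n_r < 1) stop("n_r must be >= 1")
  if (lambda0 <= 0) stop("lambda0 must be > 0")
  if (!is.null(g) && abs(g) >= 1) stop("g must satisfy |g| < 1")
  if (!is.null(mu_s)) {
    if (mu_s <= 0) stop("mu_s must be > 0")
    if (is.null(g)) {
      g <- 1 - mu_sp / mu_s
      if (abs(g) >= 1) stop("inconsistent mu_s and mu_sp")
    } else {
      rel <- abs(mu_sp - mu_s * (1 - g)) / mu_sp
      if (rel > 1e-9) {
        stop("mu_sp must equal mu_s * (1 - g) (relative error ",
             format(rel), ")")
      }
    }
  } else if (!is.null(g)) {
    mu_s <- mu_sp / (1 - g)
  }
  structure(
    list(mu_a = mu_a, mu_sp = mu_sp, mu_s = mu_s, g = g,
         n_r = n_r, lambda0 = lambda0),
    class = "inirs_optics"
  )
}

#' @export
print.inirs_optics <- function(x, ...) {
  cat("Optical properties:\n")
  cat(sprintf("  mu_a    = %g 1/cm\n", x$mu_a))
  cat(sprintf("  mu_s'   = %g 1/cm\n", x$mu_sp))
  if (!is.null(x$mu_s)) cat(sprintf("  mu_s    = %g 1/cm (g = %g)\n", x$mu_s, x$g))
  cat(sprintf("  n_r     = %g\n", x$n_r))
  cat(sprintf("  lambda0 = %g nm\n", x$lambda0))
  invisible(x)
}

#' Mean-squared displacement model for dynamic scatterers
#'
#' Describes particle motion through the mean-squared displacement (MSD)
#' as a function of lag time. Four laws are supported:
#' \describe{
#'   \item{brownian}{`6 D_B tau_d` — unordered diffusive motion.}
#'   \item{random_flow}{`v^2 tau_d^2` — advection with a Gaussian velocity
#'     distribution of standard deviation `v`.}
#'   \item{hydrodynamic}{`6 D_B (tau_d - tau_C (1 - exp(-tau_d/tau_C)))` —
#'     ballistic motion crossing over to diffusion on the collision time
#'     scale `tau_C`.}
#'   \item{hybrid}{`6 D_B tau_d + v^2 tau_d^2` — diffusion plus advection.}
#' }
#'
#' @param kind one of `"brownian"`, `"random_flow"`, `"hydrodynamic"`,
#'   `"hybrid"`.
#' @param D_B effective Brownian diffusion coefficient (cm^2/s).
#' @param v velocity-distribution standard deviation (cm/s).
#' @param tau_C collision time (s); required for `"hydrodynamic"`.
#' @param alpha probability that a scattering event is dynamic, in [0, 1].
#'   Enters the DWS decay and the blood flow index `BFI = alpha * D_B`.
#' @return an object of class `inirs_msd`.
#' @examples
#' m <- msd_model("brownian", D_B = 1.18e-8)
#' msd(m, 1e-4)
#' @export
msd_model <- function(kind = c("brownian", "random_flow", "hydrodynamic",
                               "hybrid"),
                      D_B = NULL, v = NULL, tau_C = NULL, alpha = 1) {
  kind <- match.arg(kind)
  if (alpha < 0 || alpha > 1) stop("alpha must lie in [0, 1]")
  need <- switch(kind,
    brownian = "D_B", random_flow = "v",
    hydrodynamic = c("D_B", "tau_C"), hybrid = c("D_B", "v"))
  vals <- list(D_B = D_B, v = v, tau_C = tau_C)
  for (p in need) {
    if (is.null(vals[[p]])) {
      stop(sprintf("msd model '%s' requires parameter '%s'", kind, p))
    }
  }
  if (!is.null(D_B) && D_B < 0) stop("D_B must be >= 0")
  if (!is.null(v) && v < 0) stop("v must be >= 0")
  if (kind == "hydrodynamic" && tau_C <= 0) stop("tau_C must be > 0")
  structure(list(kind = kind, D_B = D_B, v = v, tau_C = tau_C, alpha = alpha),
            class = "inirs_msd")
}

#' @export
print.inirs_msd <- function(x, ...) {
  cat(sprintf("MSD model '%s':", x$kind))
  for (p in c("D_B", "v", "tau_C")) {
    if (!is.null(x[[p]])) cat(sprintf(" %s = %g", p, x[[p]]))
  }
  cat(sprintf(" alpha = %g\n", x$alpha))
  invisible(x)
}

#' Evaluate a mean-squared displacement law
#'
#' @param model an [msd_model()].
#' @param tau_d lag time(s) in seconds, >= 0.
#' @return mean-squared displacement in cm^2, same length as `tau_d`.
#' @export
msd <- function(model, tau_d) {
  stopifnot(inherits(model, "inirs_msd"))
  if (any(tau_d < 0)) stop("tau_d must be >= 0")
  switch(model$kind,
    brownian = 6 * model$D_B * tau_d,
    random_flow = model$v^2 * tau_d^2,
    hydrodynamic = 6 * model$D_B *
      (tau_d - model$tau_C * (1 - exp(-tau_d / model$tau_C))),
    hybrid = 6 * model$D_B * tau_d + model$v^2 * tau_d^2
  )
}

#' Single-scattering (DLS) field autocorrelation
#'
#' Normalized field autocorrelation for single scattering at a fixed
#' scattering vector of magnitude `q`, with a static scattering fraction:
#' `g1 = eta_c + (1 - eta_c) exp(-q^2 <dr^2(tau_d)> / 6)`.
#'
#' @param eta_c static scattering fraction in [0, 1].
#' @param q scattering vector magnitude (1/cm).
#' @param model an [msd_model()].
#' @param tau_d lag time(s) in seconds.
#' @return normalized autocorrelation values in (0, 1].
#' @export
g1_dls <- function(eta_c, q, model, tau_d) {
  if (eta_c < 0 || eta_c > 1) stop("eta_c must lie in [0, 1]")
  eta_c + (1 - eta_c) * exp(-q^2 * msd(model, tau_d) / 6)
}

#' Diffusing-wave (DWS) TOF-resolved field autocorrelation
#'
#' Normalized field autocorrelation in the multiple-scattering regime at a
#' fixed time of flight:
#' `g1 = exp(-(1/3) alpha k^2 <dr^2(tau_d)> mu_s' c tau_s / n_r)`,
#' where `k = 2 pi n_r / lambda0` is the medium wavenumber and
#' `c tau_s / n_r` the photon path length.
#'
#' @param tau_s time of flight in ps, >= 0.
#' @param tau_d lag time(s) in seconds.
#' @param optics an [optical_properties()].
#' @param model an [msd_model()] (its `alpha` is used as the dynamic
#'   scattering probability).
#' @return normalized autocorrelation values in (0, 1].
#' @export
g1_dws <- function(tau_s, tau_d, optics, model) {
  stopifnot(inherits(optics, "inirs_optics"))
  if (any(tau_s < 0)) stop("tau_s must be >= 0")
  k <- wavenumber(optics$lambda0, optics$n_r)
  exp(-(1 / 3) * model$alpha * k^2 * msd(model, tau_d) *
        optics$mu_sp * C_VACUUM_CM_S * (tau_s / PS_PER_S) / optics$n_r)
}

#' DWS decay rate versus time of flight, and its inverse
#'
#' For Brownian motion the TOF-resolved decay rate of the DWS field
#' autocorrelation is linear in TOF:
#' `xi(tau_s) = 2 k^2 BFI mu_s' c (tau_s - tau_s0) / n_r`,
#' with `BFI = alpha D_B` the blood flow index. `bfi_from_slope()` inverts
#' the relation: `BFI = lambda0^2 slope / (8 pi^2 n_r mu_s' c)`, where
#' `slope` is the fitted slope of `xi` versus TOF.
#'
#' @param tau_s time of flight in ps.
#' @param bfi blood flow index `alpha * D_B` (cm^2/s), >= 0.
#' @param optics an [optical_properties()].
#' @param tau_s0 TOF-axis intercept in ps (0 for a homogeneous medium;
#'   non-zero values absorb a low-flow superficial layer).
#' @return `decay_rate_line()`: decay rate(s) in 1/s.
#' @examples
#' op <- optical_properties(0.045, 10, n_r = 1.33, lambda0 = 855)
#' xi <- decay_rate_line(c(100, 200), bfi = 1.18e-8, optics = op)
#' bfi_from_slope(diff(xi) / 100, op)  # recovers 1.18e-8
#' @export
decay_rate_line <- function(tau_s, bfi, optics, tau_s0 = 0) {
  stopifnot(inherits(optics, "inirs_optics"))
  if (bfi < 0) stop("bfi must be >= 0")
  k <- wavenumber(optics$lambda0, optics$n_r)
  2 * k^2 * bfi * optics$mu_sp * C_VACUUM_CM_S *
    ((tau_s - tau_s0) / PS_PER_S) / optics$n_r
}

#' @rdname decay_rate_line
#' @param slope slope of the decay rate versus TOF, in 1/(s ps), >= 0.
#' @return `bfi_from_slope()`: blood flow index in cm^2/s.
#' @export
bfi_from_slope <- function(slope, optics) {
  stopifnot(inherits(optics, "inirs_optics"))
  if (optics$mu_sp == 0) stop("mu_sp must be non-zero")
  if (any(slope < 0)) stop("slope must be >= 0")
  slope_si <- slope * PS_PER_S  # 1/(s s)
  nm_to_cm(optics$lambda0)^2 * slope_si /
    (8 * pi^2 * optics$n_r * optics$mu_sp * C_VACUUM_CM_S)
}

#' Fitted decay-rate line
#'
#' Container for the linear dependence of the autocorrelation decay rate on
#' time of flight: slope, TOF-axis intercept `tau_s0`, and the blood flow
#' index derived from the slope.
#'
#' @param slope decay rate per TOF, 1/(s ps).
#' @param tau_s0 TOF-axis intercept, ps.
#' @param optics an [optical_properties()] used to convert slope to BFI.
#' @param se optional named list of standard errors (`slope`, `tau_s0`).
#' @return an object of class `decay_line` with elements `slope`, `tau_s0`,
#'   `bfi`, and `optics`.
#' @export
decay_line <- function(slope, tau_s0, optics, se = NULL) {
  structure(
    list(slope = slope, tau_s0 = tau_s0,
         bfi = bfi_from_slope(slope, optics), optics = optics, se = se),
    class = "decay_line"
  )
}

#' @export
print.decay_line <- function(x, ...) {
  cat("Decay-rate line xi(tau_s):\n")
  cat(sprintf("  slope  = %g 1/(s ps)\n", x$slope))
  cat(sprintf("  tau_s0 = %g ps\n", x$tau_s0))
  cat(sprintf("  BFI    = %g cm^2/s\n", x$bfi))
  invisible(x)
}

#' @export
coef.decay_line <- function(object, ...) {
  c(slope = object$slope, tau_s0 = object$tau_s0, bfi = object$bfi)
}

#' @export
predict.decay_line <- function(object, tau_s, ...) {
  decay_rate_line(tau_s, object$bfi, object$optics, object$tau_s0)
}
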