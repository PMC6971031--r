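#' Time-domain diffusion reflectance for a semi-infinite medium
#'
#' Temporal point spread function (TPSF) of a semi-infinite homogeneous
#' turbid medium in the diffusion approximation, with the extrapolated
#' boundary condition. An isotropic point source is placed at depth
#' `z0 = 1/mu_s'` below the surface; the boundary is satisfied with a
#' negative image source mirrored about the extrapolated boundary plane at
#' `z = -z_b`, `z_b = 2 A D`, where `D = 1/(3 mu_s')` and the internal
#' reflection parameter `A` follows from the refractive index mismatch
#' (Groenhuis polynomial approximation to the internal diffuse reflectance).
#' The time-resolved reflectance at radial distance `rho` is
#' \deqn{R(\rho, t) = (4\pi D v)^{-3/2} t^{-5/2}
#'   e^{-\mu_a v t} e^{-\rho^2/(4 D v t)}
#'   \tfrac{1}{2}\left[z_0 e^{-z_0^2/(4 D v t)} +
#'   (z_0 + 2 z_b) e^{-(z_0+2z_b)^2/(4 D v t)}\right],}
#' with `v = c/n_r` the speed of light in the medium. The output is in
#' arbitrary units (analyses use shape only, with a free amplitude).
#'
#' @param tau_s time(s) of flight in ps, > 0.
#' @param rho source-detector separation in cm, >= 0.
#' @param optics an [optical_properties()].
#' @param A boundary reflection parameter override; by default computed
#'   from `n_r`. Use `A = 1` for an index-matched (non-reflecting) surface,
#'   e.g. when comparing with index-matched Monte Carlo.
#' @return reflectance values, strictly positive, same length as `tau_s`.
#' @examples
#' op <- optical_properties(0.045, 10, n_r = 1.33)
#' tpsf_semi_infinite(c(100, 500, 1000), rho = 0.76, optics = op)
#' @export
tpsf_semi_infinite <- function(tau_s, rho, optics, A = NULL) {
  stopifnot(inherits(optics, "inirs_optics"))
  if (any(tau_s <= 0)) stop("tau_s must be > 0")
  if (rho < 0) stop("rho must be >= 0")
  if (is.null(A)) A <- internal_reflection_A(optics$n_r)
  t <- tau_s / PS_PER_S
  v <- C_VACUUM_CM_S / optics$n_r
  D <- 1 / (3 * optics$mu_sp)
  z0 <- 1 / optics$mu_sp
  zb <- 2 * A * D
  s <- 4 * D * v * t
  (4 * pi * D * v)^(-3 / 2) * t^(-5 / 2) *
    exp(-optics$mu_a * v * t) * exp(-rho^2 / s) *
    0.5 * (z0 * exp(-z0^2 / s) + (z0 + 2 * zb) * exp(-(z0 + 2 * zb)^2 / s))
}

## Internal reflection parameter A = (1 + r_d) / (1 - r_d) with the
## Groenhuis polynomial for the internal diffuse reflectance r_d(n).
internal_reflection_A <- function(n_r) {
  if (n_r == 1) return(1)
  r_d <- -1.440 / n_r^2 + 0.710 / n_r + 0.668 + 0.0636 * n_r
  (1 + r_d) / (1 - r_d)
}
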