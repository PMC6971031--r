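#' @keywords internal
#' @useDynLib inirs, .registration = TRUE
#' @importFrom Rcpp evalCpp
"_PACKAGE"

## Centralized physical constants and unit conversions.
## Internal convention: lengths in cm, times in s, rates in 1/s.
## Public interfaces use the field's customary units: TOF in ps,
## wavelengths in nm, optical coefficients in 1/cm, BFI in cm^2/s,
## displacements in um.

#' Physical constants used throughout the package
#'
#' Speed of light in vacuum, in cm/s. Exposed so that analyses and tests use
#' one agreed value.
#' @export
C_VACUUM_CM_S <- 2.99792458e10

PS_PER_S <- 1e12

#' Convert a time of flight to photon path length
#'
#' Path length is `L = c * tau_s / n_r`.
#'
#' @param tau_s_ps time of flight in picoseconds.
#' @param n_r refractive index of the medium (1 for vacuum).
#' @return path length in cm.
#' @export
tof_to_pathlength <- function(tau_s_ps, n_r = 1) {
  C_VACUUM_CM_S * (tau_s_ps / PS_PER_S) / n_r
}

## nm -> cm
nm_to_cm <- function(x) x * 1e-7

## medium wavenumber k = 2 pi n_r / lambda0, in 1/cm
wavenumber <- function(lambda0_nm, n_r) {
  2 * pi * n_r / nm_to_cm(lambda0_nm)
}
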