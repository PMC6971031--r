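#' Collapse a TOF-resolved autocorrelation to a DCS-style autocorrelation
#'
#' TOF integration `G1_DCS(tau_d) = sum_tau_s G1(tau_s, tau_d) dtau_s` —
#' what a classical DWS/DCS measurement sees. Besides the full surface, a
#' fitted component surface can be integrated instead, to isolate the fast
#' dynamic component or the early-lag single-exponential description:
#' \describe{
#'   \item{full}{the measured `G1` surface.}
#'   \item{fast_component}{`I_fast(tau_s) exp(-xi_fast(tau_s) tau_d)` from
#'     order-5 fits (order-3 fits contribute their single dynamic
#'     component).}
#'   \item{slow_component}{likewise for the slow component.}
#'   \item{static}{the static amplitude, constant in lag.}
#'   \item{early_lag_fit}{`I_f(tau_s) exp(-xi(tau_s) tau_d)` from early-lag
#'     order-3 fits (pass fits produced by [early_lag_fit()]).}
#' }
#'
#' @param g1 a `tof_g1` (TOF grid must be uniform).
#' @param provenance one of `"full"`, `"fast_component"`,
#'   `"slow_component"`, `"static"`, `"early_lag_fit"`.
#' @param fits a `decay_fit_list` on the same TOF bins; required for any
#'   provenance other than `"full"`.
#' @return an object of class `dcs_g1` with `tau_d`, `values`,
#'   `provenance`, and the TOF spacing used.
#' @export
integrate_tof <- function(g1, provenance = c("full", "fast_component",
                                             "slow_component", "static",
                                             "early_lag_fit"),
                          fits = NULL) {
  stopifnot(inherits(g1, "tof_g1"))
  provenance <- match.arg(provenance)
  dts <- unique(round(diff(g1$tof_ps), 9))
  if (length(dts) != 1L) stop("TOF grid must be uniform")
  if (provenance == "full") {
    vals <- colSums(g1$G1, na.rm = TRUE) * dts
  } else {
    if (is.null(fits)) stop("fits are required for component provenances")
    surf <- component_surface(fits, g1$tau_d, provenance)
    vals <- colSums(surf, na.rm = TRUE) * dts
  }
  structure(list(tau_d = g1$tau_d, values = vals, provenance = provenance,
                 dtau_s_ps = dts),
            class = "dcs_g1")
}

## matrix [fit bins x lags] of the selected fitted component
component_surface <- function(fits, tau_d, provenance) {
  rows <- lapply(fits, function(f) {
    if (!f$converged) return(rep(NA_real_, length(tau_d)))
    co <- f$coefficients
    if (provenance == "static") {
      rep(if ("I_c" %in% names(co)) co[["I_c"]] else 0, length(tau_d))
    } else if (provenance == "slow_component") {
      if (f$order == 5) co[["I_slow"]] * exp(-co[["xi_slow"]] * tau_d)
      else rep(0, length(tau_d))
    } else { # fast_component / early_lag_fit
      if (f$order == 5) {
        co[["I_fast"]] * exp(-co[["xi_fast"]] * tau_d)
      } else if ("I_f" %in% names(co)) {
        co[["I_f"]] * exp(-co[["xi"]] * tau_d)
      } else {
        exp(-co[["xi"]] * tau_d)
      }
    }
  })
  do.call(rbind, rows)
}

#' Amplitude profile of a fitted component across TOF bins
#'
#' @param fits a `decay_fit_list`.
#' @param provenance `"fast_component"`, `"slow_component"`, `"static"`, or
#'   `"early_lag_fit"` (the dynamic amplitude of order-2/3 fits).
#' @return amplitude per fit (NA where unavailable).
#' @export
component_amplitude <- function(fits, provenance) {
  vapply(fits, function(f) {
    if (!f$converged) return(NA_real_)
    co <- f$coefficients
    switch(provenance,
      static = if ("I_c" %in% names(co)) co[["I_c"]] else 0,
      slow_component = if (f$order == 5) co[["I_slow"]] else 0,
      if (f$order == 5) co[["I_fast"]]
      else if ("I_f" %in% names(co)) co[["I_f"]]
      else NA_real_)
  }, numeric(1))
}

#' @export
print.dcs_g1 <- function(x, ...) {
  cat(sprintf("DCS-style autocorrelation (%s): %d lags, G1(0) = %.4g\n",
              x$provenance, length(x$tau_d), x$values[1]))
  invisible(x)
}

#' Fit DWS/DCS theory to a TOF-integrated autocorrelation
#'
#' Least squares of the TPSF-weighted DWS kernel
#' \deqn{g_1^{DCS}(\tau_d; BFI) = A\,
#'   \frac{\sum_{\tau_s} I(\tau_s) e^{-\xi(\tau_s; BFI)\tau_d}}
#'        {\sum_{\tau_s} I(\tau_s)},}
#' with the Brownian decay-rate line `xi(tau_s; BFI)` through the origin
#' (`tau_s0 = 0`), against the normalized autocorrelation
#' `G1_DCS/G1_DCS(0)` over a lag region. The amplitude `A` is free within
#' [0.9, 1.1]. Because the kernel weights by the TOF distribution, the
#' result depends on the assumed optical properties — including absorption
#' through the TPSF — unlike TOF-resolved BFI estimation.
#'
#' @param dcs a `dcs_g1` from [integrate_tof()].
#' @param tof_ps,tpsf the TOF distribution used as the kernel weight
#'   (measured or modeled TPSF on a uniform grid).
#' @param optics an [optical_properties()].
#' @param fit_region `c(lo, hi)` lag range in s.
#' @return an object of class `dcs_fit` with `bfi`, `amp`, `adj_r2`,
#'   `fit_region`, and the fitted data.
#' @export
fit_dcs <- function(dcs, tof_ps, tpsf, optics,
                    fit_region = c(0, max(dcs$tau_d))) {
  stopifnot(inherits(dcs, "dcs_g1"), inherits(optics, "inirs_optics"),
            length(tof_ps) == length(tpsf))
  sel <- which(dcs$tau_d >= fit_region[1] & dcs$tau_d <= fit_region[2])
  if (length(sel) < 5) stop("fit region too narrow")
  td <- dcs$tau_d[sel]
  y <- dcs$values[sel] / dcs$values[1]
  w <- tpsf / sum(tpsf)
  kernel <- function(bfi, td) {
    xi <- decay_rate_line(tof_ps, bfi, optics, tau_s0 = 0)
    as.vector(w %*% exp(-outer(xi, td)))
  }
  ## initial BFI from the mean decay time of the data
  i_e <- which(y < y[1] * exp(-1))[1]
  xi0 <- if (is.na(i_e)) 1 / max(td) else 1 / td[i_e]
  mean_tof <- sum(w * tof_ps)
  bfi0 <- max(xi0 / decay_rate_line(mean_tof, 1, optics, 0), 1e-12)
  fit <- minpack.lm::nls.lm(
    par = c(log_bfi = log(bfi0), amp = 1),
    lower = c(-60, 0.9), upper = c(0, 1.1),
    fn = function(p) y - p[2] * kernel(exp(p[1]), td),
    control = minpack.lm::nls.lm.control(maxiter = 200))
  bfi <- exp(unname(fit$par[1]))
  fitted_y <- unname(fit$par[2]) * kernel(bfi, td)
  structure(
    list(bfi = bfi, amp = unname(fit$par[2]),
         adj_r2 = adjusted_r2(y, fitted_y, 2),
         converged = fit$info %in% 1:4,
         fit_region = fit_region, tau_d = td, y = y, fitted = fitted_y,
         provenance = dcs$provenance),
    class = "dcs_fit")
}

#' @export
print.dcs_fit <- function(x, ...) {
  cat(sprintf(
    "DCS fit (%s, lags %.2g-%.2g ms): BFI = %.4g cm^2/s, adj R^2 = %.4f\n",
    x$provenance, x$fit_region[1] * 1e3, x$fit_region[2] * 1e3,
    x$bfi, x$adj_r2))
  invisible(x)
}

#' @export
coef.dcs_fit <- function(object, ...) {
  c(bfi = object$bfi, amp = object$amp)
}

#' Compare DCS blood flow indices across provenances and fit regions
#'
#' Reproduces the DWS/DCS deconstruction: the BFI fitted to the full
#' TOF-integrated autocorrelation depends on the lag fit region (the slow
#' component contaminates late lags), while the BFI from integrating only
#' the fast component, or the early-lag single-exponential fits, is
#' fit-region independent.
#'
#' @param g1 a `tof_g1`.
#' @param fits a `decay_fit_list` used for the component surfaces.
#' @param early_fits optional `decay_fit_list` from early-lag fitting, used
#'   for the `early_lag_fit` provenance (defaults to `fits`).
#' @param tof_ps,tpsf kernel TOF distribution as in [fit_dcs()].
#' @param optics an [optical_properties()].
#' @param fit_regions a list of `c(lo, hi)` lag ranges in s.
#' @return a data frame with one row per provenance x fit region:
#'   `provenance`, `region_lo`, `region_hi`, `bfi`, `adj_r2`.
#' @export
deconstruction_report <- function(g1, fits, early_fits = NULL,
                                  tof_ps, tpsf, optics,
                                  fit_regions = list(c(0, 2.5e-3),
                                                     c(0, 10e-3))) {
  if (is.null(early_fits)) early_fits <- fits
  provs <- c("full", "fast_component", "slow_component", "early_lag_fit")
  rows <- list()
  for (pv in provs) {
    pv_fits <- if (pv == "early_lag_fit") early_fits else fits
    dcs <- integrate_tof(g1, pv, fits = pv_fits)
    ## kernel weight: the TOF distribution of the signal actually
    ## integrated — the full TPSF for the full surface, the component's own
    ## amplitude profile otherwise
    if (pv == "full") {
      w_tof <- tof_ps; w_int <- tpsf
    } else {
      w_tof <- vapply(pv_fits, `[[`, numeric(1), "tau_s")
      w_int <- component_amplitude(pv_fits, pv)
      keep <- !is.na(w_int) & w_int > 0
      w_tof <- w_tof[keep]; w_int <- w_int[keep]
    }
    for (fr in fit_regions) {
      row <- tryCatch({
        f <- fit_dcs(dcs, w_tof, w_int, optics, fit_region = fr)
        data.frame(provenance = pv, region_lo = fr[1], region_hi = fr[2],
                   bfi = f$bfi, adj_r2 = f$adj_r2)
      }, error = function(e) {
        data.frame(provenance = pv, region_lo = fr[1], region_hi = fr[2],
                   bfi = NA_real_, adj_r2 = NA_real_)
      })
      rows[[length(rows) + 1L]] <- row
    }
  }
  do.call(rbind, rows)
}
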