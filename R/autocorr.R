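#' TOF-resolved field autocorrelation container
#'
#' Shared container produced by [estimate_g1()] (from measured/synthesized
#' coherence series) and [autocorrelation_from_paths()] (from Monte Carlo
#' ensembles): the autocorrelation surface `G1[tof, lag]` in intensity
#' units, the TPSF (`G1` at lag 0), and averaging metadata.
#'
#' @name tof_g1
NULL

#' @export
print.tof_g1 <- function(x, ...) {
  cat(sprintf(
    "TOF-resolved G1: %d TOF bins x %d lags (to %.3g ms)%s\n",
    length(x$tof_ps), length(x$tau_d), max(x$tau_d) * 1e3,
    if (!is.null(x$averaging)) {
      sprintf(", %.0f%% TOF averaging", 100 * x$averaging$fraction)
    } else ""))
  invisible(x)
}

#' Estimate the TOF-resolved field autocorrelation
#'
#' Per TOF bin, the biased (divide-by-N) sample autocovariance
#' `G1(tau_s, tau_d) = <Gamma*(t) Gamma(t + tau_d)>` over the full block,
#' without mean subtraction (the static field component is part of the
#' signal and is modeled explicitly by the fit). After motion correction the
#' intrinsic autocorrelation is real for unbiased dynamics, so with
#' `take_real = TRUE` the real part is the estimate and the imaginary part
#' is retained for diagnostics.
#'
#' @param series a [coherence_series()].
#' @param tau_d_max maximum lag in s (default 10 ms, the standard fitting
#'   window). A warning is issued beyond a tenth of the block duration.
#' @param take_real return `Re(G1)` (appropriate after motion correction).
#' @return an object of class `tof_g1` with fields `tof_ps`, `tau_d`, `G1`,
#'   `tpsf` (mean intensity per bin), and `im_g1` (imaginary part) when
#'   `take_real`.
#' @export
estimate_g1 <- function(series, tau_d_max = 10e-3, take_real = TRUE) {
  stopifnot(inherits(series, "coherence_series"))
  dt <- series$dt
  n <- ncol(series$gamma)
  if (tau_d_max > n * dt / 10) {
    warning("tau_d_max exceeds a tenth of the block; estimator variance high")
  }
  n_lags <- min(n - 1L, floor(tau_d_max / dt)) + 1L
  nb <- nrow(series$gamma)
  G1c <- matrix(0+0i, nb, n_lags)
  for (b in seq_len(nb)) {
    G1c[b, ] <- autocov_fft(series$gamma[b, ], n_lags)
  }
  tpsf <- rowMeans(Mod(series$gamma)^2)
  out <- list(tof_ps = series$tof_ps, tau_d = (0:(n_lags - 1L)) * dt,
              tpsf = tpsf, n_paths = NULL, source = "series",
              seed = series$seed, averaging = NULL)
  if (take_real) {
    out$G1 <- Re(G1c)
    out$im_g1 <- Im(G1c)
  } else {
    out$G1 <- G1c
  }
  structure(out, class = "tof_g1")
}

## biased complex autocovariance via FFT, lags 0..n_lags-1 (no mean removal)
autocov_fft <- function(x, n_lags) {
  n <- length(x)
  m <- stats::nextn(n + n_lags, 2)
  xf <- stats::fft(c(x, rep(0+0i, m - n)))
  r <- stats::fft(Conj(xf) * xf, inverse = TRUE) / m
  r[seq_len(n_lags)] / n
}

#' Estimate the TOF-resolved intensity autocorrelation
#'
#' `G2(tau_s, tau_d) = <I(t) I(t + tau_d)>` with `I = |Gamma|^2`, biased
#' estimator, no mean subtraction. Note that for an exponential field
#' autocorrelation the intensity autocorrelation decays twice as fast, so a
#' field lag resolution of 10 us is equivalent to a 5 us intensity lag
#' resolution.
#'
#' @inheritParams estimate_g1
#' @return an object of class `tof_g2` with `tof_ps`, `tau_d`, `G2`, and
#'   `Ibar` (mean intensity per bin).
#' @export
estimate_g2 <- function(series, tau_d_max = 10e-3) {
  stopifnot(inherits(series, "coherence_series"))
  dt <- series$dt
  n <- ncol(series$gamma)
  n_lags <- min(n - 1L, floor(tau_d_max / dt)) + 1L
  nb <- nrow(series$gamma)
  G2 <- matrix(0, nb, n_lags)
  for (b in seq_len(nb)) {
    I <- Mod(series$gamma[b, ])^2
    G2[b, ] <- Re(autocov_fft(complex(real = I), n_lags))
  }
  structure(
    list(tof_ps = series$tof_ps, tau_d = (0:(n_lags - 1L)) * dt, G2 = G2,
         Ibar = rowMeans(Mod(series$gamma)^2)),
    class = "tof_g2"
  )
}

#' Intensity autocorrelation predicted from the field autocorrelation
#'
#' Heterodyne (modified) Siegert relation for a Gaussian dynamic field plus
#' a static component: writing `G1(tau) = I_c + C(tau)` with `I_c` the
#' static intensity and `C` the dynamic field autocovariance,
#' \deqn{G_2(\tau) = \bar I^2 + \beta\left(|C(\tau)|^2 +
#'   2 I_c \,\mathrm{Re}\, C(\tau)\right), \qquad \bar I = I_c + C(0).}
#' For a fully dynamic field (`I_c = 0`) this reduces to the classical
#' Siegert relation `g2 = 1 + beta |g1|^2`.
#'
#' @param G1 field autocorrelation values at the lags of interest (lag 0
#'   first), in intensity units.
#' @param I_c static component intensity (same units), default 0.
#' @param beta coherence factor in (0, 1], default 1 (single-mode
#'   synthesis).
#' @return predicted intensity autocorrelation at the same lags.
#' @export
siegert_predict <- function(G1, I_c = 0, beta = 1) {
  C <- G1 - I_c
  Ibar <- I_c + Re(C[1])
  Ibar^2 + beta * (Mod(C)^2 + 2 * I_c * Re(C))
}

#' TOF-dependent averaging of the autocorrelation surface
#'
#' At each TOF `tau_s`, replaces `G1(tau_s, .)` by its mean over the TOF
#' bins whose centers lie in `[tau_s (1 - fraction/2), tau_s (1 + fraction/2)]`
#' (a 20% window at 1000 ps averages 900-1100 ps). Window endpoints are
#' clipped to the grid; the number of bins averaged is recorded.
#'
#' @param g1 a `tof_g1`.
#' @param fraction relative window width in [0, 1); 0 is the identity.
#' @return a `tof_g1` with averaged `G1` and `tpsf` and an `averaging`
#'   metadata field (`fraction`, `n_samples` per bin).
#' @export
tof_dependent_average <- function(g1, fraction = 0.2) {
  stopifnot(inherits(g1, "tof_g1"))
  if (fraction < 0 || fraction >= 1) stop("fraction must lie in [0, 1)")
  if (fraction == 0) return(g1)
  out <- g1
  n_samples <- integer(length(g1$tof_ps))
  for (i in seq_along(g1$tof_ps)) {
    ts <- g1$tof_ps[i]
    sel <- which(g1$tof_ps >= ts * (1 - fraction / 2) &
                 g1$tof_ps <= ts * (1 + fraction / 2))
    n_samples[i] <- length(sel)
    out$G1[i, ] <- colMeans(g1$G1[sel, , drop = FALSE], na.rm = TRUE)
    out$tpsf[i] <- mean(g1$tpsf[sel], na.rm = TRUE)
  }
  out$averaging <- list(fraction = fraction, n_samples = n_samples)
  out
}

#' Block-bootstrap standard errors for an autocorrelation slice
#'
#' Splits the delay-time series into contiguous blocks (default 50 ms),
#' computes the biased autocorrelation per block, and bootstraps the mean
#' over blocks (default 200 resamples). Returns the bootstrap standard
#' error per lag; quantile-based 95% intervals are also provided.
#'
#' @param series a [coherence_series()].
#' @param tof_select as in [window_autocorrelation()].
#' @param tau_d_max maximum lag in s.
#' @param n_boot number of bootstrap resamples.
#' @param block block length in s.
#' @param take_real operate on the real part (post-correction contract).
#' @param seed seed for the resampling.
#' @return a list with `tau_d`, `mean`, `se`, `lo`, `hi`.
#' @export
bootstrap_g1_ci <- function(series, tof_select = "peak", tau_d_max = 10e-3,
                            n_boot = 200, block = 50e-3, take_real = TRUE,
                            seed = 1) {
  stopifnot(inherits(series, "coherence_series"))
  dt <- series$dt
  x <- select_trace(series, tof_select)
  nb <- floor(block / dt)
  n_lags <- floor(tau_d_max / dt) + 1L
  nblocks <- floor(length(x) / nb)
  if (nblocks < 2) stop("block too long for the data")
  per_block <- vapply(seq_len(nblocks), function(i) {
    r <- autocov_fft(x[((i - 1) * nb + 1):(i * nb)], n_lags)
    if (take_real) Re(r) else Mod(r)
  }, numeric(n_lags))
  set.seed(as.integer(seed))
  boots <- vapply(seq_len(n_boot), function(i) {
    rowMeans(per_block[, sample.int(nblocks, replace = TRUE), drop = FALSE])
  }, numeric(n_lags))
  list(tau_d = (0:(n_lags - 1L)) * dt,
       mean = rowMeans(per_block),
       se = apply(boots, 1, stats::sd),
       lo = apply(boots, 1, stats::quantile, probs = 0.025),
       hi = apply(boots, 1, stats::quantile, probs = 0.975))
}
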