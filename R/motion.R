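#' Short-window complex autocorrelation of a coherence series
#'
#' Biased (normalized-by-N) sample autocorrelation of a selected complex
#' trace over a short window centered at `center_t`. The trace is the
#' peak-TOF bin (TOF of the TPSF maximum), the TOF-integrated series (sum of
#' `Gamma` over TOF before correlating), or an explicit TOF bin. Used as the
#' input to Doppler frequency estimation: for rigid axial motion the
#' windowed autocorrelation rotates in the complex plane at the bulk Doppler
#' frequency.
#'
#' @param series a [coherence_series()].
#' @param center_t window center in s.
#' @param window window length in s (default 2 ms); must be at least 10
#'   delay-time samples.
#' @param tof_select `"peak"`, `"tof_integrated"`, or a numeric TOF in ps
#'   (nearest bin is used).
#' @param n_lags number of lags to return (default: half the window).
#' @return complex autocorrelation values at lags `0:(n_lags-1)` times the
#'   delay-time resolution, with attributes `dt` and `lags`.
#' @export
window_autocorrelation <- function(series, center_t, window = 2e-3,
                                   tof_select = "peak", n_lags = NULL) {
  stopifnot(inherits(series, "coherence_series"))
  dt <- series$dt
  if (window < 10 * dt) stop("window must span at least 10 samples")
  trace <- select_trace(series, tof_select)
  nw <- round(window / dt)
  i0 <- round(center_t / dt) + 1L - nw %/% 2L
  if (i0 < 1L || i0 + nw - 1L > length(trace)) {
    stop("window exceeds the data extent")
  }
  x <- trace[i0:(i0 + nw - 1L)]
  if (is.null(n_lags)) n_lags <- nw %/% 2L
  acf_biased_complex(x, n_lags, dt)
}

select_trace <- function(series, tof_select) {
  if (identical(tof_select, "peak")) {
    tpsf <- rowMeans(Mod(series$gamma)^2)
    series$gamma[which.max(tpsf), ]
  } else if (identical(tof_select, "tof_integrated")) {
    colSums(series$gamma)
  } else if (is.numeric(tof_select)) {
    series$gamma[which.min(abs(series$tof_ps - tof_select)), ]
  } else {
    stop("tof_select must be 'peak', 'tof_integrated', or a TOF in ps")
  }
}

## biased complex sample autocorrelation at lags 0..n_lags-1
acf_biased_complex <- function(x, n_lags, dt) {
  n <- length(x)
  n_lags <- min(n_lags, n - 1L)
  out <- vapply(0:(n_lags - 1L), function(m) {
    sum(Conj(x[1:(n - m)]) * x[(1 + m):n]) / n
  }, complex(1))
  attr(out, "dt") <- dt
  attr(out, "lags") <- (0:(n_lags - 1L)) * dt
  out
}

#' Doppler frequency from a windowed autocorrelation
#'
#' The bulk Doppler frequency is located at the maximum of the power
#' spectrum of the complex windowed autocorrelation, computed with 8x
#' zero padding and refined by parabolic interpolation on log power.
#' Bounded by the Nyquist frequency `1/(2 dt)`. Ties at the peak resolve to
#' the lower |frequency|.
#'
#' @param g1w complex autocorrelation from [window_autocorrelation()].
#' @param dt lag resolution in s (taken from `g1w`'s attribute if absent).
#' @return estimated Doppler shift in Hz (NA for an all-zero input, with a
#'   warning).
#' @export
doppler_estimate <- function(g1w, dt = attr(g1w, "dt")) {
  if (length(g1w) < 8) stop("need at least 8 lags")
  if (all(Mod(g1w) == 0)) {
    warning("all-zero autocorrelation; Doppler undefined")
    return(NA_real_)
  }
  nfft <- 8L * 2^ceiling(log2(length(g1w)))
  sp <- Mod(stats::fft(c(unclass(g1w), rep(0+0i, nfft - length(g1w)))))^2
  freqs <- (seq_len(nfft) - 1L) / (nfft * dt)
  freqs[freqs >= 1 / (2 * dt)] <- freqs[freqs >= 1 / (2 * dt)] - 1 / dt
  ## ties: prefer lower |frequency|
  pk <- which(sp == max(sp))
  if (length(pk) > 1L) pk <- pk[which.min(abs(freqs[pk]))]
  ## parabolic interpolation on log power around the peak (circular index)
  im <- ((pk - 2L) %% nfft) + 1L
  ip <- (pk %% nfft) + 1L
  lp <- log(pmax(sp[c(im, pk, ip)], .Machine$double.xmin))
  denom <- lp[1] - 2 * lp[2] + lp[3]
  delta <- if (denom != 0) 0.5 * (lp[1] - lp[3]) / denom else 0
  delta <- max(-0.5, min(0.5, delta))
  f <- freqs[pk] + delta / (nfft * dt)
  max(-1 / (2 * dt), min(1 / (2 * dt), f))
}

#' Sliding-window Doppler frequency track
#'
#' Applies [window_autocorrelation()] + [doppler_estimate()] on a sliding
#' window (default 2 ms window, 1 ms hop giving 50% overlap) across the
#' whole block.
#'
#' @inheritParams window_autocorrelation
#' @param hop hop between window centers in s.
#' @return a data frame with columns `t` (window center, s) and `df` (Hz).
#' @export
doppler_track <- function(series, window = 2e-3, hop = 1e-3,
                          tof_select = "peak") {
  stopifnot(inherits(series, "coherence_series"))
  dt <- series$dt
  trace <- select_trace(series, tof_select)
  nw <- round(window / dt)
  centers <- seq((nw %/% 2) * dt, max(series$t_d) - (nw %/% 2) * dt, by = hop)
  n_lags <- nw %/% 2L
  df <- vapply(centers, function(ct) {
    i0 <- round(ct / dt) + 1L - nw %/% 2L
    x <- trace[i0:(i0 + nw - 1L)]
    doppler_estimate(acf_biased_complex(x, n_lags, dt), dt)
  }, numeric(1))
  data.frame(t = centers, df = df)
}

#' Cumulative bulk phase from a Doppler track
#'
#' Interpolates the per-window Doppler frequencies onto the delay-time grid,
#' converts to per-sample phase increments `2 pi df dt`, and accumulates to
#' a continuous unwrapped phase with `theta(0) = 0`.
#'
#' @param track data frame from [doppler_track()] (must be contiguous: no
#'   `NA` frequencies).
#' @param t_d delay-time grid (s) onto which to accumulate.
#' @return cumulative phase in rad on `t_d`.
#' @export
cumulative_phase <- function(track, t_d) {
  if (anyNA(track$df)) stop("Doppler track contains gaps")
  dt <- t_d[2] - t_d[1]
  f <- stats::approx(track$t, track$df, xout = t_d, rule = 2)$y
  theta <- cumsum(2 * pi * f * dt)
  theta - theta[1]
}

#' Remove bulk-motion phase from a coherence series
#'
#' Multiplies every TOF bin by `exp(-i theta(t_d))` — the bulk phase is
#' common to all TOFs for rigid axial motion.
#'
#' @param series a [coherence_series()].
#' @param theta phase in rad on the series' delay-time grid.
#' @return the corrected `coherence_series`.
#' @export
correct_motion <- function(series, theta) {
  stopifnot(inherits(series, "coherence_series"),
            length(theta) == ncol(series$gamma))
  out <- series
  out$gamma <- sweep(series$gamma, 2, exp(-1i * theta), `*`)
  out
}

#' Estimate and correct bulk motion in one step
#'
#' Convenience wrapper: Doppler track, cumulative phase, correction.
#'
#' @inheritParams doppler_track
#' @return a list with `series` (corrected), `track`, and `theta`.
#' @export
estimate_and_correct <- function(series, window = 2e-3, hop = 1e-3,
                                 tof_select = "peak") {
  track <- doppler_track(series, window, hop, tof_select)
  theta <- cumulative_phase(track, series$t_d)
  list(series = correct_motion(series, theta), track = track, theta = theta)
}

#' Convert bulk phase to axial displacement, and Doppler shift to velocity
#'
#' `Z = theta lambda0 / (4 pi)` (um) and `dV = df lambda0 / 2` (um/s).
#'
#' @param theta cumulative phase in rad.
#' @param lambda0 wavelength in nm.
#' @return displacement in um.
#' @export
phase_to_displacement <- function(theta, lambda0 = 855) {
  theta * (lambda0 * 1e-3) / (4 * pi)
}

#' @rdname phase_to_displacement
#' @param df Doppler frequency shift in Hz.
#' @return `doppler_velocity()`: velocity in um/s.
#' @export
doppler_velocity <- function(df, lambda0 = 855) {
  df * (lambda0 * 1e-3) / 2
}
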