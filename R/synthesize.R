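#' Acquisition configuration
#'
#' Describes the swept-source acquisition: sweep (and hence delay-time
#' sampling) rate, block duration, TOF grid, wavelength, and the angle
#' between illumination and detection. The delay-time resolution is
#' `1 / sweep_rate` and the number of delay-time points is
#' `block_duration * sweep_rate`.
#'
#' @param sweep_rate laser sweep rate in Hz (default 1e5, i.e. a 10 us lag
#'   resolution).
#' @param block_duration acquisition block length in s (default 2.5, i.e.
#'   250,000 delay-time points at the default sweep rate).
#' @param tof_grid_ps uniform TOF grid for the synthesized bins, in ps.
#' @param lambda0 center wavelength in nm.
#' @param alpha_sd angle between illumination and detection in rad.
#' @return an object of class `acquisition_config`.
#' @export
acquisition_config <- function(sweep_rate = 1e5, block_duration = 2.5,
                               tof_grid_ps = seq(0, 990, by = 22),
                               lambda0 = 855, alpha_sd = 10 * pi / 180) {
  n <- round(block_duration * sweep_rate)
  structure(
    list(sweep_rate = sweep_rate, dt = 1 / sweep_rate,
         block_duration = block_duration, n_time_points = n,
         tof_grid_ps = tof_grid_ps, lambda0 = lambda0, alpha_sd = alpha_sd),
    class = "acquisition_config"
  )
}

#' @export
print.acquisition_config <- function(x, ...) {
  cat(sprintf(
    "Acquisition: %g kHz sweep, %g s block (%d points), %d TOF bins, %g nm\n",
    x$sweep_rate / 1e3, x$block_duration, x$n_time_points,
    length(x$tof_grid_ps), x$lambda0))
  invisible(x)
}

#' Per-TOF-bin component amplitudes and decay rates
#'
#' Ground-truth decomposition of the field at each TOF bin into a static
#' component and up to two exponentially decorrelating dynamic components
#' (slow and fast), in TPSF (intensity) units. This is the constant plus
#' bi-exponential structure used for model fitting.
#'
#' @param tof_ps TOF bin centers in ps.
#' @param I_static,I_slow,I_fast component intensities per bin, >= 0
#'   (recycled if scalar).
#' @param xi_slow,xi_fast decay rates per bin in 1/s, >= 0.
#' @return an object of class `component_spec`.
#' @export
component_spec <- function(tof_ps, I_static = 0, I_slow = 0, xi_slow = 0,
                           I_fast = 0, xi_fast = 0) {
  n <- length(tof_ps)
  rec <- function(x) {
    x <- rep_len(x, n)
    if (any(x < 0)) stop("amplitudes and rates must be >= 0")
    x
  }
  structure(
    list(tof_ps = tof_ps, I_static = rec(I_static),
         I_slow = rec(I_slow), xi_slow = rec(xi_slow),
         I_fast = rec(I_fast), xi_fast = rec(xi_fast)),
    class = "component_spec"
  )
}

#' Total intensity (TPSF) of a component specification
#' @param components a [component_spec()].
#' @return per-bin total intensity.
#' @export
component_tpsf <- function(components) {
  components$I_static + components$I_slow + components$I_fast
}

#' Synthesize a bulk-motion trace
#'
#' The axial velocity follows a random walk: at each delay-time step the
#' velocity changes by a zero-mean Gaussian increment of standard deviation
#' `velocity_rw_std` (um/s). The per-step bulk Doppler phase increment is
#' \deqn{\Delta\theta = \frac{4\pi}{\lambda_0}
#'   \frac{\Delta z + \Delta z\cos\alpha_{SD} + \Delta x\sin\alpha_{SD}}{2},}
#' and the cumulative phase is its running sum. The equivalent Doppler
#' frequency is `df = dtheta/dt / (2 pi)` and the Doppler velocity
#' `dV = df * lambda0 / 2`.
#'
#' @param config an [acquisition_config()].
#' @param velocity_rw_std per-step standard deviation of the axial velocity
#'   increments, um/s (default 0.2, giving ~100 um/s RMS axial speeds by the
#'   end of a 2.5 s block).
#' @param lateral_rw_std same for the lateral velocity (default 0: purely
#'   axial motion).
#' @param seed integer seed.
#' @return an object of class `motion_trace`: `t_d` (s), `dz`, `dx`
#'   (per-step displacements, um), `z` (cumulative axial displacement, um),
#'   `theta` (cumulative bulk phase, rad, `theta[1] = 0`), `df` (Hz), `dV`
#'   (um/s).
#' @export
synthesize_motion <- function(config, velocity_rw_std = 0.2,
                              lateral_rw_std = 0, seed = 1) {
  stopifnot(inherits(config, "acquisition_config"))
  if (velocity_rw_std < 0 || lateral_rw_std < 0) {
    stop("velocity standard deviations must be >= 0")
  }
  n <- config$n_time_points
  set.seed(as.integer(seed))
  vz <- cumsum(stats::rnorm(n, 0, velocity_rw_std))       # um/s
  vx <- if (lateral_rw_std > 0) {
    cumsum(stats::rnorm(n, 0, lateral_rw_std))
  } else rep(0, n)
  dz <- vz * config$dt                                     # um per step
  dx <- vx * config$dt
  lam_um <- config$lambda0 * 1e-3
  dtheta <- (4 * pi / lam_um) *
    (dz + dz * cos(config$alpha_sd) + dx * sin(config$alpha_sd)) / 2
  theta <- cumsum(dtheta)
  theta <- theta - theta[1]                                # theta(0) = 0
  df <- dtheta / (2 * pi * config$dt)
  structure(
    list(t_d = (seq_len(n) - 1) * config$dt, dz = dz, dx = dx,
         z = cumsum(dz), theta = theta, df = df,
         dV = df * lam_um / 2, config = config, seed = seed),
    class = "motion_trace"
  )
}

#' @export
print.motion_trace <- function(x, ...) {
  cat(sprintf(
    "Motion trace over %.3g s: axial range %.2f um, |Doppler| up to %.0f Hz\n",
    max(x$t_d), diff(range(x$z)), max(abs(x$df))))
  invisible(x)
}

#' Synthesize a mutual coherence function time series
#'
#' Builds, per TOF bin,
#' `Gamma(tau_s, t_d) = exp(i theta(t_d)) * (sqrt(I_c) exp(i phi_c)
#'   + sqrt(I_slow) u_slow + sqrt(I_fast) u_fast) + noise`,
#' where each `u` is a unit-variance circular complex AR(1) process with
#' autocorrelation `exp(-xi tau_d)` (exact discretization of an
#' Ornstein-Uhlenbeck process, i.e. Gaussian speckle statistics), `phi_c` a
#' fixed random phase per bin, `theta` the common bulk-motion phase, and the
#' noise circular complex white with variance set by the target peak
#' signal-to-noise ratio. The ensemble field autocorrelation of the
#' motion-free part is `I_c + I_slow exp(-xi_slow tau_d) +
#' I_fast exp(-xi_fast tau_d)` by construction.
#'
#' Components are mutually independent between and within bins; per-bin
#' random substreams are derived deterministically from the master seed, so
#' the same seed yields the same underlying component processes whether or
#' not motion or noise is applied.
#'
#' @param components a [component_spec()] on the config's TOF grid.
#' @param config an [acquisition_config()].
#' @param motion a [synthesize_motion()] trace, or `NULL` for a motion-free
#'   series.
#' @param snr_db peak signal-to-noise ratio in dB (noise variance =
#'   max TPSF / 10^(snr_db/10)); `Inf` for noise-free.
#' @param seed master integer seed.
#' @return an object of class `coherence_series`: `tof_ps`, `t_d`, complex
#'   matrix `gamma` (TOF bins x delay times), and metadata (`lambda0`,
#'   `alpha_sd`, `dt`, `seed`).
#' @export
synthesize_gamma <- function(components, config, motion = NULL,
                             snr_db = 40, seed = 1) {
  stopifnot(inherits(components, "component_spec"),
            inherits(config, "acquisition_config"))
  if (!identical(length(components$tof_ps), length(config$tof_grid_ps))) {
    stop("component spec and config TOF grids differ in length")
  }
  if (!is.null(motion)) {
    stopifnot(inherits(motion, "motion_trace"))
    if (length(motion$theta) != config$n_time_points) {
      stop("motion trace length does not match the acquisition config")
    }
  }
  n <- config$n_time_points
  nb <- length(components$tof_ps)
  gamma <- matrix(0+0i, nb, n)
  tpsf_peak <- max(component_tpsf(components))
  noise_var <- if (is.infinite(snr_db)) 0 else tpsf_peak / 10^(snr_db / 10)
  for (b in seq_len(nb)) {
    set.seed(as.integer((as.numeric(seed) * 1009 + b * 7919) %% .Machine$integer.max))
    g <- 0+0i
    if (components$I_static[b] > 0) {
      phi_c <- stats::runif(1, 0, 2 * pi)
      g <- g + sqrt(components$I_static[b]) * exp(1i * phi_c)
    }
    for (comp in c("slow", "fast")) {
      I <- components[[paste0("I_", comp)]][b]
      xi <- components[[paste0("xi_", comp)]][b]
      if (I > 0) {
        g <- g + sqrt(I) * complex_ar1(n, xi, config$dt)
      }
    }
    if (noise_var > 0) {
      g <- g + sqrt(noise_var / 2) *
        complex(real = stats::rnorm(n), imaginary = stats::rnorm(n))
    }
    gamma[b, ] <- g
  }
  if (!is.null(motion)) {
    rot <- exp(1i * motion$theta)
    gamma <- sweep(gamma, 2, rot, `*`)
  }
  coherence_series(
    tof_ps = components$tof_ps,
    t_d = (seq_len(n) - 1) * config$dt,
    gamma = gamma,
    lambda0 = config$lambda0, alpha_sd = config$alpha_sd, dt = config$dt,
    seed = seed
  )
}

## Unit-variance circular complex AR(1) with autocorrelation exp(-xi tau):
## u[k+1] = a u[k] + sqrt(1 - a^2) w[k], a = exp(-xi dt),
## w circular complex standard normal (variance 1 total).
complex_ar1 <- function(n, xi, dt) {
  a <- exp(-xi * dt)
  w <- complex(real = stats::rnorm(n, 0, sqrt(0.5)),
               imaginary = stats::rnorm(n, 0, sqrt(0.5)))
  if (a == 0) return(w)
  ## stationary start + recursive filter on real and imaginary parts
  innov <- sqrt(1 - a^2) * w
  innov[1] <- w[1]  # stationary initial draw (unit variance)
  re <- stats::filter(Re(innov), a, method = "recursive")
  im <- stats::filter(Im(innov), a, method = "recursive")
  complex(real = as.numeric(re), imaginary = as.numeric(im))
}

#' Mutual coherence function time series
#'
#' Raw container of the complex interference amplitude between sample and
#' reference fields, per TOF bin and delay time.
#'
#' @param tof_ps TOF grid in ps.
#' @param t_d delay-time grid in s (uniform).
#' @param gamma complex matrix, `length(tof_ps)` x `length(t_d)`.
#' @param lambda0 center wavelength (nm).
#' @param alpha_sd source-detector angle (rad).
#' @param dt delay-time resolution (s).
#' @param seed generating seed, if any.
#' @return an object of class `coherence_series`.
#' @export
coherence_series <- function(tof_ps, t_d, gamma, lambda0 = 855,
                             alpha_sd = 0, dt = NULL, seed = NULL) {
  stopifnot(is.matrix(gamma), nrow(gamma) == length(tof_ps),
            ncol(gamma) == length(t_d))
  if (is.null(dt)) dt <- t_d[2] - t_d[1]
  structure(
    list(tof_ps = tof_ps, t_d = t_d, gamma = gamma, lambda0 = lambda0,
         alpha_sd = alpha_sd, dt = dt, seed = seed),
    class = "coherence_series"
  )
}

#' @export
print.coherence_series <- function(x, ...) {
  cat(sprintf(
    "Mutual coherence series: %d TOF bins x %d delay times (%.3g s at %.3g us)\n",
    nrow(x$gamma), ncol(x$gamma), max(x$t_d), x$dt * 1e6))
  invisible(x)
}

#' Blur component profiles with the instrument response function
#'
#' Convolves the per-component amplitude profiles with the intensity IRF on
#' the TOF grid; the per-component decay rates are carried over by
#' amplitude-weighted interpolation (`xi_blur = conv(I * xi) / conv(I)`).
#' Total amplitude is conserved when the IRF support fits the grid.
#'
#' @param components a [component_spec()] on a uniform fine TOF grid.
#' @param irf an `inirs_irf` with the same grid spacing.
#' @return a `component_spec` on the same grid.
#' @export
blur_with_irf <- function(components, irf) {
  stopifnot(inherits(components, "component_spec"), inherits(irf, "inirs_irf"))
  tof <- components$tof_ps
  conv <- function(v) convolve_irf(v, irf, tof_ps = tof)
  out <- components
  for (comp in c("static", "slow", "fast")) {
    Ifield <- paste0("I_", comp)
    Ib <- conv(components[[Ifield]])
    Ib[Ib < 0] <- 0  # clip convolution ringing
    out[[Ifield]] <- Ib
    if (comp != "static") {
      xif <- paste0("xi_", comp)
      num <- conv(components[[Ifield]] * components[[xif]])
      out[[xif]] <- ifelse(Ib > 0, pmax(0, num / pmax(Ib, 1e-300)), 0)
    }
  }
  out
}
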