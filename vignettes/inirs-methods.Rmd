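---
title: "TOF-resolved diffuse optical flowmetry with inirs: models, simulation, and fitting"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{TOF-resolved diffuse optical flowmetry with inirs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6,
                      fig.height = 4)
```

```{r setup}
library(inirs)
```

## The measurement and its models

Interferometric near-infrared spectroscopy (iNIRS) measures, for every
photon time of flight (TOF) $\tau_s$, the complex mutual coherence function
$\Gamma_{rs}(\tau_s, t_d)$ between light returning from tissue and a
reference beam, as a function of laboratory ("delay") time $t_d$. Its
autocorrelation over delay time,

$$G_1(\tau_s, \tau_d) = \langle \Gamma^*_{rs}(\tau_s, t_d)\,
  \Gamma_{rs}(\tau_s, t_d + \tau_d)\rangle_{t_d},$$

decays with lag $\tau_d$ at a rate set by the motion of the scatterers the
light encountered — in vivo, mainly red blood cells. The lag-0 slice is the
temporal point spread function (TPSF), so one measurement carries both the
photon TOF distribution (as in time-domain NIRS) and the field dynamics (as
in diffuse correlation spectroscopy, DCS, but TOF-resolved and without the
Siegert relation).

Scatterer motion enters through the mean-squared displacement (MSD)
$\langle\Delta r^2(\tau_d)\rangle$. `msd_model()` implements four laws:
Brownian ($6 D_B \tau_d$), random flow ($v^2\tau_d^2$), hydrodynamic
diffusion (ballistic-to-diffusive crossover on the collision time
$\tau_C$), and the hybrid sum of diffusion and flow. In the
single-scattering (DLS) regime the field autocorrelation at scattering
vector $q$ is $\eta_c + (1-\eta_c)\exp[-q^2\langle\Delta
r^2\rangle/6]$ (`g1_dls()`); in the diffusive (DWS) regime, at fixed TOF,

$$g_1(\tau_s,\tau_d) = \exp\!\left[-\tfrac{1}{3}\alpha k^2
  \langle\Delta r^2(\tau_d)\rangle\, \mu_s' c\,\tau_s / n_r\right],$$

with $\alpha$ the probability that a scattering event is dynamic and $k$
the medium wavenumber (`g1_dws()`). For Brownian motion the decay rate is
linear in TOF,

$$\xi(\tau_s) = \frac{2k^2\,\mathrm{BFI}\,\mu_s' c\,(\tau_s -
  \tau_{s,0})}{n_r},\qquad \mathrm{BFI} = \alpha D_B,$$

so a linear regression of fitted decay rates on TOF yields the blood flow
index from the slope alone: $\mathrm{BFI} = \lambda_0^2\,\mathrm{slope} /
(8\pi^2 n_r \mu_s' c)$ (`decay_rate_line()`, `bfi_from_slope()`). The
intercept $\tau_{s,0}$ is zero for a homogeneous medium; a positive value
is the semi-empirical signature of a thin low-flow superficial layer.
Absorption never enters this route — one of the method's main advantages
over classical DCS.

```{r}
op <- optical_properties(mu_a = 0.045, mu_sp = 10, n_r = 1.33, lambda0 = 855)
xi <- decay_rate_line(c(200, 400), bfi = 1.18e-8, optics = op)
xi
bfi_from_slope(diff(xi) / 200, op)
```

## Optical properties from the TPSF

`tpsf_semi_infinite()` implements the time-domain diffusion approximation
for a semi-infinite homogeneous medium with the extrapolated boundary
condition: an isotropic source at depth $z_0 = 1/\mu_s'$, an image source
mirrored about the plane $z = -z_b$ with $z_b = 2AD$, $D = 1/(3\mu_s')$,
and the internal-reflection parameter $A$ computed from the refractive
index by the Groenhuis polynomial (an `A` override is available, e.g.
$A = 1$ for index-matched comparisons with the Monte Carlo, whose free
surface is non-reflecting). `fit_tpsf_optics()` fits the IRF-convolved
model to a measured TPSF with free amplitude and TOF offset, on the log
scale, from 100 ps upward — earlier TOFs are not diffusive. The fit runs
in two stages (offset fixed at zero, then released) because amplitude,
offset, and $\mu_s'$ trade off along a shallow valley.

The instrument response function is modeled in the TOF domain.
`irf_profile()` builds it as the squared-magnitude Fourier transform of a
spectral apodization window over the laser tuning range: a rectangular
window over 64.7 GHz gives a 13.7 ps sinc$^2$ IRF, a Hann window about
22 ps. Because the measured 21.9 ps width does not pin down a unique
window, the window is a parameter, and `irf_gaussian()` lets analyses
specify the IRF directly by its width.

```{r}
irf_fwhm(irf_profile(64.7, "hann"))
```

## Correlation-transport Monte Carlo

`simulate_paths()` runs a photon random walk through layered media in
which every scattering event is dynamic with a per-layer probability.
Dynamic and static events can have different anisotropies — the key to the
"dynamical snake path" phenomenon: with RBC-like forward scattering
($g \approx 0.975$) and a small dynamic fraction (blood volume of a few
percent), many paths accumulate only small momentum transfer at dynamic
events and decorrelate slowly, producing the bi-exponential
autocorrelations seen in vivo and absent in Intralipid ($g \approx 0.6$,
fully dynamic). Each detected path records the sufficient statistic
$\sum_i q_i^2$ per layer, so TOF-resolved autocorrelations for any MSD law
follow by reweighting (`autocorrelation_from_paths()`), and
`filter_paths()` isolates snake paths by their largest dynamic deflection.

Design choices, in brief: layers are index matched (no internal Fresnel
reflection — a documented simplification); photons launch as a pencil beam;
azimuthal angles are uniform; absorption is handled by continuous weight
attenuation with Russian roulette below $10^{-6}$ (survival 0.1); the TOF
cutoff defaults to 2000 ps and TOF bins to 22 ps, mirroring the instrument
resolution; $\mu_s$ is derived from $\mu_s'$ through the event-probability
weighted composite anisotropy. The detector exploits cylindrical symmetry:
an annulus $[\rho - r, \rho + r]$ statistically equivalent to an off-axis
disk but with far higher collection efficiency. Henyey-Greenstein is the
default phase function; a two-term HG mixture is available for dynamic
events because the tails' shape depends on the phase function, not just on
$g$.

In the checks we run routinely, $2\times 10^5$ photons in a homogeneous
all-dynamic isotropic medium reproduce the DWS decay-rate line to about 1%
in slope with a TOF intercept below 2 ps, and the detected mean TOF at
7.6 mm separation matches the diffusion TPSF (with $A = 1$) to well under
5% for TOFs beyond 200 ps — at earlier TOFs the diffusion approximation
itself, not the simulation, is the limiting factor.

## Synthetic acquisition: what it emulates, and what it does not

`synthesize_gamma()` generates $\Gamma_{rs}$ time series directly in the
TOF domain: per TOF bin, a static phasor of fixed random phase plus up to
two dynamic components, each a unit-variance circular complex AR(1)
process — the exact discretization of an Ornstein-Uhlenbeck process, so
the ensemble autocorrelation is exactly the constant plus bi-exponential
model. This presumes Gaussian field statistics (fully developed speckle).
Defaults mirror the acquisition this toolkit is built around: 100 kHz
sweep rate (10 µs lag resolution), 2.5 s blocks (250,000 delay-time
points), 855 nm, and additive circular complex white noise at 40 dB peak
SNR. Raw spectral fringes are not synthesized: all analysis operates after
the TOF transform, and the IRF acts on component profiles via
`blur_with_irf()`.

Bulk motion (`synthesize_motion()`) follows a random-walk axial velocity;
each step advances the common bulk phase by
$\Delta\theta = (4\pi/\lambda_0)\,[\Delta z(1 + \cos\alpha_{SD}) +
\Delta x \sin\alpha_{SD}]/2$. The default step size (0.2 µm/s per 10 µs
step) yields RMS axial speeds near 100 µm/s by the end of a block —
chosen once from the physics: an uncorrected static-bin decay time of
several hundred microseconds implies Doppler shifts of a few hundred Hz at
855 nm. Real in vivo motion is not literally a velocity random walk; the
parameter is configurable and the correction pipeline does not depend on
the walk's specifics. The null-separation geometry is emulated by giving
the forearm-like preset a strong static backscatter component early in TOF
(approximately IRF-shaped), which is what makes phase estimation from the
peak-TOF bin work in practice.

What passing tests on this generator do *not* show: performance under
non-Gaussian field statistics, detector afterpulsing, sweep nonlinearity,
shot-noise-exact photon statistics, or motion with lateral components and
tissue deformation.

## Motion correction

`doppler_track()` slides a 2 ms window (1 ms hop — the 50% overlap halves
phase-tracking lag; the hop is not dictated by theory and is a parameter)
over the peak-TOF or TOF-integrated trace, computes the biased windowed
autocorrelation, and reads the Doppler shift off the maximum of its
8×-zero-padded power spectrum with parabolic interpolation on log power
(ties resolve toward zero frequency). Frequencies are integrated to a
cumulative unwrapped phase (`cumulative_phase()`) and removed from all TOF
bins at once (`correct_motion()`), since rigid axial motion shifts every
TOF identically. After correction the intrinsic autocorrelation should be
real; `estimate_g1(take_real = TRUE)` returns the real part and keeps the
imaginary part as a diagnostic of the noise floor.

On the default synthetic forearm scene the recovered phase tracks the
injected one to well under $\lambda/20$ RMS, the sliding Doppler estimate
correlates with the ground-truth windowed velocity at $R^2 > 0.95$, and
the corrected static-bin autocorrelation matches the motion-free ground
truth to a fraction of a percent, while the uncorrected one decays an
order of magnitude faster.

## Estimation and fitting choices

The autocovariance estimator divides by $N$ (not $N-m$): biased, but with
lower variance at long lags; for a static component this produces a known
linear taper $(1 - m/N)$, negligible at the default 10 ms window against
2.5 s blocks. No mean is subtracted — the static component *is* the
mean-like term and the fit models it explicitly. The lag-0 sample of an
estimated autocorrelation contains the additive-noise power, so the
per-TOF fitting driver excludes it by default; otherwise a 5-parameter fit
will spend a component on that single point. Confidence intervals for
autocorrelations use a block bootstrap (50 ms blocks, 200 resamples by
default); parameter CIs come from the Jacobian covariance at the optimum
(95%, t distribution). Both CI methods are this package's choices — the
quantities they describe are standard, the methods unstated in the
measurement literature.

`fit_decay()` fits the 1/2/3/5-parameter models with nonnegativity bounds,
Levenberg-Marquardt, and 8 multi-starts log-spaced in rate between
1/window and the sampling rate; ties in the objective resolve to the
solution found in fewer iterations. Fits are performed on unnormalized
autocorrelations (amplitudes in TPSF units). A bi-exponential whose rates
agree within 5%, or with a dynamic amplitude below 0.5% of the dynamic
total, collapses to the order-3 result with a `degenerate` flag — both
situations are reparametrizations of a mono-exponential. The order-5
labels are sorted so $\xi_{fast} \ge \xi_{slow}$. The "early-lag" variant
(`early_lag_fit()`) defaults its window to a quarter of the fast
component's $1/e$ time from a pilot fit; the measurement literature never
quantifies "early", so the window is exposed. Adjusted $R^2$
(`adjusted_r2()`) arbitrates model order: on Monte Carlo tissue-like media
the order-5 fit wins at intermediate TOFs and collapses at late TOFs,
on Intralipid-like media it never wins — the same pattern used in vivo.

`decay_rate_regression()` weights rates by inverse CI variance, flooring
each rate's standard error at 0.1% of its estimate: a residual-based CI
from a noise-free curve (common in Monte Carlo output) is not a credible
weight and would make the weighted design numerically rank-deficient.

## Deconstructing DCS

`integrate_tof()` collapses the surface (or a fitted component of it) over
TOF; `fit_dcs()` fits the TPSF-weighted DWS kernel
$\sum_{\tau_s} I(\tau_s)\, e^{-\xi(\tau_s;\mathrm{BFI})\tau_d}$ (rates
through the origin) to the normalized result, with amplitude free within
[0.9, 1.1]. The kernel uses the TOF distribution of the signal actually
integrated — the full TPSF for the full surface, a component's own
amplitude profile for component provenances. This choice is what makes the
deconstruction reproduce the in vivo finding: BFI fitted to the full
TOF-integrated autocorrelation depends strongly on the lag fit region
(slow tails contaminate late lags), whereas the fast-component integral
fits DWS theory with adjusted $R^2 \approx 1$ and a region-independent
BFI. The analytic semi-infinite correlation-diffusion solution is
deliberately out of scope: the kernel form needs no extra geometry model.
Exact lag regions for "early" versus "entire" are parameters
(`fit_regions`).

## Worked example

A small end-to-end run (shortened block for the vignette; defaults are
2.5 s):

```{r}
fx <- make_fixture("intralipid", seed = 1, block_duration = 0.5)
g1 <- estimate_g1(fx$series)
fits <- fit_decay_tof(g1, order = 3, window = 10e-3)
dl <- decay_rate_regression(fits, fx$optics)
dl
```

The recovered blood flow index sits within a few percent of the injected
$1.18\times 10^{-8}\,\mathrm{cm^2\,s^{-1}}$ with a TOF intercept near
zero, as expected for a homogeneous fully dynamic phantom.

```{r}
plot(vapply(fits, `[[`, numeric(1), "tau_s"),
     vapply(fits, function(f) coef(f)["xi"], numeric(1)),
     xlab = "time of flight (ps)", ylab = "decay rate (1/s)")
lines(fx$components$tof_ps, predict(dl, fx$components$tof_ps), col = 2)
```

## Problem sizes and determinism

The shipped tests and the acceptance script use $10^5$–$3\times10^5$
photons for Monte Carlo scenes and one to a few full-length synthetic
blocks per check; these sizes hold every quantitative tolerance in the
suite with margin. Every stochastic stage takes an explicit seed, derives
per-bin substreams deterministically from it, and records it in its output,
so reruns are bit-identical.

## Known limitations

- The diffusion TPSF is semi-infinite only; layered media are handled by
  Monte Carlo, not analytically.
- The Monte Carlo ignores internal reflection and refraction at
  boundaries and does not model polarization or ballistic-regime field
  propagation.
- The synthesis assumes Gaussian field statistics and rigid axial motion;
  the motion statistical model is a stand-in.
- The intermediate DLS-to-DWS regime is represented empirically (Monte
  Carlo plus the 5-parameter fit), not by closed-form theory.
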