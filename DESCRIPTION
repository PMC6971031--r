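Package: inirs
Title: Time-of-Flight Resolved Diffuse Optical Flowmetry
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Simulation and analysis toolkit for interferometric near-infrared
    spectroscopy (iNIRS), a time-of-flight (TOF) resolved method for measuring
    field fluctuations of multiply scattered light in turbid media such as
    living tissue. Provides closed-form field-autocorrelation models (DLS and
    DWS regimes; Brownian, advective, and hydrodynamic mean-squared
    displacement laws), a correlation-transport photon Monte Carlo for layered
    media with mixed static and dynamic scattering, direct stochastic
    synthesis of mutual coherence function time series with bulk-motion
    artifacts and noise, sliding-window Doppler motion correction,
    TOF-resolved autocorrelation estimation, multi-exponential decay fitting
    with blood flow index extraction, time-domain diffusion fitting of
    temporal point spread functions for optical properties, and TOF
    integration to diffuse correlation spectroscopy (DCS) style
    autocorrelations.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    minpack.lm,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
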