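Package: trnexafs
Title: Simulation and Kinetic Analysis of Time-Resolved NEXAFS Pump-Probe
    Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for femtosecond time-resolved near-edge X-ray absorption
    fine structure (TR-NEXAFS) experiments at free-electron lasers, built
    around the oxygen K-edge photophysics of gas-phase nucleobases. Provides
    construction of model NEXAFS spectra from stick lines (Gaussian
    broadening plus a cumulative-Gaussian ionization edge), population
    mixing into transient difference spectra, analytic sequential
    rate-equation (Bateman chain) populations with closed-form Gaussian
    instrument-response convolution, a shot-level synthetic data generator
    emulating free-electron-laser intensity and timing jitter with Poisson
    counting noise, the jitter-resorting and binning reduction into
    difference maps and region-of-interest time traces, and nonlinear
    least-squares recovery of the kinetic parameters (internal-conversion
    onset delay and biexponential excited-state decay) with standard
    errors.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    ggplot2,
    jsonlite,
    minpack.lm,
    rlang,
    stats,
    utils,
    yaml
Suggests:
    deSolve,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
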