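Package: kuramotoRC
Title: Hybrid Reservoir Computing for Kuramoto Oscillator Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forecasting of nonlinear oscillator networks with echo state
    networks and physics-informed hybrid reservoir computers that embed a
    one-step expert Kuramoto integrator. Provides ground-truth simulators for
    the standard and bi-harmonic Kuramoto models (synchronous, asynchronous,
    multi-frequency, heteroclinic-cycle and partial-synchrony regimes),
    phase-component coordinates, ridge-trained readouts, normalized mean
    square error and valid-time forecast metrics, and ensemble, parameter
    sweep and grid-search experiment harnesses.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    Rcpp,
    stats,
    utils,
    jsonlite
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
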