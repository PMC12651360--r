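Package: vibrofirm
Title: Noncontact Acoustic Vibration Assessment of Fruit Firmness
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for noncontact acoustic-vibration
    assessment of intact fruit firmness. Generates synthetic laser-vibrometer
    style vibration records with cultivar-specific resonance structure,
    estimates autoregressive (Burg) power spectral densities on a fixed
    0-5000 Hz grid, and predicts puncture-test firmness from the spectra with
    partial least squares regression, PCA plus support vector regression, and
    a one-dimensional Inception/squeeze-and-excitation convolutional network,
    including gradient-based saliency maps over frequency and layer-freezing
    transfer learning for adapting a trained network to a new cultivar.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    graphics,
    utils,
    signal,
    e1071,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
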