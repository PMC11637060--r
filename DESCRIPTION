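Package: pasos
Title: Speed-of-Sound Estimation and Aberration Correction for
    Photoacoustic/Ultrasound Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation-driven toolkit for learning-based speed-of-sound (SoS)
    estimation and aberration correction in dual-modal photoacoustic (PA) /
    ultrasound (US) imaging with a 128-element linear array. Generates digital
    tissue phantoms (randomized ellipse models and layered evaluation
    patterns), simulates single-plane-wave pulse-echo US and PA acquisition
    with a staggered-grid acoustic solver, conditions raw RF channel data into
    network-ready 128x1024 frames, trains a fully convolutional
    encoder-decoder to regress pixel-wise SoS maps from RF data (with
    frozen-base residual-head transfer learning), and performs time-reversal
    PA reconstruction with either a constant SoS, an autofocus-selected SoS,
    or a pixel-wise SoS map. Includes RMSE/SSIM/FWHM/SNR evaluation metrics
    and a benchmarking harness comparing the constant-1540 assumption, the
    autofocus baseline, and the learned estimator.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    signal,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    tiff,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
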