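Package: coptgak
Type: Package
Title: Class-Optimized Global Alignment Kernel Scoring and Generative-Model
    Monitoring for Sensor Time Series
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Similarity scoring for multichannel, uniformly sampled sensor
    time series (e.g. body-worn accelerometer and gyroscope windows) built
    around the Global Alignment Kernel (GAK), with the kernel bandwidth
    calibrated per activity class by maximizing the mean train-validation
    score under a constraint on the score standard deviation ("class-optimized"
    GAK).  Scores are computed per channel, optionally on Welch power spectral
    densities rather than raw signals, and averaged.  The package also
    provides cosine, Pearson and RMSE baselines, early-stopping monitors for
    the training and the denoising (sampling) phase of a time-series
    denoising diffusion model, a seeded generator of IMU-like cyclic and
    acyclic datasets, and a minimal demonstration diffusion harness with a
    per-channel linear noise schedule.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    data.table,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'RcppExports.R'
    'utils.R'
    'AllClasses.R'
    'AllGenerics.R'
    'sequence-methods.R'
    'io.R'
    'preprocessing.R'
    'welch.R'
    'similarity.R'
    'calibration.R'
    'monitoring.R'
    'synthgen.R'
    'ddpm.R'
    'runconfig.R'
    'coptgak-package.R'
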