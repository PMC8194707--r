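Package: tugsae
Title: Fall-Risk Assessment from Timed-Up-and-Go Accelerometry with
    Time-Frequency Images and Stacked Autoencoders
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for wearable-sensor fall-risk assessment from the timed
    up and go (TUG) test. Converts triaxial accelerometer traces into
    complex-Morlet time-frequency images, classifies them with a sparse
    stacked autoencoder trained by greedy layer-wise pretraining followed
    by supervised fine-tuning, and compares against a statistical-feature
    baseline (t-test feature screening and linear discriminant analysis)
    under leave-one-out cross-validation. Includes a seeded synthetic TUG
    cohort generator emulating the five-phase structure of the test and
    class-dependent walking-band spectral energy, so the full pipeline is
    reproducible without access to clinical recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    MASS,
    png,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    knitr
Config/testthat/edition: 3
biocViews: Classification, FeatureExtraction, TimeCourse
RoxygenNote: 7.3.3
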