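Package: eegcaps
Title: Temporal-Spatial-Frequency EEG Tensors and Capsule Networks for
    Subject-Independent Classification
Version: 1.0.0
Authors@R:
    person("eegcaps", "developers", email = "eegcaps@example.org",
           role = c("aut", "cre"))
Description: Transforms multichannel resting-state EEG into a four-dimensional
    temporal-spatial-frequency representation (FIR band filter bank composed
    with a 10-20 electrode-grid projection) and classifies it with a 3D
    convolution + capsule network trained by margin loss under strictly
    subject-independent cross-validation.  Includes the seven-step
    preprocessing chain (band-pass and notch filtering, pluggable ICA artifact
    removal, fixed-window segmentation, amplitude rejection, average
    re-referencing, z-score standardization), a synthetic multi-subject EEG
    cohort generator with band-specific group effects and 1/f background
    noise, EDF input/output, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp (>= 1.0.0),
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
SystemRequirements: C++17
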