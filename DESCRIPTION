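Package: imagerybci
Title: Detection of Mental Imagery in Cue-Based EEG Paradigms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for detecting mental imagery and attempted
    movements from cue-based EEG recordings, as used in brain-computer
    interface studies with patients with disorders of consciousness.
    Provides event-related desynchronization/synchronization (ERD/ERS)
    time-frequency maps with t-percentile bootstrap significance, log
    band-power feature extraction with linear discriminant classification
    under nested block-wise and leave-one-trial-out cross-validation,
    orthogonal Laplacian derivations with autoregressive inverse-filter
    artifact detection, and a simulated online feedback loop.  A
    paradigm-faithful synthetic EEG generator with known ground truth makes
    every stage testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    signal,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    MASS,
    testthat (>= 3.0.0)
LinkingTo:
    Rcpp
Config/testthat/edition: 3
RoxygenNote: 7.3.3
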