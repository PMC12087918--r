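Package: physiogasf
Title: Emotion-State Classification from Physiological Signals via
    Gramian Angular Fields and Domain-Generalized Residual Networks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A pipeline for classifying affective states from multichannel
    physiological recordings (EDA, BVP, temperature, respiration, ...).
    Each channel is split into subseries from which two time-domain and
    five frequency-domain features are pre-extracted; sliding windows over
    the resulting feature series are encoded as paired local/global
    Gramian angular summation field (GASF) image stacks and classified by
    a dual-stream 3D-convolutional residual network. Temporal covariate
    shift is mitigated by segmenting same-class training samples into
    maximally dissimilar domains (KMeans++ with size-aware merging) and
    aligning them during training with a maximum mean discrepancy (MMD)
    auxiliary loss. Includes a synthetic-recording generator with
    class-dependent spectral content, planted within-class regimes and
    controllable distribution drift for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    yaml,
    jsonlite
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
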