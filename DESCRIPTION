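Package: musclenet
Title: Multiplex Functional Mandibular Muscle Networks from Surface EMG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Constructs multiplex functional muscle networks from six-channel
    surface electromyography of the mandibular muscles during speech, and
    derives objective markers of bulbar motor involvement. Implements the full
    pipeline: crosstalk suppression and zero-phase filtering; visibility-graph
    descriptors (density, spectral radius ratio) of local-standard-deviation
    series; significance-gated, band-averaged, Fisher-z intermuscular
    coherence in the theta/alpha, beta and low-gamma bands; weighted graph
    descriptors (mean nodal strength, assortativity, global efficiency,
    clustering, laterality); jaw kinematic metrics (acceleration time, mean
    acceleration, stiffness); maximum-likelihood factor reduction with
    oblimin rotation, parallel analysis and tenBerge scores; linear
    mixed-effects disease-effect models and repeated cross-validated
    classification. A seeded synthetic cohort generator emulates
    burst-structured EMG with band-limited common drives so the whole
    pipeline is testable without human recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    ggplot2,
    generics,
    signal,
    igraph,
    lme4,
    lmerTest,
    emmeans,
    randomForest,
    e1071,
    class,
    pROC,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr
Config/testthat/edition: 3
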