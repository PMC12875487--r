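Package: musictrf
Title: Neural Encoding of Rhythmic and Melodic Expectations with Temporal
    Response Functions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for studying how continuous EEG encodes
    probabilistic musical expectations. Monophonic melodies are converted into
    discrete pitch and inter-onset-interval-ratio viewpoints; a variable-order
    Markov (PPM) sequence model with short- and long-term components yields
    note-by-note surprise and entropy for pitch and timing; time-lagged ridge
    regression (temporal response functions) relates acoustic and
    information-theoretic regressors to multichannel EEG; variance partitioning
    with temporally randomized regressors isolates the unique contribution of
    each feature set; and surprise-quantile event-related potentials are
    compared with spatiotemporal cluster-based permutation tests. Synthetic
    melody corpora and synthetic multi-subject EEG with planted response
    kernels provide ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Rcpp,
    jsonlite,
    lme4,
    emmeans,
    signal,
    stats,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    ggplot2,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
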