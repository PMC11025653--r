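Package: rnngbold
Title: Incremental-Parsing Complexity Metrics for fMRI Encoding Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Links generative parsing models to brain signals. Implements
    generative recurrent neural network grammars (RNNGs) under top-down and
    left-corner transition strategies, word-synchronous beam-search surprisal
    and distance metrics, Kneser-Ney 5-gram and LSTM baselines, construction
    of hemodynamic-response-convolved fMRI regressors, random-intercept
    linear mixed-effects model-comparison ladders over regions of interest,
    and a simplified two-level whole-brain general linear model with
    FDR plus cluster-extent thresholding. Ships a synthetic-data module
    (PCFG treebanks, stimulus schedules, simulated BOLD with known ground
    truth) so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    lme4,
    RNifti
Config/testthat/edition: 3
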