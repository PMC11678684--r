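Package: lncstack
Title: Stacked Ensemble Prediction of lncRNA Subcellular Localization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Predicts whether a long non-coding RNA transcript localizes to
    the cytoplasm or the nucleus from its sequence alone. Transcripts are
    encoded with five nucleotide descriptor families (cumulative skew,
    composition/transition/distribution, pseudo k-tuple nucleotide
    composition for k = 2..5, and 4-mer frequencies) together with three
    amino-acid descriptor families (CTDT, CKSAAP and tripeptide composition)
    computed on the peptides translated from the two highest-scoring open
    reading frames. A consensus of seven feature-selection algorithms prunes
    the fused feature space, a Boruta shadow-feature screen picks base
    learners out of an eleven-model pool, and a logistic-regression
    meta-learner stacks the survivors. Includes a synthetic labelled-sequence
    generator, full evaluation metrics, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    class,
    e1071,
    glmnet,
    jsonlite,
    matrixStats,
    ranger,
    rpart,
    stats,
    tools,
    utils,
    xgboost
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
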