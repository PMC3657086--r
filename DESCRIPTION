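Package: qsarmatrix
Title: Automated QSAR Model-Matrix Construction, Triage and Publication
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A project-based toolkit for automated quantitative
    structure-activity relationship (QSAR) modelling. Prepares
    structure-activity datasets (desalting, neutralisation,
    canonicalisation, response transforms), constructs multiple train/test
    splits (random, stratified, sphere-exclusion cluster based, predefined),
    computes 2D descriptor blocks (molecular properties, Kier-Hall chi
    indices, electrotopological state values, ECFP6/FCFP4 circular
    fingerprints) and named descriptor subsets, builds the full
    combinatorial matrix of models over splits x descriptor subsets x
    learners with failure isolation, provides ROC/REC validation, sortable
    model triage, split-bias diagnostics via multidimensional scaling,
    Y-scrambling, and publishes selected models as self-contained
    prediction bundles that replay data preparation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ChemmineR,
    ChemmineOB,
    Matrix,
    dplyr,
    e1071,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    nnet,
    purrr,
    randomForest,
    rlang,
    rpart,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    mixOmics,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
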