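Package: ehrmine
Title: Hierarchical Representation Mining and Case-Control Prediction
    for Electronic Health Records
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for phenotype prediction from longitudinal electronic
    health records in a matched case-control design.  Provides a seeded
    synthetic-cohort generator with planted discriminative events; cohort
    selection, time-before-diagnosis censoring, negation and family-note
    policies and rare-event pruning; constrained edit-distance grouping of
    free-text clinical entities into canonical surface forms; a
    word-containment hierarchy over textual events together with ICD-10 and
    ATC code rollups; sparse patient-by-event feature matrices under count,
    binary, L2-normalised and tf-idf encodings; filter-based feature ranking
    (Welch t, mutual information, chi-square) with top-fraction selection;
    and a cross-validated classifier harness (random forest, complement and
    Bernoulli naive Bayes, linear support vector machine) evaluated across a
    grid of prediction horizons.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Matrix,
    e1071,
    graphics,
    igraph,
    jsonlite,
    methods,
    pROC,
    ranger,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
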