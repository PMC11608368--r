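Package: scbackdoor
Title: Backdoor Data-Poisoning Attacks and Defenses for Single-Cell
    Cell-Type Classifiers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Constructs poisoned single-cell expression datasets that embed a
    depth-conserving threshold-zeroing trigger into heterogeneity-ranked victim
    cells and relabel them to an attacker-chosen target cell type; evaluates the
    resulting backdoor with attack success rate alongside clean-set accuracy,
    Cohen's kappa and macro-F1; and provides countermeasures (download hash
    verification, anomaly-score data sanitization, retraining-based model
    purification). Ships a synthetic labelled scRNA-seq count simulator and two
    surrogate classifiers so the full attack-train-evaluate loop runs on one CPU
    with no external data, plus readers and writers for H5AD, MatrixMarket and
    CSV labelled matrices and a command-line interface with reproducibility
    manifests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Matrix,
    digest,
    dplyr,
    generics,
    ggplot2,
    glmnet,
    class,
    jsonlite,
    methods,
    purrr,
    readr,
    rhdf5,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr
Suggests:
    e1071,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
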