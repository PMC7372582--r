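Package: phenoscreen
Title: Multi-Cell-Line Image-Based Phenotypic Profiling and Selective Hit Calling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for multi-cell-line Cell Painting screens:
    aggregation of per-cell morphology features to image- and well-level
    profiles, DMSO plate normalization, near-zero-variance and correlation
    feature selection, random-forest mechanism-of-action classification with
    leave-one-cell-line-out cross-validation, PCA/Mahalanobis phenotypic hit
    calling, nuclei-count z-score viability hit calling with cancer-versus-
    control selectivity rules, and Spearman-distance hierarchical clustering
    of cell-line responses. Includes a synthetic screen generator with known
    ground truth for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    tibble,
    dplyr,
    tidyr,
    readr,
    rlang,
    data.table,
    randomForest,
    jsonlite,
    yaml,
    ape
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
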