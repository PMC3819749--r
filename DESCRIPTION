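Package: aggprop
Title: Peptide Aggregation Propensity Prediction from Physicochemical
    Property Scales
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Sequence-based prediction of peptide aggregation propensity and
    detection of aggregation-prone regions in proteins, following the ProA
    approach. Peptides are encoded as averages of unit-scaled per-residue
    physicochemical property scales (AAindex format plus literature scales),
    aggregation-relevant properties are selected by SVM recursive feature
    elimination and by iterative random-forest Gini-importance elimination,
    and linear-SVM and random-forest propensity predictors are trained and
    validated by nested k-fold and leave-one-protein-out cross-validation.
    Whole proteins are scanned with a symmetric sliding window to produce
    per-residue propensity profiles and called aggregation-prone regions.
    Includes a synthetic fixture generator that plants class signal through
    residue-composition bias for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    randomForest,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
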