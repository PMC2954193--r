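Package: protclass
Title: Composition and Profile Based Binary Classification of Protein Sequences
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A toolkit for building and evaluating binary protein-sequence
    classifiers from compositional and evolutionary features. Provides five
    sequence encodings (amino-acid composition, split amino-acid composition,
    dipeptide composition, one-gap dipeptide composition, and a 400-dimension
    logistic-normalized PSSM composition), RBF-kernel support-vector and
    feed-forward neural-network classifiers behind a common decision-score
    contract, leave-one-out cross-validation with decision-threshold scanning,
    the standard performance metrics (sensitivity, specificity, accuracy,
    Matthews correlation coefficient, positive predictive value), ROC/AUC, a
    synthetic labeled-dataset generator with matched synthetic PSSM profiles,
    and a command-line interface over the whole workflow.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    optparse,
    purrr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
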