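Package: cypvar
Title: Sequence-Based Classification of Missense Mutations in Cytochrome P450s
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Classifies missense mutations in cytochrome P450 enzymes as benign
    or deleterious from sequence-derived information alone. Reads PSI-BLAST
    ASCII position-specific scoring matrices and predicted relative solvent
    accessibility profiles, derives five conservation and accessibility
    features per mutation (absolute similarity-score difference, size change
    weighted by similarity-score difference, windowed Shannon-entropy Z-score,
    predicted RSA, and windowed RSA variance), selects features by F-score with
    a Pearson-correlation redundancy filter, and trains either a Fisher linear
    discriminant or a small feed-forward neural network with standard or
    resilient backpropagation under a stratified 5-fold cross-validation
    protocol with held-out validation subsets. Includes confusion-table
    metrics (accuracy, recall, precision, Matthews correlation coefficient),
    ROC/AUC, consensus combiners, method-comparison reports, and a synthetic
    fixture generator so the full pipeline is testable without external
    databases.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    generics
Suggests:
    Biostrings,
    MASS,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
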