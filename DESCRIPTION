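Package: twasmr
Title: Transcriptome-Wide Association and Mendelian Randomization with
    Synthetic Benchmarks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A tibble-first toolkit for summary-statistics transcriptome-wide
    association studies (TWAS) and Mendelian randomization (MR), built around
    a seeded synthetic-data generator with known ground truth. Covers cis
    expression prediction model training (elastic net, cross-tissue
    sparse-group lasso, similarity-weighted joint-tissue fits), fixed-effect
    GWAS meta-analysis, allele harmonization, LD clumping, gene-level
    association from GWAS z-scores with an LD reference, pleiotropy-robust MR
    estimators (IVW, weighted median, Egger regression, per-instrument
    heterogeneity penalization), bidirectional and locus-restricted MR, and a
    phenome-wide association scan.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    glmnet,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
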