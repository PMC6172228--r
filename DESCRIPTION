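Package: humab
Title: Humanness Scoring and Statistical Humanization of Antibody Variable Regions
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Scores the "humanness" of aligned immunoglobulin VH/VL variable
    regions with the log posterior-predictive density of a multivariate
    Gaussian sequence model (a multivariate Student-t under a
    Normal-Inverse-Wishart prior), alongside nearest-neighbour Hamming
    distance baselines. Provides ROC-based model and threshold selection,
    and CDR-preserving humanization of murine sequences by steepest
    descent and simulated-annealing Monte Carlo on the model energy.
    Includes seeded generators of synthetic aligned ensembles with
    per-site profiles and pairwise couplings for testing and benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tools,
    utils,
    withr
Suggests:
    optparse,
    pracma,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
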