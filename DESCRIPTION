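Package: mrsomics
Title: Multi-Table Integration of In Vivo MRS Metabolite Profiles with Transcriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Links longitudinal and spatial in vivo proton magnetic resonance
    spectroscopy (1H-MRS) metabolite profiles with mixed-species (human tumor /
    mouse host) RNA-seq transcriptomes from orthotopic xenograft models of
    glioblastoma. Provides CRLB-based quality filtering and total-creatine
    normalization of metabolite tables, TMM normalization of counts,
    regularized iterative PCA imputation, statistical-triplet ordination
    (weighted PCA, within-group analysis, Monte-Carlo between-group inertia
    tests), STATIS multi-table compromise analysis, sparse PCA and sparse PLS
    gene selection with bootstrap consolidation, coinertia analysis with RV
    permutation tests, variation partitioning, consensus k-means clustering,
    and hypergeometric gene-set enrichment with homolog mapping. Ships a
    synthetic-data generator with planted ground truth emulating the study
    design, and end-to-end pipeline drivers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    edgeR,
    fgsea,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    mixOmics,
    testthat (>= 3.0.0),
    vegan,
    withr,
    yaml
Config/testthat/edition: 3
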