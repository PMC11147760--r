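Package: amlprog
Title: Shared AML Transcriptional Programs from Longitudinal Single-Cell
    Co-Culture Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Discovers acute myeloid leukemia (AML) transcriptional programs
    shared across patients from longitudinal single-cell co-culture
    experiments using a two-tier clustering procedure (within-sample
    clustering followed by meta-clustering of cluster centroids), scores
    program abundance in bulk RNA-seq cohorts, and associates abundance with
    T-cell killing sensitivity, clinical subtype, and survival. Includes
    receptor-ligand interaction scoring between AML programs and effector
    T cells, a simplified transcriptional-diversity differentiation score,
    killing-assay elimination-efficiency statistics, and a synthetic-data
    generator with planted ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    cluster,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    methods,
    purrr,
    readr,
    rlang,
    stats,
    survival,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
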