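Package: proteotriage
Title: Replicate-Based Triage and Multi-Branch Statistics for Label-Free
    Proteomics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A pipeline for label-free quantitative proteomics matrices
    (protein x sample x technical replicate AUC values) from small-cohort
    designs. Implements replicate-based presence calling and Venn-style
    cohort classification of proteins, three differently-imputed statistical
    branches (minimum-fraction imputation with median normalization, Pareto
    scaling, PCA, Welch tests and volcano classification; k-nearest-neighbour
    imputation feeding gene-set-permutation GSEA with a consensus pathway
    graph; half-group-minimum imputation feeding fold-change selection,
    hypergeometric pathway over-representation and protein-protein
    interaction hub analysis), an annotation-overlap branch, and a
    synthetic-data generator with planted ground truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    graphics,
    stats,
    utils,
    tools,
    igraph,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
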