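Package: stratomics
Title: Driver-Mutation-Stratified Integrative Multi-Omics Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Stratifies a tumor cohort into a truncating-mutation group and a
    "pan-negative" group from somatic mutation calls, then detects and
    integrates molecular differences between the groups across three layers:
    differential mRNA and miRNA expression by a conditional negative-binomial
    exact test with TMM normalization, differential DNA methylation of
    array beta-values by a SAM-style moderated statistic with permutation
    significance, and miRNA-target / methylation / expression overlaps
    (hyper-methylated down-regulated genes). Gene-set over-representation uses
    hypergeometric tests with Benjamini-Hochberg adjustment, and
    mutation-specific co-expression networks are built by intersecting
    top-fraction Pearson correlations with a reference protein-interaction
    graph. A synthetic multi-omics generator with recorded ground truth
    emulates the TCGA-like inputs so the whole pipeline can be validated at
    desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    igraph,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    edgeR,
    withr
Config/testthat/edition: 3
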