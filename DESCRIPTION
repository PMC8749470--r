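Package: recnet
Title: Receptor Prioritization by Network Neighborhood Enrichment and
    Co-Expression Clustering
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Prioritizes cell-surface receptors and transcription factors
    from single-cell RNA-seq data by testing whether each candidate's direct
    neighbors in a composite gene interaction network are enriched for genes
    differentially expressed in a target cell type (hypergeometric test over
    Wilcoxon rank-sum differential expression), then clusters the selected
    candidates by single-cell co-expression (agglomerative clustering on
    correlation distance), locates the cluster containing seed receptors such
    as the VEGF receptors KDR and FLT1, and tests that cluster for gene-set
    enrichment (e.g. angiogenesis, GO:0001525). Includes readers and writers
    for 10x-style MatrixMarket triplets, dense TSV matrices, edge lists, GMT
    collections and label tables; per-cell-type expression summaries
    (fraction of cells expressing, mean log-normalized level); marker-based
    cell typing; and a planted-truth negative-binomial simulator so every
    stage is verifiable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    igraph,
    jsonlite,
    yaml,
    graphics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
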