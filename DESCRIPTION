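Package: scaffscan
Title: Positional Clustering of Co-Regulated Genes on Genome Scaffolds
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects positional clusters of co-regulated genes along the
    gene order of genome scaffolds using a spacing-threshold scanning
    statistic with a permutation null, as used to study the genomic
    clustering of carbohydrate-active enzyme (CAZyme) genes in filamentous
    fungi. Includes the upstream selection of differentially expressed
    genes from replicated two-condition intensity matrices (quantile
    normalization, replicate-CV filtering, fold-change and moderated-t
    testing with Benjamini-Hochberg FDR control), downstream gene-list
    overlap statistics, readers and writers for TSV/GFF3/BED gene-order
    tables, and a synthetic-data generator that plants co-regulated
    clusters so every stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    grDevices,
    jsonlite,
    limma,
    rtracklayer,
    stats,
    tibble,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
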