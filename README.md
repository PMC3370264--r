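# scaffscan

Positional clustering of co-regulated genes on genome scaffolds.

## The problem

In filamentous fungi (and many other genomes), functionally related genes
such as carbohydrate-active enzymes (CAZymes) sit in discrete physical
clusters along the chromosomes. When perturbing a regulator changes the
expression of a few hundred genes, the natural follow-up question is
positional: are the responding genes *clustered* along the gene order of
the genome scaffolds, or scattered as uniform random placement would
predict?

`scaffscan` is for transcriptomics researchers who have (i) a gene-order
table for their genome (TSV, GFF3 or BED), and (ii) a replicated
two-condition expression matrix or a ready-made hit list, and want a
tested, reproducible answer to that question.

## The statistic

All distances are **gene-ordinal**: a gene's position is its 0-based rank
in the coordinate-sorted gene list of its scaffold. With *N* genes and *k*
hits, the expected spacing under uniform placement is *d&#772; = N / k*,
and the cluster threshold is *&tau; = d&#772; / c* (divisor *c* = 3 by
default: hits at least threefold closer than expected). A cluster is a
maximal run of hits whose consecutive gaps are all &le; *&tau;*, kept when
it has &ge; `min_hits` hits and its local hit density *n*/span is &ge;
`min_enrichment`-fold the genome-wide density *k/N*. Significance comes
from a permutation null: random hit sets of size *k* are rescanned with
identical parameters, and the cluster count's upper-tail p-value is
reported with add-one smoothing.

Around the scan, the package implements the full pipeline: quantile
normalization, replicate-CV filtering, fold-change plus moderated-t
testing with Benjamini&ndash;Hochberg FDR control, hit-list selection,
category (e.g. CAZyme) density enrichment of the called regions,
hypergeometric gene-list overlap, and a synthetic-data generator that
plants co-regulated clusters so every stage is testable without any
external data.

## Worked example

```r
library(scaffscan)

cfg <- simulation_config(n_genes = 3000, n_scaffolds = 6, n_regulated = 250,
                         n_planted_clusters = 6, cluster_size_range = c(6, 9),
                         seed = 42)
genome <- simulate_genome(cfg)
expr   <- simulate_expression(genome, cfg)

de   <- differential_expression(expr, cv_threshold = Inf)
hits <- select_regulated(de, fold_cut = 2, q_cut = 0.05, direction = "down")
length(hits)
#> [1] 250

scan <- scan_genome(genome, hits, scan_params(min_hits = 6,
                                              n_permutations = 999,
                                              seed = 43))
scan <- permutation_test(genome, scan)
scan
#> Positional cluster scan: 250 hits among 3000 genes
#>   expected spacing 12.0, threshold 4.00 (divisor 3)
#>   6 cluster(s) on 3 scaffold(s); mean 7.5 hits/cluster, mean 8.4-fold enriched
#>   permutation p (n_clusters) = 0.001
```

Reading this: 250 hits among 3000 genes means one hit per 12 loci if
placement were random, so hits at gaps of &le; 4 genes count as clustered.
The scan finds 6 clusters (here, exactly the 6 planted ones) averaging 7.5
hit genes each, with hit density 8.4-fold above genome average; none of
999 random hit sets produced as many clusters, so p = 1/1000.

```r
scan$clusters[, 1:6]
#> # A tibble: 6 x 6
#>   cluster_id  scaffold    start_ordinal end_ordinal n_hits span_genes
#> 1 cluster_001 scaffold_01           167         177      8         11
#> 2 cluster_002 scaffold_01           414         425      8         12
#> 3 cluster_003 scaffold_01           591         597      6          7
#> 4 cluster_004 scaffold_01           752         765      9         14
#> 5 cluster_005 scaffold_02           305         317      7         13
#> 6 cluster_006 scaffold_03           429         437      7          9
```

The hit list recovered by the DE stage coincides with the planted ground
truth:

```r
directional_overlap(hits, gene_list(truth_regulated(genome)), nrow(genome))
#> Gene-list overlap: 250 shared of 250 (A) and 250 (B), universe 3000
#>   100.0% of A, 100.0% of B; hypergeometric p = 0
```

(The p-value underflows to 0 for overlaps this extreme.)

`run_all(pipeline_config(...), out_dir)` drives the same stages end to end
from one seed and writes TSV/BED/JSON outputs plus a `summary.json`
report; `write_clusters_bed()` exports the calls for genome browsers.

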