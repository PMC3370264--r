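test_that("expected spacing is total genes per hit", {
  expect_equal(expected_spacing(9143, 769), 9143 / 769)
  expect_equal(round(expected_spacing(9143, 769), 1), 11.9)
  expect_equal(expected_spacing(100, 100), 1)
  expect_equal(expected_spacing(1000, 40), 25)
  expect_error(expected_spacing(100, 0), "no scan")
  expect_error(expected_spacing(100, 101), "exceed")
})

test_that("the spacing threshold divides the expected spacing", {
  expect_equal(spacing_threshold(12, 3), 4)
  expect_equal(spacing_threshold(9143 / 769, 1), 9143 / 769)
  expect_equal(spacing_threshold(9143 / 769, 3), 9143 / 769 / 3,
               tolerance = 1e-12)
  expect_error(spacing_threshold(12, 0), "divisor")
})

test_that("scan_scaffold calls the hand-checked clusters", {
  # no hits
  expect_equal(nrow(scan_scaffold(integer(0), 3.9, 0.1)), 0L)
  # a solid run of 7 adjacent hits
  cl <- scan_scaffold(0:6, 3.9, 769 / 9143)
  expect_equal(nrow(cl), 1L)
  expect_equal(cl$n_hits, 7L)
  expect_equal(cl$span_genes, 7L)
  expect_equal(cl$enrichment, 1 / (769 / 9143))
  # the pair {0,2} dies by min_hits; {50,52,54} survives
  cl2 <- scan_scaffold(c(0L, 2L, 50L, 52L, 54L), 3.9, 0.0841,
                       scan_params(min_hits = 3))
  expect_equal(nrow(cl2), 1L)
  expect_equal(cl2$start_ordinal, 50L)
  expect_equal(cl2$end_ordinal, 54L)
  expect_equal(cl2$n_hits, 3L)
})

test_that("unsorted or duplicated ordinals are rejected", {
  expect_error(scan_scaffold(c(3L, 1L), 3.9, 0.1), "strictly increasing")
  expect_error(scan_scaffold(c(1L, 1L, 4L), 3.9, 0.1), "strictly increasing")
})

test_that("scan_scaffold equals the brute-force oracle on random instances", {
  set.seed(101)
  for (trial in 1:100) {
    n <- sample(20:200, 1)
    k <- sample.int(max(2L, n %/% 3), 1) + 1L
    o <- random_hits(n, k)
    gd <- k / n
    th <- spacing_threshold(expected_spacing(n, k), 3)
    params <- scan_params(min_hits = sample(2:4, 1),
                          min_enrichment = sample(c(1, 3), 1))
    got <- scan_scaffold(o, th, gd, params)
    want <- oracle_scan(o, th, gd, params$min_hits, params$min_enrichment)
    expect_equal(nrow(got), nrow(want))
    expect_equal(got$start_ordinal, want$start_ordinal)
    expect_equal(got$end_ordinal, want$end_ordinal)
    expect_equal(got$n_hits, want$n_hits)
    expect_equal(got$enrichment, want$enrichment)
  }
})

test_that("the intervening-gene gap metric shifts gaps by one", {
  # gaps of 2 ordinals = 1 intervening gene
  o <- c(0L, 2L, 4L, 6L)
  a <- scan_scaffold(o, 1.5, 0.1, scan_params(min_hits = 3,
                                              min_enrichment = 1))
  expect_equal(nrow(a), 0L)  # ordinal gaps are 2 > 1.5
  b <- scan_scaffold(o, 1.5, 0.1,
                     scan_params(min_hits = 3, min_enrichment = 1,
                                 gap_metric = "intervening"))
  expect_equal(nrow(b), 1L)  # intervening gaps are 1 <= 1.5
  expect_equal(oracle_scan(o, 1.5, 0.1, 3, 1, gap_metric = "intervening")$n_hits,
               b$n_hits)
})

test_that("clusters are invariant under relabeling and order reversal", {
  set.seed(55)
  n <- 120L
  o <- random_hits(n, 18L)
  th <- spacing_threshold(expected_spacing(n, 18L), 3)
  params <- scan_params(min_hits = 3)
  fwd <- scan_scaffold(o, th, 18 / n, params)
  rev_o <- sort((n - 1L) - o)
  bwd <- scan_scaffold(rev_o, th, 18 / n, params)
  expect_equal(nrow(bwd), nrow(fwd))
  expect_setequal(bwd$n_hits, fwd$n_hits)
  expect_setequal(bwd$span_genes, fwd$span_genes)
  # mirrored coordinates
  expect_setequal((n - 1L) - bwd$end_ordinal, fwd$start_ordinal)
})

test_that("lowering the threshold only refines clusters", {
  set.seed(77)
  params <- scan_params(min_hits = 2, min_enrichment = 0)
  for (trial in 1:50) {
    n <- sample(50:200, 1)
    k <- sample(5:30, 1)
    o <- random_hits(n, k)
    gd <- k / n
    t_hi <- sample(2:6, 1)
    t_lo <- t_hi / 2
    hi <- scan_scaffold(o, t_hi, gd, params)
    lo <- scan_scaffold(o, t_lo, gd, params)
    if (nrow(lo) == 0) next
    for (i in seq_len(nrow(lo))) {
      parent <- which(hi$start_ordinal <= lo$start_ordinal[i] &
                        hi$end_ordinal >= lo$end_ordinal[i])
      expect_length(parent, 1L)
      expect_lte(lo$span_genes[i], hi$span_genes[parent])
    }
  }
})

test_that("equally spaced hits beyond the threshold give zero clusters", {
  o <- seq(0L, 990L, by = 10L)   # 100 hits, gaps 10
  th <- spacing_threshold(expected_spacing(1000, 100), 3)  # 10/3
  expect_equal(nrow(scan_scaffold(o, th, 0.1)), 0L)
})

test_that("scan_genome summarizes per-scaffold scans consistently", {
  g <- toy_genome(c(60L, 40L))
  hits <- c(g$gene_id[g$scaffold == "sc01" & g$ordinal %in% c(0:3, 30:34)],
            g$gene_id[g$scaffold == "sc02" & g$ordinal %in% 10:14])
  sc <- scan_genome(g, gene_list(hits), scan_params(min_hits = 3))
  expect_equal(sc$n_total, 100L)
  expect_equal(sc$n_hits, 14L)
  expect_equal(sc$expected_spacing, 100 / 14)
  expect_equal(sc$n_clusters, 3L)
  expect_equal(sc$n_scaffolds_with_clusters, 2L)
  # summary means recomputable from the cluster list
  expect_equal(sc$mean_hits_per_cluster, mean(sc$clusters$n_hits))
  expect_equal(sc$mean_enrichment, mean(sc$clusters$enrichment))
  expect_equal(sc$mean_span_genes, mean(sc$clusters$span_genes))
  # member genes are hits within the span
  for (i in seq_len(nrow(sc$clusters))) {
    ids <- sc$clusters$hit_genes[[i]]
    expect_true(all(ids %in% hits))
    o <- g$ordinal[match(ids, g$gene_id)]
    expect_equal(min(o), sc$clusters$start_ordinal[i])
    expect_equal(max(o), sc$clusters$end_ordinal[i])
  }
})

test_that("hits absent from the genome are reported by id", {
  g <- toy_genome(c(20L))
  expect_error(scan_genome(g, gene_list(c("t0001", "nope"))), "nope")
})

test_that("saturated hit sets give enrichment 1 and are discarded", {
  # every gene a hit: expected spacing 1, so the adjacent gaps of 1 join
  # into one run per scaffold when the divisor is 1
  g <- toy_genome(c(50L, 30L))
  sc <- scan_genome(g, gene_list(g$gene_id),
                    scan_params(spacing_divisor = 1, min_hits = 3,
                                min_enrichment = 1))
  expect_equal(sc$n_clusters, 2L)
  expect_equal(sc$clusters$enrichment, c(1, 1))
  sc2 <- scan_genome(g, gene_list(g$gene_id),
                     scan_params(spacing_divisor = 1, min_hits = 3,
                                 min_enrichment = 1.5))
  expect_equal(sc2$n_clusters, 0L)
})

test_that("planted clusters are recovered with correct spans", {
  cfg <- simulation_config(n_genes = 3000L, n_scaffolds = 5L,
                           n_regulated = 120L, n_planted_clusters = 5L,
                           cluster_size_range = c(8L, 8L),
                           within_cluster_spacing = 2L, seed = 13L)
  g <- simulate_genome(cfg)
  sc <- scan_genome(g, gene_list(truth_regulated(g)),
                    scan_params(min_hits = 5))
  tc <- truth_clusters(g)
  for (i in seq_len(nrow(tc))) {
    match_cl <- sc$clusters[sc$clusters$scaffold == tc$scaffold[i] &
                              sc$clusters$start_ordinal <= tc$start_ordinal[i] &
                              sc$clusters$end_ordinal >= tc$end_ordinal[i], ]
    expect_gte(nrow(match_cl), 1L)
  }
})

test_that("permutation p is 1 for an empty observed scan", {
  g <- toy_genome(c(30L))
  hits <- g$gene_id[g$ordinal %in% c(0L, 15L, 29L)]
  sc <- scan_genome(g, gene_list(hits), scan_params(n_permutations = 49,
                                                    seed = 1))
  sc <- permutation_test(g, sc)
  expect_equal(sc$permutation_p_n_clusters, 1)
})

test_that("strongly planted scans get the smallest attainable p", {
  cfg <- simulation_config(n_genes = 2000L, n_scaffolds = 3L,
                           n_regulated = 40L, n_planted_clusters = 5L,
                           cluster_size_range = c(8L, 8L),
                           within_cluster_spacing = 1L, seed = 19L)
  g <- simulate_genome(cfg)
  sc <- scan_genome(g, gene_list(truth_regulated(g)),
                    scan_params(min_hits = 5, n_permutations = 999,
                                seed = 20L))
  sc <- permutation_test(g, sc)
  expect_equal(sc$permutation_p_n_clusters, 1 / 1000)
})

test_that("one shuffled hit set falls inside the null support", {
  cfg <- simulation_config(n_genes = 1500L, n_scaffolds = 3L,
                           n_regulated = 120L, n_planted_clusters = 0L,
                           seed = 23L)
  g <- simulate_genome(cfg)
  sc <- scan_genome(g, gene_list(truth_regulated(g)),
                    scan_params(n_permutations = 99, seed = 24L))
  sc <- permutation_test(g, sc)
  null_counts <- attr(sc, "null_n_clusters")
  expect_gte(sc$n_clusters, min(null_counts))
  expect_lte(sc$n_clusters, max(null_counts) + 2L)
})

test_that("stratified permutation preserves per-scaffold hit counts", {
  g <- toy_genome(c(60L, 40L))
  hits <- c(g$gene_id[g$scaffold == "sc01"][1:9],
            g$gene_id[g$scaffold == "sc02"][1:3])
  sc <- scan_genome(g, gene_list(hits),
                    scan_params(n_permutations = 19, seed = 2,
                                stratified = TRUE))
  expect_equal(unname(sc$hits_per_scaffold), c(9L, 3L))
  sc <- permutation_test(g, sc)
  expect_true(sc$permutation_p_n_clusters > 0 &&
                sc$permutation_p_n_clusters <= 1)
})

test_that("category enrichment follows the density ratio definition", {
  # 2000-gene genome; 80 labelled genes; a 20-gene region with 8 of them
  df <- data.frame(gene_id = sprintf("g%04d", 1:2000), scaffold = "s",
                   ordinal = 0:1999)
  labelled <- c(1:8, seq(100, 1955, length.out = 72))
  df$categories <- ifelse(seq_len(2000) %in% round(labelled), "CAZ", "")
  g <- genome_table(df)
  regions <- data.frame(scaffold = "s", start_ordinal = 0L,
                        end_ordinal = 19L)
  expect_equal(category_density_enrichment(g, regions, "CAZ"),
               (8 / 20) / (80 / 2000))
  # whole-genome region has enrichment 1
  whole <- data.frame(scaffold = "s", start_ordinal = 0L,
                      end_ordinal = 1999L)
  expect_equal(category_density_enrichment(g, whole, "CAZ"), 1)
  expect_error(category_density_enrichment(g, regions[0, ], "CAZ"), "empty")
  expect_error(category_density_enrichment(g, regions, "nope"), "labels no gene")
})
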