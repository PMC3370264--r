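#' Parameters of the positional cluster scan
#'
#' The scan criterion: consecutive hits belong to the same candidate
#' cluster when the ordinal gap between them is at most the spacing
#' threshold (the genome-wide expected spacing divided by
#' `spacing_divisor`); candidates are kept when they contain at least
#' `min_hits` hits and their local hit density is at least
#' `min_enrichment`-fold the genome-wide density.
#'
#' @param spacing_divisor Threshold = expected spacing / divisor
#'   (default 3, the "threefold smaller than average" rule).
#' @param min_hits Minimum hits per cluster (default 3; two adjacent hits
#'   trivially exceed threefold enrichment).
#' @param min_enrichment Minimum fold enrichment of local over global hit
#'   density (default 3).
#' @param n_permutations Permutations for the significance test
#'   (default 1000).
#' @param seed Optional integer seed for the permutation draw.
#' @param gap_metric `"ordinal"` (gap = difference of ordinal positions;
#'   adjacent genes have gap 1) or `"intervening"` (gap = number of genes
#'   strictly between two hits = ordinal difference - 1).
#' @param strict Compare gaps with `<` instead of `<=` (default `FALSE`).
#' @param stratified Draw permutation hits per scaffold, preserving the
#'   observed per-scaffold hit counts, instead of genome-wide uniform
#'   draws (default `FALSE`).
#' @return A list of class `scan_params`.
#' @export
scan_params <- function(spacing_divisor = 3, min_hits = 3L,
                        min_enrichment = 3, n_permutations = 1000L,
                        seed = NULL, gap_metric = c("ordinal", "intervening"),
                        strict = FALSE, stratified = FALSE) {
  if (!is_number(spacing_divisor) || spacing_divisor <= 0)
    abort("spacing_divisor must be > 0")
  if (!is_count(min_hits, 2L)) abort("min_hits must be an integer >= 2")
  if (!is_number(min_enrichment) || min_enrichment < 0)
    abort("min_enrichment must be >= 0")
  if (!is_count(n_permutations, 1L)) abort("n_permutations must be >= 1")
  gap_metric <- match.arg(gap_metric)
  structure(list(spacing_divisor = spacing_divisor,
                 min_hits = as.integer(min_hits),
                 min_enrichment = min_enrichment,
                 n_permutations = as.integer(n_permutations),
                 seed = seed, gap_metric = gap_metric,
                 strict = isTRUE(strict), stratified = isTRUE(stratified)),
            class = "scan_params")
}

#' Expected spacing between hits under uniform placement
#'
#' The mean ordinal gap between hits if `n_hits` hits were placed uniformly
#' among `n_total` genes: `n_total / n_hits`. No rounding is applied; for
#' display, one decimal is customary (e.g. 9143 genes / 769 hits = 11.9,
#' "one hit at every twelfth locus").
#'
#' @param n_total Total number of genes.
#' @param n_hits Number of hit genes; must satisfy `0 < n_hits <= n_total`.
#' @return The expected spacing as a real number.
#' @export
expected_spacing <- function(n_total, n_hits) {
  if (!is_count(n_total, 1L)) abort("n_total must be a positive integer")
  if (!is_count(n_hits, 0L)) abort("n_hits must be a non-negative integer")
  if (n_hits == 0) abort("n_hits is 0: no scan possible")
  if (n_hits > n_total) abort("n_hits must not exceed n_total")
  n_total / n_hits
}

#' Spacing threshold for the cluster criterion
#'
#' Divides the expected spacing by `divisor`; hits closer than this are
#' considered clustered ("at least threefold smaller than the average
#' distribution").
#'
#' @param spacing Expected spacing (see [expected_spacing()]).
#' @param divisor Positive divisor, default 3.
#' @return `spacing / divisor`.
#' @export
spacing_threshold <- function(spacing, divisor = 3) {
  if (!is_number(spacing) || spacing <= 0) abort("spacing must be > 0")
  if (!is_number(divisor) || divisor <= 0) abort("divisor must be > 0")
  spacing / divisor
}

# Shared scan core, used identically by the per-scaffold scan and the
# permutation rescans. `pos` must be strictly increasing; positions on
# different scaffolds must be padded apart by more than the threshold so
# runs never bridge scaffolds. Returns candidate runs (start/end index into
# pos) before the min_hits / min_enrichment filters.
scan_runs <- function(pos, threshold, gap_metric, strict) {
  n <- length(pos)
  if (n == 0) return(cbind(start = integer(0), end = integer(0)))
  gaps <- diff(pos)
  if (gap_metric == "intervening") gaps <- gaps - 1
  ok <- if (strict) gaps < threshold else gaps <= threshold
  r <- rle(ok)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  # run over gaps i..j joins hits i..j+1
  cbind(start = starts[keep], end = ends[keep] + 1L)
}

# filter candidate runs into cluster calls; returns tibble in ordinal space
call_clusters <- function(pos, runs, global_density, params) {
  if (nrow(runs) == 0)
    return(tibble(start_ordinal = integer(0), end_ordinal = integer(0),
                  n_hits = integer(0), span_genes = integer(0),
                  local_density = numeric(0), enrichment = numeric(0),
                  hit_index = list()))
  n_hits <- unname(runs[, "end"] - runs[, "start"] + 1L)
  start_o <- unname(pos[runs[, "start"]])
  end_o <- unname(pos[runs[, "end"]])
  span <- end_o - start_o + 1L
  dens <- n_hits / span
  enr <- dens / global_density
  keep <- n_hits >= params$min_hits & enr >= params$min_enrichment
  tibble(start_ordinal = as.integer(start_o[keep]),
         end_ordinal = as.integer(end_o[keep]),
         n_hits = as.integer(n_hits[keep]),
         span_genes = as.integer(span[keep]),
         local_density = dens[keep],
         enrichment = enr[keep],
         hit_index = lapply(which(keep), function(i)
           seq.int(runs[i, "start"], runs[i, "end"])))
}

#' Scan one scaffold's hit ordinals for positional clusters
#'
#' Records the ordinal gaps between consecutive hits, chains maximal runs
#' whose internal gaps are all within the spacing threshold, and keeps
#' runs with at least `min_hits` hits whose local hit density
#' (`n_hits / span_genes`) is at least `min_enrichment` times
#' `global_density`. Returned clusters are disjoint and ordered.
#'
#' @param hit_ordinals Strictly increasing integer ordinals of the hits on
#'   one scaffold (0-based).
#' @param threshold Spacing threshold (see [spacing_threshold()]).
#' @param global_density Genome-wide hit density `n_hits / n_total`.
#' @param params A [scan_params()] (its `min_hits`, `min_enrichment`,
#'   `gap_metric` and `strict` fields are used).
#' @return A tibble with one row per cluster: `start_ordinal`,
#'   `end_ordinal`, `n_hits`, `span_genes`, `local_density`, `enrichment`,
#'   `hit_index` (list-column of indices into `hit_ordinals`).
#' @export
scan_scaffold <- function(hit_ordinals, threshold, global_density,
                          params = scan_params()) {
  if (length(hit_ordinals) > 0) {
    if (any(hit_ordinals != as.integer(hit_ordinals)))
      abort("hit ordinals must be integers")
    if (any(diff(hit_ordinals) <= 0))
      abort("hit ordinals must be strictly increasing (sorted, no duplicates)")
    if (any(hit_ordinals < 0)) abort("hit ordinals must be >= 0")
  }
  if (!is_number(threshold) || threshold <= 0) abort("threshold must be > 0")
  if (!is_number(global_density) || global_density <= 0 || global_density > 1)
    abort("global_density must lie in (0, 1]")
  runs <- scan_runs(hit_ordinals, threshold, params$gap_metric, params$strict)
  call_clusters(hit_ordinals, runs, global_density, params)
}

#' Scan a genome for positional clusters of hit genes
#'
#' Maps the hit genes onto the ordered gene lists of the scaffolds,
#' computes the genome-wide expected spacing and the spacing threshold,
#' scans every scaffold with [scan_scaffold()] and assembles the global
#' summary. The permutation p-value is filled in by [permutation_test()].
#'
#' @param genome A [genome_table()].
#' @param hits A [gene_list()] or character vector of hit gene ids; every
#'   id must be present in the genome.
#' @param params A [scan_params()].
#' @return A list of class `scan_result` with fields `n_total`, `n_hits`,
#'   `global_density`, `expected_spacing`, `threshold`, `clusters` (a
#'   tibble with `cluster_id`, `scaffold`, ordinal span, `n_hits`,
#'   `span_genes`, `local_density`, `enrichment`, `hit_genes`),
#'   `n_clusters`, `n_scaffolds_with_clusters`, `mean_hits_per_cluster`,
#'   `mean_span_genes`, `mean_enrichment`, `permutation_p_n_clusters`
#'   (`NA` until [permutation_test()] is run) and `params`.
#' @export
scan_genome <- function(genome, hits, params = scan_params()) {
  stopifnot(inherits(genome, "genome_table"))
  hits <- unique(as.character(hits))
  missing_ids <- setdiff(hits, genome$gene_id)
  if (length(missing_ids) > 0)
    abort("hit id(s) absent from genome: %s", id_preview(missing_ids))
  n_total <- nrow(genome)
  n_hits <- length(hits)
  spacing <- expected_spacing(n_total, n_hits)
  threshold <- spacing_threshold(spacing, params$spacing_divisor)
  global_density <- n_hits / n_total
  is_hit <- genome$gene_id %in% hits
  cl_list <- list()
  for (sc in unique(genome$scaffold)) {
    rows <- which(genome$scaffold == sc & is_hit)
    if (length(rows) == 0) next
    o <- order(genome$ordinal[rows])
    rows <- rows[o]
    cl <- scan_scaffold(genome$ordinal[rows], threshold, global_density, params)
    if (nrow(cl) == 0) next
    cl$scaffold <- sc
    cl$hit_genes <- lapply(cl$hit_index, function(ix) genome$gene_id[rows[ix]])
    cl$hit_index <- NULL
    cl_list[[length(cl_list) + 1L]] <- cl
  }
  clusters <- if (length(cl_list) > 0) do.call(rbind, cl_list) else
    tibble(start_ordinal = integer(0), end_ordinal = integer(0),
           n_hits = integer(0), span_genes = integer(0),
           local_density = numeric(0), enrichment = numeric(0),
           scaffold = character(0), hit_genes = list())
  clusters <- clusters[order(clusters$scaffold, clusters$start_ordinal), ,
                       drop = FALSE]
  clusters <- tibble(
    cluster_id = if (nrow(clusters) > 0)
      sprintf("cluster_%03d", seq_len(nrow(clusters))) else character(0),
    scaffold = clusters$scaffold,
    start_ordinal = clusters$start_ordinal,
    end_ordinal = clusters$end_ordinal,
    n_hits = clusters$n_hits,
    span_genes = clusters$span_genes,
    local_density = clusters$local_density,
    enrichment = clusters$enrichment,
    hit_genes = clusters$hit_genes
  )
  hits_per_scaffold <- vapply(split(is_hit, genome$scaffold), sum, integer(1))
  structure(list(
    n_total = n_total,
    n_hits = n_hits,
    hits_per_scaffold = hits_per_scaffold,
    global_density = global_density,
    expected_spacing = spacing,
    threshold = threshold,
    clusters = clusters,
    n_clusters = nrow(clusters),
    n_scaffolds_with_clusters = length(unique(clusters$scaffold)),
    mean_hits_per_cluster = if (nrow(clusters) > 0) mean(clusters$n_hits) else NA_real_,
    mean_span_genes = if (nrow(clusters) > 0) mean(clusters$span_genes) else NA_real_,
    mean_enrichment = if (nrow(clusters) > 0) mean(clusters$enrichment) else NA_real_,
    permutation_p_n_clusters = NA_real_,
    params = params
  ), class = "scan_result")
}

#' @export
print.scan_result <- function(x, ...) {
  cat(sprintf(
    paste0("Positional cluster scan: %d hits among %d genes\n",
           "  expected spacing %.1f, threshold %.2f (divisor %g)\n",
           "  %d cluster(s) on %d scaffold(s)"),
    x$n_hits, x$n_total, x$expected_spacing, x$threshold,
    x$params$spacing_divisor, x$n_clusters, x$n_scaffolds_with_clusters))
  if (x$n_clusters > 0)
    cat(sprintf("; mean %.1f hits/cluster, mean %.1f-fold enriched",
                x$mean_hits_per_cluster, x$mean_enrichment))
  cat("\n")
  if (!is.na(x$permutation_p_n_clusters))
    cat(sprintf("  permutation p (n_clusters) = %.4g\n",
                x$permutation_p_n_clusters))
  invisible(x)
}

# padded global positions: ordinals shifted per scaffold so that
# cross-scaffold gaps always exceed the threshold
padded_positions <- function(genome, threshold) {
  pad <- floor(threshold) + 2L
  sizes <- table(factor(genome$scaffold, levels = unique(genome$scaffold)))
  offs <- cumsum(c(0L, (as.integer(sizes) + pad)[-length(sizes)]))
  names(offs) <- names(sizes)
  genome$ordinal + offs[genome$scaffold]
}

#' Permutation test for the number of called clusters
#'
#' Draws `n_permutations` random hit sets of the observed size (uniformly
#' without replacement genome-wide, or per scaffold when
#' `params$stratified`), rescans each with identical parameters, and
#' reports the add-one-smoothed upper-tail p-value
#' `p = (1 + #permutations with >= observed clusters) /
#' (n_permutations + 1)` -- the probability of seeing at least as many
#' clusters under random placement of the hit genes.
#'
#' @param genome The [genome_table()] that was scanned.
#' @param observed A `scan_result` from [scan_genome()].
#' @param params A [scan_params()]; defaults to the parameters stored in
#'   `observed`. Its `seed`, if non-`NULL`, seeds the draw.
#' @return `observed` with `permutation_p_n_clusters` filled in and the
#'   null cluster counts attached as attribute `"null_n_clusters"`.
#' @export
permutation_test <- function(genome, observed, params = observed$params) {
  stopifnot(inherits(genome, "genome_table"), inherits(observed, "scan_result"))
  if (!is_count(params$n_permutations, 1L)) abort("n_permutations must be >= 1")
  if (!is.null(params$seed)) set.seed(params$seed)
  n <- nrow(genome)
  k <- observed$n_hits
  gd <- observed$global_density
  th <- observed$threshold
  pos_all <- padded_positions(genome, th)
  scaffold_rows <- split(seq_len(n), genome$scaffold)
  count_one <- function(idx) {
    pos <- sort(pos_all[idx])
    runs <- scan_runs(pos, th, params$gap_metric, params$strict)
    if (nrow(runs) == 0) return(0L)
    n_h <- runs[, "end"] - runs[, "start"] + 1L
    span <- pos[runs[, "end"]] - pos[runs[, "start"]] + 1
    sum(n_h >= params$min_hits & (n_h / span) / gd >= params$min_enrichment)
  }
  null_counts <- integer(params$n_permutations)
  for (b in seq_len(params$n_permutations)) {
    idx <- if (params$stratified) {
      unlist(lapply(names(scaffold_rows), function(sc) {
        rows <- scaffold_rows[[sc]]
        k_sc <- observed$hits_per_scaffold[sc]
        if (!is.na(k_sc) && k_sc > 0) rows[sample.int(length(rows), k_sc)]
        else integer(0)
      }), use.names = FALSE)
    } else {
      sample.int(n, k)
    }
    null_counts[b] <- count_one(idx)
  }
  p <- (1 + sum(null_counts >= observed$n_clusters)) /
    (params$n_permutations + 1)
  observed$permutation_p_n_clusters <- p
  attr(observed, "null_n_clusters") <- null_counts
  observed
}

#' Category density enrichment within genome regions
#'
#' Ratio of the category's gene density inside a set of regions to its
#' genome-wide density:
#' `(category genes in regions / genes in regions) /
#' (category genes genome-wide / total genes)`. Used, for example, to ask
#' how strongly CAZyme genes are concentrated in called cluster regions.
#'
#' @param genome A [genome_table()] with category labels.
#' @param regions A data frame with columns `scaffold`, `start_ordinal`,
#'   `end_ordinal` (inclusive), or a `scan_result` whose clusters are used.
#' @param category Category label (case-sensitive exact match).
#' @return The fold enrichment (a single real number).
#' @export
category_density_enrichment <- function(genome, regions, category) {
  stopifnot(inherits(genome, "genome_table"))
  if (inherits(regions, "scan_result")) regions <- regions$clusters
  regions <- as.data.frame(regions)
  if (nrow(regions) == 0) abort("empty region list: enrichment undefined")
  req <- c("scaffold", "start_ordinal", "end_ordinal")
  if (!all(req %in% names(regions)))
    abort("regions must have columns scaffold, start_ordinal, end_ordinal")
  has_cat <- vapply(genome$categories, function(x) category %in% x, logical(1))
  n_cat_total <- sum(has_cat)
  if (n_cat_total == 0)
    abort("category '%s' labels no gene in the genome", category)
  in_region <- rep(FALSE, nrow(genome))
  for (i in seq_len(nrow(regions))) {
    in_region <- in_region |
      (genome$scaffold == regions$scaffold[i] &
         genome$ordinal >= regions$start_ordinal[i] &
         genome$ordinal <= regions$end_ordinal[i])
  }
  n_in <- sum(in_region)
  if (n_in == 0) abort("regions contain no genes: enrichment undefined")
  (sum(has_cat & in_region) / n_in) / (n_cat_total / nrow(genome))
}
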