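#' Directional overlap between two gene lists
#'
#' Counts the genes shared by two lists, expresses the overlap as a
#' percentage of each list, and reports the hypergeometric upper-tail
#' probability of drawing at least that many shared genes when `n_a` genes
#' are sampled from a universe in which `n_b` genes are marked.
#'
#' @param list_a,list_b [gene_list()]s or character vectors
#'   (duplicate-free).
#' @param universe Size of the gene universe (e.g. the genome gene count);
#'   must be at least `|A union B|`.
#' @return A list of class `overlap_result` with fields `n_a`, `n_b`,
#'   `n_universe`, `n_overlap`, `pct_of_a`, `pct_of_b`,
#'   `hypergeometric_p`, `shared_ids`.
#' @export
directional_overlap <- function(list_a, list_b, universe) {
  a <- unclass(gene_list(as.character(list_a)))
  b <- unclass(gene_list(as.character(list_b)))
  if (!is_count(universe, 1L)) abort("universe must be a positive integer")
  n_union <- length(union(a, b))
  if (universe < n_union)
    abort("universe (%d) is smaller than |A union B| (%d)", universe, n_union)
  shared <- intersect(a, b)
  k <- length(shared)
  n_a <- length(a)
  n_b <- length(b)
  p <- phyper(k - 1, n_b, universe - n_b, n_a, lower.tail = FALSE)
  structure(list(
    n_a = n_a, n_b = n_b, n_universe = as.integer(universe),
    n_overlap = k,
    pct_of_a = if (n_a > 0) 100 * k / n_a else NA_real_,
    pct_of_b = if (n_b > 0) 100 * k / n_b else NA_real_,
    hypergeometric_p = p,
    shared_ids = sort(shared)
  ), class = "overlap_result")
}

#' @export
print.overlap_result <- function(x, ...) {
  cat(sprintf(
    paste0("Gene-list overlap: %d shared of %d (A) and %d (B), ",
           "universe %d\n  %.1f%% of A, %.1f%% of B; ",
           "hypergeometric p = %.3g\n"),
    x$n_overlap, x$n_a, x$n_b, x$n_universe,
    x$pct_of_a, x$pct_of_b, x$hypergeometric_p))
  invisible(x)
}

#' Reciprocal (anti-correlated) overlap of two signed comparisons
#'
#' For two experiments each yielding an up- and a down-regulated list,
#' computes the two anti-correlated components -- genes up in A and down in
#' B, and genes down in A and up in B -- separately and combined, as used
#' when asking how much of one response mirrors another (e.g. genes
#' upregulated during sporulation and downregulated in a deletion strain,
#' and vice versa).
#'
#' @param a_up,a_down Up-/down-regulated lists of experiment A.
#' @param b_up,b_down Up-/down-regulated lists of experiment B.
#' @param universe Gene universe size.
#' @return A list with elements `up_a_down_b` and `down_a_up_b` (each an
#'   `overlap_result`) and `n_overlap_total`, the summed overlap count.
#' @export
reciprocal_overlap <- function(a_up, a_down, b_up, b_down, universe) {
  comp1 <- directional_overlap(a_up, b_down, universe)
  comp2 <- directional_overlap(a_down, b_up, universe)
  list(up_a_down_b = comp1,
       down_a_up_b = comp2,
       n_overlap_total = comp1$n_overlap + comp2$n_overlap)
}
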