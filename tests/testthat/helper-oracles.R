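# Independent brute-force oracles, deliberately written as literal
# translations of the definitions and kept free of any package internals.

# Enumerate every maximal run of hits whose internal gaps are all within
# the threshold, then filter by min_hits and enrichment, one hit at a time.
oracle_scan <- function(ordinals, threshold, global_density,
                        min_hits = 3L, min_enrichment = 3,
                        gap_metric = "ordinal", strict = FALSE) {
  out <- list()
  i <- 1L
  n <- length(ordinals)
  while (i <= n) {
    j <- i
    while (j < n) {
      gap <- ordinals[j + 1L] - ordinals[j]
      if (gap_metric == "intervening") gap <- gap - 1L
      joined <- if (strict) gap < threshold else gap <= threshold
      if (!joined) break
      j <- j + 1L
    }
    k <- j - i + 1L
    span <- ordinals[j] - ordinals[i] + 1L
    enr <- (k / span) / global_density
    if (k >= min_hits && enr >= min_enrichment) {
      out[[length(out) + 1L]] <- data.frame(
        start_ordinal = ordinals[i], end_ordinal = ordinals[j],
        n_hits = k, span_genes = span, enrichment = enr)
    }
    i <- j + 1L
  }
  if (length(out) == 0)
    return(data.frame(start_ordinal = integer(0), end_ordinal = integer(0),
                      n_hits = integer(0), span_genes = integer(0),
                      enrichment = numeric(0)))
  do.call(rbind, out)
}

# Step-up BH by its definition: q(i) = min over {j: p_j >= p_i} of
# min(1, p_j * n / rank(j)), rank(j) = #{p <= p_j}.
oracle_bh <- function(p) {
  n <- length(p)
  vapply(p, function(pi) {
    js <- which(p >= pi)
    min(1, min(vapply(js, function(j) p[j] * n / sum(p <= p[j]), numeric(1))))
  }, numeric(1))
}

# Hypergeometric upper tail from first principles.
oracle_hyper_ge <- function(k, n_a, n_b, universe) {
  xs <- k:min(n_a, n_b)
  sum(vapply(xs, function(x)
    choose(n_b, x) * choose(universe - n_b, n_a - x), numeric(1))) /
    choose(universe, n_a)
}
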