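# Small in-code fixtures shared across tests.

# genome with given scaffold sizes; optional bp coordinates
toy_genome <- function(sizes, bp = TRUE) {
  n <- sum(sizes)
  scaff <- rep(sprintf("sc%02d", seq_along(sizes)), sizes)
  ordinal <- unlist(lapply(sizes, function(k) seq_len(k) - 1L))
  df <- data.frame(
    gene_id = sprintf("t%04d", seq_len(n)),
    scaffold = scaff, ordinal = ordinal,
    stringsAsFactors = FALSE)
  if (bp) {
    df$start_bp <- ordinal * 1000L + 1L
    df$end_bp <- ordinal * 1000L + 800L
    df$strand <- "+"
  }
  genome_table(df)
}

# two-condition expression matrix from per-condition replicate matrices
toy_em <- function(control, treatment, gene_ids = NULL) {
  m <- cbind(control, treatment)
  if (is.null(gene_ids)) gene_ids <- sprintf("t%04d", seq_len(nrow(m)))
  colnames(m) <- c(sprintf("control_r%d", seq_len(ncol(control))),
                   sprintf("treatment_r%d", seq_len(ncol(treatment))))
  rownames(m) <- gene_ids
  expression_matrix(m, data.frame(
    sample_id = colnames(m),
    condition = rep(c("control", "treatment"),
                    c(ncol(control), ncol(treatment))),
    replicate = c(seq_len(ncol(control)), seq_len(ncol(treatment)))))
}

# random hit ordinals on a single scaffold of n genes
random_hits <- function(n, k) sort(sample.int(n, k)) - 1L
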