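#' Construct an expression matrix with its design
#'
#' Bundles a strictly positive intensity matrix (genes x samples, linear
#' scale) with the two-condition replicated design describing its columns.
#' Conditions are labelled `"control"` and `"treatment"`; fold changes are
#' always treatment relative to control.
#'
#' @param intensities Numeric matrix, rownames = gene ids, colnames =
#'   sample ids, all values `> 0`.
#' @param design Data frame with columns `sample_id`, `condition`
#'   (`"control"`/`"treatment"`) and `replicate` (integer index within
#'   condition). Every matrix column must have exactly one design row.
#' @return An object of class `expression_matrix`: a list with elements
#'   `intensities` and `design`.
#' @export
expression_matrix <- function(intensities, design) {
  if (!is.matrix(intensities) || !is.numeric(intensities))
    abort("intensities must be a numeric matrix")
  if (is.null(rownames(intensities)) || is.null(colnames(intensities)))
    abort("intensities must have gene ids as rownames and sample ids as colnames")
  bad <- which(!is.finite(intensities) | intensities <= 0)
  if (length(bad) > 0) {
    rows <- unique(rownames(intensities)[(bad - 1L) %% nrow(intensities) + 1L])
    abort("intensities must be strictly positive and finite; offending gene(s): %s",
          id_preview(rows))
  }
  design <- as_tibble(design)
  req <- c("sample_id", "condition", "replicate")
  if (!all(req %in% names(design)))
    abort("design must have columns sample_id, condition, replicate")
  design$sample_id <- as.character(design$sample_id)
  design$condition <- as.character(design$condition)
  design$replicate <- as.integer(design$replicate)
  if (!all(design$condition %in% c("control", "treatment")))
    abort("design conditions must be 'control' or 'treatment'")
  extra <- setdiff(colnames(intensities), design$sample_id)
  if (length(extra) > 0)
    abort("sample(s) absent from design: %s", id_preview(extra))
  orphan <- setdiff(design$sample_id, colnames(intensities))
  if (length(orphan) > 0)
    abort("design sample(s) absent from matrix: %s", id_preview(orphan))
  if (anyDuplicated(design$sample_id))
    abort("duplicate sample_id in design")
  if (length(unique(design$condition)) < 2)
    abort("design must contain both a control and a treatment condition")
  design <- design[match(colnames(intensities), design$sample_id), , drop = FALSE]
  structure(list(intensities = intensities, design = design),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  n_rep <- table(x$design$condition)
  cat(sprintf("Expression matrix: %d genes x %d samples (%s)\n",
              nrow(x$intensities), ncol(x$intensities),
              paste(sprintf("%s n=%d", names(n_rep), as.integer(n_rep)),
                    collapse = ", ")))
  invisible(x)
}

# column indices of one condition
condition_samples <- function(em, condition) {
  which(em$design$condition == condition)
}
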