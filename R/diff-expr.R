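#' Quantile-normalize an intensity matrix
#'
#' Forces every sample's intensity distribution onto the common reference
#' given by the row-wise means of the sorted columns, the standard
#' between-array normalization for single-channel microarrays. Ties within
#' a column are resolved by average-rank interpolation into the reference
#' (tied values stay tied). The operation is idempotent, and on tie-free
#' data every column of the result has the identical sorted value vector.
#'
#' @param em An [expression_matrix()] with at least two samples.
#' @return An [expression_matrix()] with normalized intensities and the
#'   same design.
#' @export
quantile_normalize <- function(em) {
  stopifnot(inherits(em, "expression_matrix"))
  if (ncol(em$intensities) < 2)
    abort("quantile normalization needs at least two samples")
  norm <- limma::normalizeQuantiles(em$intensities, ties = TRUE)
  dimnames(norm) <- dimnames(em$intensities)
  expression_matrix(norm, em$design)
}

#' Replicate-variability (CV) filter
#'
#' Flags genes whose replicate variability is acceptable in *every*
#' condition: the coefficient of variation, `sd(replicates) /
#' mean(replicates)` on the linear intensity scale with the sample
#' (`n - 1`) standard deviation, must not exceed `threshold`. This encodes
#' the common microarray rule of discarding transcripts whose replicate SD
#' exceeds 20% of the mean. A zero or non-finite replicate mean fails the
#' gene with a flagged reason rather than an error.
#'
#' @param em An [expression_matrix()] with `>= 2` replicates per condition.
#' @param threshold Maximum tolerated CV per condition (default 0.20; use
#'   `Inf` to disable the filter).
#' @return A tibble with columns `gene_id`, `cv_control`, `cv_treatment`,
#'   `passes_cv_filter`, `cv_fail_reason`.
#' @export
cv_filter <- function(em, threshold = 0.20) {
  stopifnot(inherits(em, "expression_matrix"))
  if (!is_number(threshold) || threshold < 0) abort("threshold must be >= 0")
  ctrl <- condition_samples(em, "control")
  trt <- condition_samples(em, "treatment")
  if (length(ctrl) < 2 || length(trt) < 2)
    abort("CV filter needs at least two replicates per condition")
  x <- em$intensities
  cv_one <- function(idx) {
    m <- rowMeans(x[, idx, drop = FALSE])
    s <- apply(x[, idx, drop = FALSE], 1L, sd)
    unname(ifelse(is.finite(m) & m != 0, s / m, NA_real_))
  }
  cv_c <- cv_one(ctrl)
  cv_t <- cv_one(trt)
  undefined <- is.na(cv_c) | is.na(cv_t)
  pass <- !undefined & cv_c <= threshold & cv_t <= threshold
  tibble(
    gene_id = rownames(x),
    cv_control = cv_c,
    cv_treatment = cv_t,
    passes_cv_filter = pass,
    cv_fail_reason = ifelse(pass, NA_character_,
                            ifelse(undefined, "zero_or_undefined_mean",
                                   "cv_above_threshold"))
  )
}

#' Per-gene fold change, direction and significance test
#'
#' Fold change is the ratio of the linear-scale condition means, reported
#' as `max(ratio, 1/ratio)` so it is always `>= 1`, with `direction`
#' recording the sign (`"down"` when the treatment mean is lower). The
#' p-value comes from a per-gene test on log2 intensities:
#'
#' * `"moderated"` (default): limma's moderated t statistic
#'   (`lmFit()` + `eBayes()`), which shares variance information across
#'   genes -- the standard choice when each condition has only two or three
#'   replicates.
#' * `"welch"`: Welch's two-sample t-test per gene, with no information
#'   sharing; returns `NA` where the test is undefined (constant values).
#'
#' With fewer than two replicates in a condition the p-value is undefined
#' and reported as `NA` for every gene (such genes can never be selected).
#'
#' @param em An [expression_matrix()], normally quantile-normalized first.
#' @param test `"moderated"` or `"welch"`.
#' @return A tibble with columns `gene_id`, `mean_control`,
#'   `mean_treatment`, `fold_change`, `direction`, `p_value`.
#' @export
fold_and_test <- function(em, test = c("moderated", "welch")) {
  stopifnot(inherits(em, "expression_matrix"))
  test <- match.arg(test)
  x <- em$intensities
  ctrl <- condition_samples(em, "control")
  trt <- condition_samples(em, "treatment")
  m_c <- unname(rowMeans(x[, ctrl, drop = FALSE]))
  m_t <- unname(rowMeans(x[, trt, drop = FALSE]))
  fold <- pmax(m_t / m_c, m_c / m_t)
  direction <- ifelse(m_t < m_c, "down", ifelse(m_t > m_c, "up", "none"))
  if (length(ctrl) < 2 || length(trt) < 2) {
    p <- rep(NA_real_, nrow(x))
  } else if (test == "moderated") {
    lx <- log2(x)
    design <- model.matrix(~ factor(em$design$condition,
                                    levels = c("control", "treatment")))
    # quantile normalization can leave a gene with identical replicate
    # values (tied ranks); eBayes offsets those variances itself, so its
    # warning about them is expected and muffled
    fit <- withCallingHandlers(
      limma::eBayes(limma::lmFit(lx, design)),
      warning = function(w) {
        if (grepl("Zero sample variances", conditionMessage(w)))
          invokeRestart("muffleWarning")
      })
    p <- fit$p.value[, 2L]
  } else {
    lx <- log2(x)
    p <- vapply(seq_len(nrow(lx)), function(i) {
      tryCatch(t.test(lx[i, trt], lx[i, ctrl])$p.value,
               error = function(e) NA_real_)
    }, numeric(1))
  }
  tibble(gene_id = rownames(x), mean_control = m_c, mean_treatment = m_t,
         fold_change = fold, direction = direction, p_value = unname(p))
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up false-discovery-rate adjustment:
#' `q(i) = min over {j: p(j) >= p(i)} of min(1, p(j) * n / rank(j))`.
#' Elementwise `q >= p` and `q` lies in `[0, 1]`. `NA` p-values yield `NA`
#' q-values; values outside `[0, 1]` are an error.
#'
#' @param p Numeric vector of p-values in `[0, 1]` (`NA` allowed).
#' @return Numeric vector of q-values.
#' @export
bh_adjust <- function(p) {
  if (!is.numeric(p)) abort("p-values must be numeric")
  bad <- which(!is.na(p) & (p < 0 | p > 1))
  if (length(bad) > 0)
    abort("p-values outside [0, 1] at position(s): %s", id_preview(bad))
  p.adjust(p, method = "BH")
}

#' Full differential-expression table
#'
#' Runs the selection chain used for replicated two-condition intensity
#' data: optional quantile normalization, replicate-CV filtering,
#' fold-change computation, a per-gene test on log2 intensities and BH FDR
#' adjustment. Thresholding into a final gene list is done separately by
#' [select_regulated()].
#'
#' @inheritParams fold_and_test
#' @param cv_threshold Passed to [cv_filter()]; `Inf` disables the filter.
#' @param normalize Quantile-normalize before filtering and testing
#'   (default `TRUE`).
#' @return A tibble (the DE table) with columns `gene_id`, `mean_control`,
#'   `mean_treatment`, `fold_change`, `direction`, `cv_control`,
#'   `cv_treatment`, `passes_cv_filter`, `cv_fail_reason`, `p_value`,
#'   `q_value`.
#' @export
differential_expression <- function(em, cv_threshold = 0.20,
                                    test = c("moderated", "welch"),
                                    normalize = TRUE) {
  stopifnot(inherits(em, "expression_matrix"))
  test <- match.arg(test)
  if (normalize) em <- quantile_normalize(em)
  n_rep <- table(em$design$condition)
  cv <- if (all(n_rep >= 2)) {
    cv_filter(em, threshold = cv_threshold)
  } else {
    # unreplicated conditions: replicate CV undefined; only a vacuous
    # (infinite) threshold lets genes through
    tibble(gene_id = rownames(em$intensities),
           cv_control = NA_real_, cv_treatment = NA_real_,
           passes_cv_filter = is.infinite(cv_threshold),
           cv_fail_reason = if (is.infinite(cv_threshold)) NA_character_
                            else "insufficient_replicates")
  }
  ft <- fold_and_test(em, test = test)
  stopifnot(identical(cv$gene_id, ft$gene_id))
  out <- tibble(
    gene_id = ft$gene_id,
    mean_control = ft$mean_control,
    mean_treatment = ft$mean_treatment,
    fold_change = ft$fold_change,
    direction = ft$direction,
    cv_control = cv$cv_control,
    cv_treatment = cv$cv_treatment,
    passes_cv_filter = cv$passes_cv_filter,
    cv_fail_reason = cv$cv_fail_reason,
    p_value = ft$p_value,
    q_value = bh_adjust(ft$p_value)
  )
  class(out) <- c("de_table", class(out))
  out
}

#' Select significantly regulated genes
#'
#' Applies the selection thresholds to a DE table: a gene is selected iff
#' it passes the CV filter (when required), its fold change reaches
#' `fold_cut`, its BH q-value is at most `q_cut`, and its direction matches
#' `direction`. Genes with undefined p-values are never selected.
#'
#' @param de A DE table from [differential_expression()].
#' @param fold_cut Minimum fold change (default 2).
#' @param q_cut Maximum BH q-value (default 0.05).
#' @param direction `"down"` (default), `"up"`, or `"any"`.
#' @param use_cv_filter Require `passes_cv_filter` (default `TRUE`).
#' @return A [gene_list()] sorted by gene id; the DE table augmented with
#'   `passes_fold`, `passes_fdr` and `selected` columns is attached as
#'   attribute `"table"`.
#' @export
select_regulated <- function(de, fold_cut = 2, q_cut = 0.05,
                             direction = c("down", "up", "any"),
                             use_cv_filter = TRUE) {
  direction <- match.arg(direction)
  if (!is_number(fold_cut) || fold_cut < 1) abort("fold_cut must be >= 1")
  if (!is_number(q_cut) || q_cut < 0 || q_cut > 1)
    abort("q_cut must lie in [0, 1]")
  de$passes_fold <- !is.na(de$fold_change) & de$fold_change >= fold_cut
  de$passes_fdr <- !is.na(de$q_value) & de$q_value <= q_cut
  dir_ok <- if (direction == "any") de$direction != "none"
            else de$direction == direction
  de$selected <- de$passes_fold & de$passes_fdr & dir_ok &
    (!use_cv_filter | de$passes_cv_filter)
  ids <- sort(de$gene_id[de$selected])
  out <- gene_list(ids, label = sprintf("fold>=%g & q<=%g", fold_cut, q_cut),
                   direction = if (direction == "any") NULL else direction)
  attr(out, "table") <- de
  out
}
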