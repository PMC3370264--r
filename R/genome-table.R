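#' Construct a genome gene-order table
#'
#' A genome table is the coordinate system for all positional scanning: one
#' row per gene, ordered by scaffold and by 0-based ordinal position within
#' the scaffold. Ordinal positions -- a gene's rank in the coordinate-sorted
#' gene list of its scaffold -- are the distance unit of the cluster
#' criterion; base-pair coordinates are optional annotation.
#'
#' @param df A data frame with columns `gene_id`, `scaffold`, `ordinal`
#'   (0-based integer within scaffold) and optionally `start_bp`, `end_bp`
#'   (1-based inclusive), `strand` (`"+"`, `"-"` or `"."`) and `categories`
#'   (a list-column of character vectors, or a character column of
#'   `";"`-separated labels).
#' @return A tibble of class `genome_table`, sorted by scaffold then ordinal.
#' @export
genome_table <- function(df) {
  df <- as_tibble(df)
  required <- c("gene_id", "scaffold", "ordinal")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0)
    abort("genome table lacks required column(s): %s",
          paste(missing_cols, collapse = ", "))
  df$gene_id <- as.character(df$gene_id)
  df$scaffold <- as.character(df$scaffold)
  df$ordinal <- as.integer(df$ordinal)
  if (!"strand" %in% names(df)) df$strand <- "."
  if (!"start_bp" %in% names(df)) df$start_bp <- NA_integer_
  if (!"end_bp" %in% names(df)) df$end_bp <- NA_integer_
  if (!"categories" %in% names(df)) {
    df$categories <- replicate(nrow(df), character(0), simplify = FALSE)
  } else if (!is.list(df$categories) && !is.character(df$categories)) {
    # an all-empty column comes back from TSV as logical NA
    df$categories <- as.character(df$categories)
    df$categories[is.na(df$categories)] <- ""
  }
  if (is.character(df$categories)) {
    df$categories <- lapply(df$categories, function(x) {
      if (is.na(x) || !nzchar(x)) character(0) else strsplit(x, ";", fixed = TRUE)[[1]]
    })
  }
  df <- df[order(df$scaffold, df$ordinal), , drop = FALSE]
  df <- df[, c("gene_id", "scaffold", "ordinal", "start_bp", "end_bp",
               "strand", "categories",
               setdiff(names(df), c("gene_id", "scaffold", "ordinal",
                                    "start_bp", "end_bp", "strand", "categories")))]
  validate_genome_table(df)
  class(df) <- c("genome_table", class(df))
  df
}

#' Validate genome-table invariants
#'
#' Checks that gene ids are unique genome-wide, that ordinals within each
#' scaffold form a contiguous `0..k-1` sequence, and that, where base-pair
#' coordinates are present, `start_bp <= end_bp` and the ordinal order
#' agrees with the `start_bp` order within each scaffold.
#'
#' @param df A data frame laid out as in [genome_table()].
#' @return The input, invisibly; errors name the offending records.
#' @export
validate_genome_table <- function(df) {
  dup <- unique(df$gene_id[duplicated(df$gene_id)])
  if (length(dup) > 0)
    abort("duplicate gene_id(s): %s", id_preview(dup))
  for (sc in unique(df$scaffold)) {
    o <- sort(df$ordinal[df$scaffold == sc])
    if (!identical(o, seq_len(length(o)) - 1L))
      abort("scaffold %s: ordinals are not a contiguous 0..%d sequence",
            sc, length(o) - 1L)
  }
  has_bp <- !is.na(df$start_bp) & !is.na(df$end_bp)
  if (any(has_bp)) {
    bad <- df$gene_id[has_bp & df$start_bp > df$end_bp]
    if (length(bad) > 0)
      abort("start_bp > end_bp for gene(s): %s", id_preview(bad))
    for (sc in unique(df$scaffold[has_bp])) {
      sub <- df[df$scaffold == sc & has_bp, , drop = FALSE]
      sub <- sub[order(sub$ordinal), , drop = FALSE]
      if (is.unsorted(sub$start_bp))
        abort("scaffold %s: ordinal order disagrees with start_bp order", sc)
    }
  }
  if (!all(df$strand %in% c("+", "-", ".", NA)))
    abort("strand values must be one of '+', '-', '.'")
  invisible(df)
}

#' @export
print.genome_table <- function(x, ...) {
  cat(sprintf("Genome table: %d genes on %d scaffold(s)\n",
              nrow(x), length(unique(x$scaffold))))
  tc <- attr(x, "truth_clusters")
  if (!is.null(tc))
    cat(sprintf("  simulated; %d regulated genes, %d planted cluster(s)\n",
                length(attr(x, "truth_regulated")), nrow(tc)))
  NextMethod()
}

#' Ground truth of a simulated genome
#'
#' Accessors for the ground truth recorded by [simulate_genome()]:
#' `truth_clusters()` returns one row per planted cluster (scaffold,
#' ordinal span, member genes); `truth_regulated()` returns the gene ids of
#' all regulated genes (planted plus dispersed).
#'
#' @param genome A `genome_table` produced by [simulate_genome()].
#' @return A tibble (clusters) or character vector (gene ids); errors if
#'   the table carries no ground truth.
#' @export
truth_clusters <- function(genome) {
  tc <- attr(genome, "truth_clusters")
  if (is.null(tc)) abort("genome table carries no planted-cluster ground truth")
  tc
}

#' @rdname truth_clusters
#' @export
truth_regulated <- function(genome) {
  tr <- attr(genome, "truth_regulated")
  if (is.null(tr)) abort("genome table carries no regulated-gene ground truth")
  tr
}

#' Construct a gene list
#'
#' An ordered, duplicate-free set of gene identifiers with an optional label
#' and regulation direction, as used for cluster scanning and overlap
#' analysis.
#'
#' @param ids Character vector of gene ids; duplicates are an error.
#' @param label Free-text label.
#' @param direction Optional, `"up"` or `"down"`.
#' @return A character vector of class `gene_list`.
#' @export
gene_list <- function(ids, label = "", direction = NULL) {
  ids <- as.character(ids)
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0)
    abort("gene list contains duplicate id(s): %s", id_preview(dup))
  if (!is.null(direction))
    direction <- match.arg(direction, c("up", "down"))
  structure(ids, label = label, direction = direction, class = "gene_list")
}

#' @export
print.gene_list <- function(x, ...) {
  lab <- attr(x, "label")
  dir <- attr(x, "direction")
  cat(sprintf("Gene list%s: %d id(s)%s\n",
              if (nzchar(lab %||% "")) paste0(" '", lab, "'") else "",
              length(x),
              if (!is.null(dir)) paste0(" [", dir, "]") else ""))
  if (length(x) > 0) cat(" ", id_preview(unclass(x), 8L), "\n")
  invisible(x)
}
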