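#' Read a genome gene-order table
#'
#' Reads a [genome_table()] from one of three dialects:
#'
#' * `"tsv"`: tab-separated with a header row and `#` comment lines;
#'   requires columns `gene_id`, `scaffold`, `ordinal`, and carries
#'   `start_bp`, `end_bp`, `strand` and `;`-separated `categories` when
#'   present.
#' * `"gff3"`: GFF3 per the v3 specification; only `gene` features are
#'   used, gene ids come from the `ID` attribute, and ordinals are derived
#'   from the coordinate sort within each scaffold with the deterministic
#'   tie-break (`start`, `end`, `gene_id`).
#' * `"bed"`: BED intervals (0-based half-open on disk, converted to
#'   1-based inclusive coordinates); gene ids come from the name field and
#'   ordinals from the coordinate sort as for GFF3.
#'
#' @param path Path to the file.
#' @param format `"tsv"`, `"gff3"` or `"bed"`.
#' @return A validated [genome_table()].
#' @export
read_genome_table <- function(path, format = c("tsv", "gff3", "bed")) {
  format <- match.arg(format)
  if (!file.exists(path)) abort("file not found: %s", path)
  if (format == "tsv") {
    df <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
    return(genome_table(df))
  }
  gr <- as.data.frame(rtracklayer::import(path, format = format))
  if (format == "gff3") {
    gr <- gr[!is.na(gr$type) & gr$type == "gene", , drop = FALSE]
    if (nrow(gr) == 0) abort("no 'gene' features in GFF3 file %s", path)
    ids <- gr$ID
    if (is.null(ids) || anyNA(ids))
      abort("GFF3 gene feature(s) lack an ID attribute in %s", path)
  } else {
    ids <- gr$name
    if (is.null(ids) || anyNA(ids))
      abort("BED record(s) lack a name field in %s", path)
  }
  df <- data.frame(gene_id = as.character(ids),
                   scaffold = as.character(gr$seqnames),
                   start_bp = gr$start, end_bp = gr$end,
                   strand = ifelse(as.character(gr$strand) == "*", ".",
                                   as.character(gr$strand)),
                   stringsAsFactors = FALSE)
  df <- df[order(df$scaffold, df$start_bp, df$end_bp, df$gene_id), , drop = FALSE]
  df$ordinal <- unlist(lapply(split(seq_len(nrow(df)), df$scaffold),
                              function(ix) seq_along(ix) - 1L),
                       use.names = FALSE)
  genome_table(df)
}

#' Write a genome gene-order table as TSV
#'
#' Inverse of `read_genome_table(..., format = "tsv")`: categories are
#' joined with `;`, missing coordinates are written as `NA`.
#'
#' @param genome A [genome_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genome_table <- function(genome, path) {
  stopifnot(inherits(genome, "genome_table"))
  out <- as.data.frame(genome[, c("gene_id", "scaffold", "ordinal",
                                  "start_bp", "end_bp", "strand")])
  out$categories <- vapply(genome$categories, paste, character(1),
                           collapse = ";")
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write the simulation ground truth
#'
#' Serializes the planted clusters and the regulated gene ids of a
#' simulated genome to two TSV/plain-text files kept separate from the
#' analysis inputs.
#'
#' @param genome A simulated [genome_table()].
#' @param path_clusters Output TSV for the planted clusters.
#' @param path_regulated Output text file (one id per line) for the
#'   regulated genes.
#' @return Invisibly, the two paths.
#' @export
write_truth <- function(genome, path_clusters, path_regulated) {
  tc <- truth_clusters(genome)
  out <- as.data.frame(tc[, c("cluster_id", "scaffold", "start_ordinal",
                              "end_ordinal", "span_genes", "n_hits")])
  out$gene_ids <- vapply(tc$gene_ids, paste, character(1), collapse = ";")
  write.table(out, path_clusters, sep = "\t", quote = FALSE, row.names = FALSE)
  write_gene_list(gene_list(truth_regulated(genome), label = "truth_regulated"),
                  path_regulated)
  invisible(c(path_clusters, path_regulated))
}

#' Read an expression matrix with its design
#'
#' The matrix file is TSV with gene ids in the first column (`gene_id`)
#' and one column per sample; the design file is TSV with columns
#' `sample_id`, `condition`, `replicate`. Zero or negative intensities and
#' samples missing from either file are rejected with an error naming the
#' offender.
#'
#' @param path_matrix,path_design Paths to the two TSV files.
#' @return An [expression_matrix()].
#' @export
read_expression <- function(path_matrix, path_design) {
  for (p in c(path_matrix, path_design))
    if (!file.exists(p)) abort("file not found: %s", p)
  mat_df <- read.delim(path_matrix, comment.char = "#",
                       stringsAsFactors = FALSE, check.names = FALSE)
  if (!"gene_id" %in% names(mat_df))
    abort("expression matrix must have a gene_id column")
  m <- as.matrix(mat_df[, setdiff(names(mat_df), "gene_id"), drop = FALSE])
  rownames(m) <- mat_df$gene_id
  design <- read.delim(path_design, comment.char = "#",
                       stringsAsFactors = FALSE)
  expression_matrix(m, design)
}

#' Write an expression matrix and its design as TSV
#'
#' @param em An [expression_matrix()].
#' @param path_matrix,path_design Output paths.
#' @return Invisibly, the two paths.
#' @export
write_expression <- function(em, path_matrix, path_design) {
  stopifnot(inherits(em, "expression_matrix"))
  out <- data.frame(gene_id = rownames(em$intensities),
                    em$intensities, check.names = FALSE)
  write.table(out, path_matrix, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(as.data.frame(em$design), path_design, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(c(path_matrix, path_design))
}

#' Read and write plain-text gene lists
#'
#' One gene id per line; `#` starts a comment, blank lines are ignored.
#' Duplicate ids are an error on reading.
#'
#' @param path Path to the file.
#' @param label Label for the resulting list (default: the file name).
#' @param direction Optional `"up"`/`"down"` annotation.
#' @return `read_gene_list()` returns a [gene_list()];
#'   `write_gene_list()` returns `path` invisibly.
#' @export
read_gene_list <- function(path, label = basename(path), direction = NULL) {
  if (!file.exists(path)) abort("file not found: %s", path)
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  gene_list(lines, label = label, direction = direction)
}

#' @rdname read_gene_list
#' @param x A [gene_list()].
#' @export
write_gene_list <- function(x, path) {
  stopifnot(inherits(x, "gene_list"))
  header <- sprintf("# gene list%s: %d ids",
                    if (nzchar(attr(x, "label") %||% ""))
                      paste0(" '", attr(x, "label"), "'") else "",
                    length(x))
  writeLines(c(header, unclass(x)), path)
  invisible(path)
}

#' Write called clusters as BED6 (or ordinal-space TSV)
#'
#' When every gene in the cluster spans carries base-pair coordinates, one
#' BED6 line is written per cluster: `chrom` = scaffold, `chromStart` =
#' smallest `start_bp - 1` (BED is 0-based half-open), `chromEnd` =
#' largest `end_bp`, `name` = cluster id, `score` =
#' `round(100 * enrichment)` capped at 1000, `strand` = `"."`. Without
#' base-pair coordinates a TSV in ordinal space is written instead. An
#' empty scan yields a file holding only a header comment.
#'
#' @param scan A `scan_result` from [scan_genome()].
#' @param genome The [genome_table()] that was scanned.
#' @param path Output path.
#' @return `path`, invisibly; the chosen dialect is attached as attribute
#'   `"format"` (`"bed"` or `"tsv"`).
#' @export
write_clusters_bed <- function(scan, genome, path) {
  stopifnot(inherits(scan, "scan_result"), inherits(genome, "genome_table"))
  cl <- scan$clusters
  if (nrow(cl) == 0) {
    writeLines("# positional cluster scan: 0 clusters", path)
    return(invisible(structure(path, format = "bed")))
  }
  span_rows <- lapply(seq_len(nrow(cl)), function(i)
    which(genome$scaffold == cl$scaffold[i] &
            genome$ordinal >= cl$start_ordinal[i] &
            genome$ordinal <= cl$end_ordinal[i]))
  have_bp <- all(vapply(span_rows, function(rw)
    !anyNA(genome$start_bp[rw]) && !anyNA(genome$end_bp[rw]), logical(1)))
  if (have_bp) {
    bed <- data.frame(
      chrom = cl$scaffold,
      chromStart = vapply(span_rows, function(rw)
        min(genome$start_bp[rw]) - 1L, numeric(1)),
      chromEnd = vapply(span_rows, function(rw)
        max(genome$end_bp[rw]), numeric(1)),
      name = cl$cluster_id,
      score = pmin(1000, round(100 * cl$enrichment)),
      strand = "."
    )
    write.table(bed, path, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
    fmt <- "bed"
  } else {
    out <- as.data.frame(cl[, c("cluster_id", "scaffold", "start_ordinal",
                                "end_ordinal", "n_hits", "span_genes",
                                "enrichment")])
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
    fmt <- "tsv"
  }
  invisible(structure(path, format = fmt))
}

#' Serialize a scan summary as JSON
#'
#' Writes the global scan summary (counts, spacing, threshold, means,
#' permutation p) plus the per-cluster table to a JSON file.
#'
#' @param scan A `scan_result`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_scan_json <- function(scan, path) {
  stopifnot(inherits(scan, "scan_result"))
  cl <- scan$clusters
  cl$hit_genes <- lapply(cl$hit_genes, identity)
  payload <- list(
    n_total = scan$n_total,
    n_hits = scan$n_hits,
    global_density = scan$global_density,
    expected_spacing = scan$expected_spacing,
    threshold = scan$threshold,
    n_clusters = scan$n_clusters,
    n_scaffolds_with_clusters = scan$n_scaffolds_with_clusters,
    mean_hits_per_cluster = scan$mean_hits_per_cluster,
    mean_span_genes = scan$mean_span_genes,
    mean_enrichment = scan$mean_enrichment,
    permutation_p_n_clusters = scan$permutation_p_n_clusters,
    params = scan$params[c("spacing_divisor", "min_hits", "min_enrichment",
                           "n_permutations", "gap_metric", "strict",
                           "stratified")],
    clusters = cl
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}
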