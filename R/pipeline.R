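#' Configuration of the end-to-end pipeline
#'
#' Bundles the stage settings and a single global seed. The seed is fanned
#' out to the stochastic stages by fixed offsets so stages can be rerun in
#' isolation: genome simulation uses `seed`, expression simulation
#' `seed + 1` (inside [simulate_expression()]), and the permutation test
#' `seed + 2`.
#'
#' @param sim A [simulation_config()]; its own `seed` is overridden by
#'   `seed`.
#' @param scan A [scan_params()]; its `seed` is overridden by `seed + 2`.
#' @param cv_threshold Replicate-CV threshold for [cv_filter()].
#' @param de_test Per-gene test (`"moderated"` or `"welch"`).
#' @param fold_cut,q_cut,direction Selection thresholds for
#'   [select_regulated()].
#' @param seed Global integer seed.
#' @param verbose Log each stage's parameters with [message()].
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = simulation_config(),
                            scan = scan_params(),
                            cv_threshold = 0.20,
                            de_test = c("moderated", "welch"),
                            fold_cut = 2, q_cut = 0.05,
                            direction = "down",
                            seed = 1L, verbose = FALSE) {
  stopifnot(inherits(sim, "simulation_config"), inherits(scan, "scan_params"))
  de_test <- match.arg(de_test)
  if (!is_count(abs(seed))) abort("seed must be an integer")
  sim$seed <- as.integer(seed)
  scan$seed <- as.integer(seed) + 2L
  structure(list(sim = sim, scan = scan, cv_threshold = cv_threshold,
                 de_test = de_test, fold_cut = fold_cut, q_cut = q_cut,
                 direction = direction, seed = as.integer(seed),
                 verbose = isTRUE(verbose)),
            class = "pipeline_config")
}

log_stage <- function(config, fmt, ...) {
  if (isTRUE(config$verbose)) message(sprintf(paste0("[scaffscan] ", fmt), ...))
}

ensure_dir <- function(dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  dir
}

#' Run the simulation stage and write its files
#'
#' Writes `genome.tsv`, `expression.tsv`, `design.tsv`,
#' `truth_clusters.tsv` and `truth_regulated.txt` into `out_dir`.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the simulated `genome` and `expression`
#'   objects and the written `paths`.
#' @export
run_simulate <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  ensure_dir(out_dir)
  log_stage(config, "simulate: %d genes, %d regulated, %d planted clusters, seed %d",
            config$sim$n_genes, config$sim$n_regulated,
            config$sim$n_planted_clusters, config$sim$seed)
  genome <- simulate_genome(config$sim)
  em <- simulate_expression(genome, config$sim)
  paths <- list(
    genome = file.path(out_dir, "genome.tsv"),
    expression = file.path(out_dir, "expression.tsv"),
    design = file.path(out_dir, "design.tsv"),
    truth_clusters = file.path(out_dir, "truth_clusters.tsv"),
    truth_regulated = file.path(out_dir, "truth_regulated.txt")
  )
  write_genome_table(genome, paths$genome)
  write_expression(em, paths$expression, paths$design)
  write_truth(genome, paths$truth_clusters, paths$truth_regulated)
  invisible(list(genome = genome, expression = em, paths = paths))
}

#' Run the differential-expression stage and write its files
#'
#' Writes `de_table.tsv` and `selected_genes.txt` into `out_dir`.
#'
#' @param em An [expression_matrix()].
#' @param config A [pipeline_config()].
#' @param out_dir Output directory.
#' @return Invisibly, a list with the DE `table`, the `selected`
#'   [gene_list()] and the written `paths`.
#' @export
run_de <- function(em, config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  ensure_dir(out_dir)
  log_stage(config, "de: test=%s cv<=%g fold>=%g q<=%g direction=%s",
            config$de_test, config$cv_threshold, config$fold_cut,
            config$q_cut, config$direction)
  de <- differential_expression(em, cv_threshold = config$cv_threshold,
                                test = config$de_test)
  selected <- select_regulated(de, fold_cut = config$fold_cut,
                               q_cut = config$q_cut,
                               direction = config$direction)
  paths <- list(de_table = file.path(out_dir, "de_table.tsv"),
                selected = file.path(out_dir, "selected_genes.txt"))
  write.table(as.data.frame(attr(selected, "table")), paths$de_table,
              sep = "\t", quote = FALSE, row.names = FALSE)
  write_gene_list(selected, paths$selected)
  invisible(list(table = attr(selected, "table"), selected = selected,
                 paths = paths))
}

#' Run the cluster-scan stage and write its files
#'
#' Scans the genome for positional clusters of the hit genes, runs the
#' permutation test, and writes `scan.json` plus `clusters.bed` (or the
#' ordinal-space TSV fallback) into `out_dir`.
#'
#' @param genome A [genome_table()].
#' @param hits A [gene_list()] of hit genes.
#' @param config A [pipeline_config()].
#' @param out_dir Output directory.
#' @return Invisibly, a list with the `scan` result and the written
#'   `paths`.
#' @export
run_scan <- function(genome, hits, config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  ensure_dir(out_dir)
  log_stage(config, "scan: divisor=%g min_hits=%d min_enrichment=%g perms=%d seed=%s",
            config$scan$spacing_divisor, config$scan$min_hits,
            config$scan$min_enrichment, config$scan$n_permutations,
            format(config$scan$seed))
  scan <- scan_genome(genome, hits, config$scan)
  scan <- permutation_test(genome, scan, config$scan)
  paths <- list(scan_json = file.path(out_dir, "scan.json"),
                clusters = file.path(out_dir, "clusters.bed"))
  write_scan_json(scan, paths$scan_json)
  write_clusters_bed(scan, genome, paths$clusters)
  invisible(list(scan = scan, paths = paths))
}

#' Run the overlap stage and write its files
#'
#' Writes `overlap.json` and `shared_genes.txt` into `out_dir`.
#'
#' @param list_a,list_b [gene_list()]s to compare.
#' @param universe Gene universe size.
#' @param config A [pipeline_config()].
#' @param out_dir Output directory.
#' @return Invisibly, a list with the `overlap` result and the written
#'   `paths`.
#' @export
run_overlap <- function(list_a, list_b, universe, config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  ensure_dir(out_dir)
  log_stage(config, "overlap: |A|=%d |B|=%d universe=%d",
            length(list_a), length(list_b), universe)
  ov <- directional_overlap(list_a, list_b, universe)
  paths <- list(overlap_json = file.path(out_dir, "overlap.json"),
                shared = file.path(out_dir, "shared_genes.txt"))
  jsonlite::write_json(ov[c("n_a", "n_b", "n_universe", "n_overlap",
                            "pct_of_a", "pct_of_b", "hypergeometric_p")],
                       paths$overlap_json, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  write_gene_list(gene_list(ov$shared_ids, label = "shared"), paths$shared)
  invisible(list(overlap = ov, paths = paths))
}

#' Run the full pipeline on simulated data
#'
#' Simulates a genome and expression study, selects regulated genes, scans
#' for positional clusters with the permutation test, compares the
#' selected list against the simulation's regulated ground truth, and
#' writes all stage outputs plus `summary.json` into `out_dir`. Given the
#' same configuration (including seed), two runs produce byte-identical
#' reports.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory.
#' @return Invisibly, a list with all stage objects and the summary list.
#' @export
run_all <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  ensure_dir(out_dir)
  sim <- run_simulate(config, out_dir)
  de <- run_de(sim$expression, config, out_dir)
  scan <- run_scan(sim$genome, de$selected, config, out_dir)
  truth <- gene_list(truth_regulated(sim$genome), label = "truth")
  ov <- run_overlap(de$selected, truth, nrow(sim$genome), config, out_dir)
  s <- scan$scan
  summary <- list(
    parameters = list(
      seed = config$seed,
      n_genes = config$sim$n_genes,
      n_scaffolds = config$sim$n_scaffolds,
      n_regulated = config$sim$n_regulated,
      n_planted_clusters = config$sim$n_planted_clusters,
      n_replicates = config$sim$n_replicates,
      noise_sd = config$sim$noise_sd,
      regulated_log2fc = config$sim$regulated_log2fc,
      cv_threshold = config$cv_threshold,
      de_test = config$de_test,
      fold_cut = config$fold_cut,
      q_cut = config$q_cut,
      direction = config$direction,
      spacing_divisor = config$scan$spacing_divisor,
      min_hits = config$scan$min_hits,
      min_enrichment = config$scan$min_enrichment,
      n_permutations = config$scan$n_permutations
    ),
    de = list(n_selected = length(de$selected)),
    scan = list(
      expected_spacing = s$expected_spacing,
      threshold = s$threshold,
      n_clusters = s$n_clusters,
      n_scaffolds_with_clusters = s$n_scaffolds_with_clusters,
      mean_hits_per_cluster = s$mean_hits_per_cluster,
      mean_span_genes = s$mean_span_genes,
      mean_enrichment = s$mean_enrichment,
      permutation_p_n_clusters = s$permutation_p_n_clusters
    ),
    overlap = list(
      n_overlap = ov$overlap$n_overlap,
      pct_of_selected = ov$overlap$pct_of_a,
      pct_of_truth = ov$overlap$pct_of_b,
      hypergeometric_p = ov$overlap$hypergeometric_p
    )
  )
  summary_path <- file.path(out_dir, "summary.json")
  jsonlite::write_json(summary, summary_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, na = "null")
  validate_summary(jsonlite::read_json(summary_path))
  invisible(list(simulate = sim, de = de, scan = scan, overlap = ov,
                 summary = summary, summary_path = summary_path))
}

#' Validate a pipeline summary report
#'
#' Checks a parsed `summary.json` against the shipped structural schema
#' (`inst/schema/summary-schema.json`): required sections, required keys
#' and scalar types.
#'
#' @param x A parsed JSON report (a list, e.g. from
#'   `jsonlite::read_json()`).
#' @return `TRUE` invisibly; errors describe the first violation.
#' @export
validate_summary <- function(x) {
  schema_path <- system.file("schema", "summary-schema.json",
                             package = "scaffscan")
  schema <- jsonlite::read_json(schema_path)
  check_node <- function(node, spec, where) {
    for (key in names(spec$required)) {
      if (!key %in% names(node))
        abort("summary report: missing key '%s' in %s", key, where)
      want <- spec$required[[key]]
      if (identical(want, "object")) next
      val <- node[[key]]
      ok <- switch(want,
                   number = is.null(val) || is.numeric(val),
                   string = is.character(val),
                   FALSE)
      if (!ok)
        abort("summary report: key '%s' in %s must be a %s", key, where, want)
    }
  }
  check_node(x, schema, "top level")
  for (sec in names(schema$sections)) {
    if (!sec %in% names(x))
      abort("summary report: missing section '%s'", sec)
    check_node(x[[sec]], schema$sections[[sec]], sec)
  }
  invisible(TRUE)
}

#' Plot the per-scaffold cluster track of a scan
#'
#' Draws one horizontal track per scaffold (gene-ordinal space) with hit
#' positions as ticks and called cluster spans as filled rectangles -- a
#' quick visual check of where the clusters sit.
#'
#' @param x A `scan_result`.
#' @param genome The [genome_table()] that was scanned.
#' @param hits The hit [gene_list()] (for drawing hit ticks); optional.
#' @param ... Ignored.
#' @return `x`, invisibly.
#' @export
plot.scan_result <- function(x, genome, hits = NULL, ...) {
  stopifnot(inherits(genome, "genome_table"))
  scaffs <- unique(genome$scaffold)
  sizes <- vapply(scaffs, function(sc) sum(genome$scaffold == sc), integer(1))
  n_s <- length(scaffs)
  graphics::plot(NULL, xlim = c(0, max(sizes)), ylim = c(0.5, n_s + 0.5),
                 xlab = "gene ordinal", ylab = "", yaxt = "n",
                 main = sprintf("%d positional cluster(s)", x$n_clusters))
  graphics::axis(2, at = seq_len(n_s), labels = scaffs, las = 2,
                 cex.axis = 0.5)
  for (i in seq_len(n_s)) {
    graphics::segments(0, i, sizes[i] - 1, i, col = "grey70")
    if (!is.null(hits)) {
      o <- genome$ordinal[genome$scaffold == scaffs[i] &
                            genome$gene_id %in% as.character(hits)]
      if (length(o) > 0)
        graphics::segments(o, i - 0.15, o, i + 0.15, col = "grey30")
    }
  }
  cl <- x$clusters
  if (nrow(cl) > 0) {
    yi <- match(cl$scaffold, scaffs)
    graphics::rect(cl$start_ordinal, yi - 0.3, cl$end_ordinal, yi + 0.3,
                   border = "firebrick", col = grDevices::adjustcolor("firebrick", 0.3))
  }
  invisible(x)
}
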