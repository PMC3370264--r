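#' Simulation settings for a synthetic genome and expression study
#'
#' Defines the study conditions that the generator emulates: a fungal-sized
#' genome laid out on scaffolds, a set of regulated (downregulated by
#' default) genes of which a part is concentrated in planted positional
#' clusters, and a replicated two-condition intensity matrix with Gaussian
#' noise on the log2 scale. Defaults mirror the microarray study the scan
#' statistic was designed for: 9143 genes, 769 regulated, two biological
#' replicates per condition, at-least-twofold downregulation.
#'
#' @param n_genes Total number of genes in the genome.
#' @param n_scaffolds Number of scaffolds.
#' @param scaffold_weights Proportions of genes per scaffold, summing to 1
#'   (tolerance 1e-9). Default: proportional to `n_scaffolds:1`, a simple
#'   decreasing size distribution resembling an assembly's scaffold sizes.
#' @param n_regulated Number of regulated (hit) genes.
#' @param n_planted_clusters Number of planted co-regulated clusters.
#' @param cluster_size_range Integer interval; hit genes per planted
#'   cluster are drawn uniformly from it.
#' @param within_cluster_spacing Maximum ordinal gap between consecutive
#'   planted hits within a cluster (1 = adjacent genes).
#' @param n_replicates Biological replicates per condition.
#' @param base_log2_intensity Mean baseline log2 intensity.
#' @param base_log2_sd Between-gene spread (SD) of baseline log2
#'   intensities. Real arrays span several orders of magnitude; a spread
#'   of 2 gives typical intensities between roughly 2^6 and 2^14. A
#'   non-zero spread is also what makes quantile normalization benign:
#'   with identical baselines every regulated gene would sit in the lower
#'   tail of the treatment distribution and normalization would shrink
#'   the planted effect.
#' @param noise_sd Standard deviation of the Gaussian replicate noise on
#'   the log2 scale; must be `>= 0`.
#' @param regulated_log2fc log2 fold change applied to regulated genes in
#'   the treatment condition; negative values (default -2, i.e. fourfold
#'   down) model downregulation.
#' @param category_probs Named numeric vector of per-gene label
#'   probabilities (e.g. `c(CAZyme = 320/9143)`), all in `[0, 1]`.
#' @param category_cluster_enrichment Multiplier applied to
#'   `category_probs` for genes lying inside planted cluster spans (capped
#'   at probability 1), emulating the elevated CAZyme density of the
#'   clustered genome regions. Set to 1 for uniform labelling.
#' @param seed Integer seed; all generator randomness derives from it.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(n_genes = 9143L,
                              n_scaffolds = 40L,
                              scaffold_weights = NULL,
                              n_regulated = 769L,
                              n_planted_clusters = 20L,
                              cluster_size_range = c(6L, 10L),
                              within_cluster_spacing = 2L,
                              n_replicates = 2L,
                              base_log2_intensity = 10,
                              base_log2_sd = 2,
                              noise_sd = 0.25,
                              regulated_log2fc = -2,
                              category_probs = c(CAZyme = 320 / 9143),
                              category_cluster_enrichment = 5,
                              seed = 1L) {
  if (!is_count(n_genes, 1L)) abort("n_genes must be a positive integer")
  if (!is_count(n_scaffolds, 1L)) abort("n_scaffolds must be a positive integer")
  if (!is_count(n_regulated, 0L)) abort("n_regulated must be a non-negative integer")
  if (n_regulated > n_genes) abort("n_regulated must not exceed n_genes")
  if (!is_count(n_planted_clusters, 0L))
    abort("n_planted_clusters must be a non-negative integer")
  if (length(cluster_size_range) != 2L ||
      !is_count(cluster_size_range[1], 2L) ||
      !is_count(cluster_size_range[2], cluster_size_range[1]))
    abort("cluster_size_range must be an increasing pair of integers >= 2")
  if (!is_count(within_cluster_spacing, 1L))
    abort("within_cluster_spacing must be a positive integer")
  if (!is_count(n_replicates, 1L)) abort("n_replicates must be a positive integer")
  if (!is_number(base_log2_sd) || base_log2_sd < 0)
    abort("base_log2_sd must be >= 0")
  if (!is_number(noise_sd) || noise_sd < 0) abort("noise_sd must be >= 0")
  if (!is_number(regulated_log2fc)) abort("regulated_log2fc must be a number")
  if (is.null(scaffold_weights)) {
    scaffold_weights <- rev(seq_len(n_scaffolds)) / sum(seq_len(n_scaffolds))
  }
  if (length(scaffold_weights) != n_scaffolds)
    abort("scaffold_weights must have length n_scaffolds")
  if (any(scaffold_weights < 0) || abs(sum(scaffold_weights) - 1) > 1e-9)
    abort("scaffold_weights must be non-negative and sum to 1 (tolerance 1e-9)")
  if (length(category_probs) > 0 &&
      (is.null(names(category_probs)) || any(!nzchar(names(category_probs)))))
    abort("category_probs must be a named vector")
  if (any(category_probs < 0 | category_probs > 1))
    abort("category probabilities must lie in [0, 1]")
  if (!is_number(category_cluster_enrichment) || category_cluster_enrichment < 0)
    abort("category_cluster_enrichment must be >= 0")
  if (!is_count(abs(seed))) abort("seed must be an integer")
  structure(list(
    n_genes = as.integer(n_genes),
    n_scaffolds = as.integer(n_scaffolds),
    scaffold_weights = scaffold_weights,
    n_regulated = as.integer(n_regulated),
    n_planted_clusters = as.integer(n_planted_clusters),
    cluster_size_range = as.integer(cluster_size_range),
    within_cluster_spacing = as.integer(within_cluster_spacing),
    n_replicates = as.integer(n_replicates),
    base_log2_intensity = base_log2_intensity,
    base_log2_sd = base_log2_sd,
    noise_sd = noise_sd,
    regulated_log2fc = regulated_log2fc,
    category_probs = category_probs,
    category_cluster_enrichment = category_cluster_enrichment,
    seed = as.integer(seed)
  ), class = "simulation_config")
}

# deterministic largest-remainder apportionment of n into shares w
apportion <- function(n, w) {
  raw <- n * w / sum(w)
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

#' Simulate a genome gene-order table with planted co-regulated clusters
#'
#' Lays `n_genes` out on scaffolds (sizes apportioned deterministically from
#' `scaffold_weights`), plants `n_planted_clusters` clusters of regulated
#' genes whose consecutive ordinal gaps are at most
#' `within_cluster_spacing`, places the remaining regulated genes uniformly
#' at random among loci outside the planted spans, and labels genes with
#' categories (e.g. `"CAZyme"`) by independent Bernoulli draws, with the
#' label probability multiplied by `category_cluster_enrichment` inside
#' planted spans.
#'
#' The single RNG stream seeded from `config$seed` is consumed in a fixed,
#' documented order (gene bp layout, cluster sizes, cluster placement,
#' within-cluster gaps, dispersed hits, category labels), so a seed fully
#' determines the genome.
#'
#' @param config A [simulation_config()].
#' @return A [genome_table()] carrying ground-truth attributes accessible
#'   via [truth_clusters()] and [truth_regulated()].
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  n <- config$n_genes
  sizes <- apportion(n, config$scaffold_weights)
  if (config$n_planted_clusters > 0 && all(sizes == 0))
    abort("no scaffold has capacity for planted clusters")
  scaff_names <- sprintf("scaffold_%02d", seq_len(config$n_scaffolds))
  scaffold <- rep(scaff_names, sizes)
  ordinal <- unlist(lapply(sizes, function(k) seq_len(k) - 1L), use.names = FALSE)
  gene_id <- sprintf("g%05d", seq_len(n))

  # bp layout: per-gene length and intergenic gap
  len <- sample(600:4000, n, replace = TRUE)
  gap <- sample(100:1500, n, replace = TRUE)
  start_bp <- integer(n)
  end_bp <- integer(n)
  offset <- cumsum(c(0L, sizes))
  for (s in seq_along(sizes)) {
    idx <- offset[s] + seq_len(sizes[s])
    if (sizes[s] == 0) next
    starts <- cumsum(c(1L, (len[idx] + gap[idx])[-sizes[s]]))
    start_bp[idx] <- starts
    end_bp[idx] <- starts + len[idx] - 1L
  }

  # plant clusters
  k_lo <- config$cluster_size_range[1]
  k_hi <- config$cluster_size_range[2]
  n_cl <- config$n_planted_clusters
  size_pool <- seq.int(k_lo, k_hi)
  cl_sizes <- if (n_cl > 0)
    size_pool[sample.int(length(size_pool), n_cl, replace = TRUE)] else integer(0)
  if (sum(cl_sizes) > config$n_regulated)
    abort("planted clusters demand %d hit genes but n_regulated is only %d",
          sum(cl_sizes), config$n_regulated)
  occupied <- rep(FALSE, n)   # loci inside a planted span (global row index)
  truth <- vector("list", n_cl)
  hit <- rep(FALSE, n)
  for (ci in seq_len(n_cl)) {
    k <- cl_sizes[ci]
    placed <- FALSE
    for (try in seq_len(1000L)) {
      gaps <- sample(seq_len(config$within_cluster_spacing), k - 1L, replace = TRUE)
      span <- sum(gaps) + 1L
      s <- sample.int(config$n_scaffolds, 1L, prob = config$scaffold_weights)
      if (sizes[s] < span) next
      start_o <- sample.int(sizes[s] - span + 1L, 1L) - 1L
      rows <- offset[s] + start_o + seq_len(span)
      # planted spans are kept apart by at least the expected hit spacing,
      # so adjacent planted clusters stay distinct under the usual
      # (spacing / 3) scan threshold
      sep <- max(2L, ceiling(n / max(1L, config$n_regulated)))
      buffer <- c(max(offset[s] + 1L, rows[1] - sep),
                  min(offset[s] + sizes[s], rows[span] + sep))
      if (any(occupied[seq(buffer[1], buffer[2])])) next
      occupied[rows] <- TRUE
      member_rows <- rows[1] + c(0L, cumsum(gaps))
      hit[member_rows] <- TRUE
      truth[[ci]] <- tibble(
        cluster_id = sprintf("PC%02d", ci),
        scaffold = scaff_names[s],
        start_ordinal = start_o,
        end_ordinal = start_o + span - 1L,
        span_genes = span,
        n_hits = k,
        gene_ids = list(gene_id[member_rows])
      )
      placed <- TRUE
      break
    }
    if (!placed)
      abort("could not place planted cluster %d (size %d): demands exceed scaffold capacity",
            ci, k)
  }
  truth <- if (n_cl > 0) do.call(rbind, truth) else
    tibble(cluster_id = character(0), scaffold = character(0),
           start_ordinal = integer(0), end_ordinal = integer(0),
           span_genes = integer(0), n_hits = integer(0), gene_ids = list())

  # dispersed regulated genes: uniform among loci outside planted spans
  n_disp <- config$n_regulated - sum(cl_sizes)
  free <- which(!occupied)
  if (n_disp > length(free))
    abort("n_regulated exceeds the loci available outside planted spans")
  if (n_disp > 0) hit[free[sample.int(length(free), n_disp)]] <- TRUE

  # category labels
  categories <- replicate(n, character(0), simplify = FALSE)
  for (lab in names(config$category_probs)) {
    p <- rep(config$category_probs[[lab]], n)
    p[occupied] <- pmin(1, p[occupied] * config$category_cluster_enrichment)
    drawn <- stats::runif(n) < p
    for (i in which(drawn)) categories[[i]] <- c(categories[[i]], lab)
  }

  gt <- genome_table(tibble(
    gene_id = gene_id, scaffold = scaffold, ordinal = ordinal,
    start_bp = start_bp, end_bp = end_bp, strand = ".",
    categories = categories
  ))
  attr(gt, "truth_clusters") <- truth
  attr(gt, "truth_regulated") <- gene_id[hit]
  attr(gt, "sim_config") <- config
  gt
}

#' Simulate a replicated two-condition expression matrix
#'
#' Log2 intensities are `base_g + effect + noise`, where `base_g` is the
#' gene's baseline (drawn once per gene from
#' `Normal(base_log2_intensity, base_log2_sd)`), `effect` equals
#' `regulated_log2fc` for regulated genes in the treatment condition and 0
#' otherwise, and `noise` is Gaussian with standard deviation `noise_sd`.
#' Intensities are emitted on the linear scale (`2^x`), so they are
#' strictly positive by construction. The RNG is seeded from
#' `config$seed + 1` (a fixed offset from the genome seed) and consumed in
#' a fixed order (baselines, then replicate noise), so a seed fully
#' determines the matrix.
#'
#' @param genome A simulated [genome_table()] (its ground truth defines the
#'   regulated genes).
#' @param config The [simulation_config()] used for the genome.
#' @return An [expression_matrix()] with samples `control_r1, ...,
#'   treatment_r1, ...`.
#' @export
simulate_expression <- function(genome, config) {
  stopifnot(inherits(config, "simulation_config"))
  if (!is_number(config$noise_sd) || config$noise_sd < 0)
    abort("noise_sd must be >= 0")
  regulated <- genome$gene_id %in% truth_regulated(genome)
  set.seed(config$seed + 1L)
  n <- nrow(genome)
  r <- config$n_replicates
  sample_id <- c(sprintf("control_r%d", seq_len(r)),
                 sprintf("treatment_r%d", seq_len(r)))
  condition <- rep(c("control", "treatment"), each = r)
  base <- rnorm(n, mean = config$base_log2_intensity,
                sd = config$base_log2_sd)
  mu <- outer(base, rep(0, 2L * r), `+`)
  mu[regulated, condition == "treatment"] <-
    mu[regulated, condition == "treatment"] + config$regulated_log2fc
  noise <- matrix(rnorm(n * 2L * r, sd = config$noise_sd), nrow = n)
  intensities <- 2 ^ (mu + noise)
  dimnames(intensities) <- list(genome$gene_id, sample_id)
  expression_matrix(intensities,
                    tibble(sample_id = sample_id, condition = condition,
                           replicate = rep(seq_len(r), times = 2L)))
}
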