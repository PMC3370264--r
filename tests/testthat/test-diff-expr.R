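test_that("quantile normalization matches the hand-computed reference", {
  em <- toy_em(matrix(c(1, 3), 2), matrix(c(2, 4), 2))
  qn <- quantile_normalize(em)
  expect_equal(unname(qn$intensities),
               cbind(c(1.5, 3.5), c(1.5, 3.5)))
})

test_that("quantile normalization fixes identical columns and is idempotent", {
  m <- matrix(rep(c(5, 1, 9, 2), 3), ncol = 3)
  em <- toy_em(m[, 1:2, drop = FALSE], m[, 3, drop = FALSE])
  qn <- quantile_normalize(em)
  expect_equal(qn$intensities, em$intensities)

  set.seed(1)
  em2 <- toy_em(matrix(exp(rnorm(40)), 20), matrix(exp(rnorm(40)), 20))
  qn1 <- quantile_normalize(em2)
  qn2 <- quantile_normalize(qn1)
  expect_equal(qn2$intensities, qn1$intensities, tolerance = 1e-12)
  # defining property: all column sorted-value vectors coincide
  sorted <- apply(qn1$intensities, 2, sort)
  expect_true(all(abs(sorted - sorted[, 1]) < 1e-12))
})

test_that("single-sample matrices cannot be quantile-normalized", {
  m <- matrix(1:4, 4, 1, dimnames = list(letters[1:4], "s1"))
  # bypass the two-condition design requirement to hit the sample check
  em <- toy_em(matrix(1:4, 4), matrix(5:8, 4))
  em$intensities <- em$intensities[, 1, drop = FALSE]
  em$design <- em$design[1, ]
  expect_error(quantile_normalize(em), "two samples")
})

test_that("the CV filter applies the per-condition 20% rule", {
  em <- toy_em(rbind(c(100, 100), c(100, 150), c(80, 120)),
               rbind(c(50, 50), c(50, 50), c(50, 50)))
  cv <- cv_filter(em, threshold = 0.20)
  expect_true(cv$passes_cv_filter[1])                  # CV 0 in both
  expect_false(cv$passes_cv_filter[2])                 # control CV 0.283
  expect_equal(cv$cv_control[2], sd(c(100, 150)) / 125)
  expect_equal(cv$cv_fail_reason[2], "cv_above_threshold")
  # a vacuous threshold passes every well-defined gene
  expect_true(all(cv_filter(em, threshold = Inf)$passes_cv_filter))
})

test_that("fold change and direction follow the condition means", {
  em <- toy_em(rbind(c(100, 100), c(30, 30), c(10, 20)),
               rbind(c(25, 25), c(60, 60), c(10, 20)))
  ft <- fold_and_test(em, test = "welch")
  expect_equal(ft$fold_change, c(4, 2, 1))
  expect_identical(ft$direction, c("down", "up", "none"))
})

test_that("welch p-values agree with stats::t.test on log2 intensities", {
  set.seed(7)
  em <- toy_em(matrix(2^rnorm(30, 10), 10), matrix(2^rnorm(30, 10), 10))
  ft <- fold_and_test(em, test = "welch")
  for (i in c(1, 5, 10)) {
    ref <- t.test(log2(em$intensities[i, 4:6]),
                  log2(em$intensities[i, 1:3]))$p.value
    expect_equal(ft$p_value[i], ref)
  }
})

test_that("BH adjustment reproduces hand-computed step-up examples", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))
  expect_error(bh_adjust(c(0.5, 1.2)), "outside")
})

test_that("BH adjustment equals the brute-force step-up definition", {
  set.seed(42)
  for (trial in 1:200) {
    n <- sample.int(50, 1)
    p <- round(runif(n), sample(c(1, 3, 7), 1))  # coarse rounding makes ties
    expect_equal(bh_adjust(p), oracle_bh(p), tolerance = 1e-12)
  }
})

test_that("no replicates means no p-values and no selections", {
  em <- toy_em(matrix(c(100, 50), 2), matrix(c(25, 50), 2))
  ft <- fold_and_test(em)
  expect_true(all(is.na(ft$p_value)))
  de <- differential_expression(em, cv_threshold = Inf, normalize = FALSE)
  sel <- select_regulated(de, use_cv_filter = FALSE)
  expect_length(sel, 0L)
})

test_that("selection flags compose and vacuous thresholds select everything", {
  set.seed(3)
  em <- toy_em(matrix(2^rnorm(40, 10, 0.1), 10),
               matrix(2^rnorm(40, 10, 0.1), 10))
  de <- differential_expression(em, cv_threshold = Inf)
  sel <- select_regulated(de, fold_cut = 1, q_cut = 1, direction = "any",
                          use_cv_filter = FALSE)
  tab <- attr(sel, "table")
  expect_setequal(as.character(sel), tab$gene_id[tab$direction != "none"])
  expect_true(all(tab$selected[match(as.character(sel), tab$gene_id)]))
  # invariant: selected implies all pass flags
  sel2 <- select_regulated(de, fold_cut = 1.05, q_cut = 0.9)
  tab2 <- attr(sel2, "table")
  expect_true(all(!tab2$selected |
                    (tab2$passes_fold & tab2$passes_fdr & tab2$passes_cv_filter)))
  # empty table in, empty list out
  de0 <- de[0, ]
  expect_length(select_regulated(de0), 0L)
})

test_that("full selection chain recovers planted genes at moderate noise", {
  cfg <- simulation_config(n_genes = 2000L, n_scaffolds = 4L,
                           n_regulated = 200L, n_planted_clusters = 5L,
                           cluster_size_range = c(6L, 8L),
                           noise_sd = 0.10, regulated_log2fc = -2,
                           seed = 77L)
  g <- simulate_genome(cfg)
  em <- simulate_expression(g, cfg)
  de <- differential_expression(em, cv_threshold = 0.20)
  sel <- select_regulated(de, fold_cut = 2, q_cut = 0.05, direction = "down")
  truth <- truth_regulated(g)
  recall <- mean(truth %in% as.character(sel))
  false_rate <- if (length(sel) > 0)
    mean(!(as.character(sel) %in% truth)) else 0
  expect_gte(recall, 0.95)
  expect_lte(false_rate, 0.05)
})

test_that("under the global null, few genes reach q <= 0.05", {
  set.seed(2024)
  frac <- replicate(200, {
    em <- toy_em(matrix(2^rnorm(400, 10, 0.25), 100),
                 matrix(2^rnorm(400, 10, 0.25), 100))
    de <- differential_expression(em, cv_threshold = Inf, normalize = FALSE)
    mean(de$q_value <= 0.05, na.rm = TRUE)
  })
  expect_lte(mean(frac), 0.05)
})
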