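test_that("classification: mutation overrides score, strict 42 boundary", {
  clin <- clinical_table(data.frame(
    sample_id = c("A", "B", "C", "D"),
    brca_status = c("mutated", "WT", "WT", "WT")))
  scars <- data.frame(sample_id = c("A", "B", "C", "E"),
                      hrd_sum = c(10, 43, 42, 50))
  g <- classify_samples(clin, scars)
  expect_equal(as.character(g$group[g$sample_id == "A"]), "BRCA_MUT")
  expect_equal(as.character(g$group[g$sample_id == "B"]), "WT_HRD_HIGH")
  expect_equal(as.character(g$group[g$sample_id == "C"]), "WT_HRD_LOW")
  # D lacks a scar score: excluded with a logged reason, not classified
  expect_false("D" %in% g$sample_id)
  excl <- attr(g, "excluded")
  expect_equal(excl$reason[excl$sample_id == "D"], "missing hrd_sum")
  # classification is total on classified samples
  expect_false(anyNA(g$group))
})

test_that("cohort filters apply in order, log counts, and commute", {
  clin <- data.frame(
    sample_id = paste0("S", 1:10),
    brca_status = "WT",
    pam50 = c(rep("LumA", 7), rep("normal-like", 3)),
    subtype = c(rep("ER+/HER2-", 8), "HER2+", "TNBC"),
    stringsAsFactors = FALSE)
  f0 <- filter_cohort(clin, list())
  attr(f0, "filter_log") <- NULL
  expect_identical(f0, clin)
  f1 <- filter_cohort(clin, list(
    list(column = "pam50", op = "!=", value = "normal-like")))
  expect_equal(nrow(f1), 7L)
  expect_equal(attr(f1, "filter_log")$excluded, 3L)
  # rules on disjoint columns commute
  r_a <- list(column = "pam50", op = "!=", value = "normal-like")
  r_b <- list(column = "subtype", op = "==", value = "ER+/HER2-")
  ab <- filter_cohort(clin, list(r_a, r_b))
  ba <- filter_cohort(clin, list(r_b, r_a))
  expect_equal(ab$sample_id, ba$sample_id)
  expect_error(filter_cohort(clin, list(
    list(column = "nope", op = "==", value = 1))), "missing column")
})

test_that("wilcoxon: exact enumeration and approximate agreement", {
  r <- wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$p, 0.1)                    # 2/20 arrangements, two-sided
  same <- wilcoxon_rank_sum(c(1, 5, 9), c(9, 5, 1))
  expect_equal(same$p, 1)
  # exact vs normal approximation within 0.02 at n = 8
  for (s in 1:10) {
    x <- withr::with_seed(s, rnorm(8))
    y <- withr::with_seed(100 + s, rnorm(8))
    p_exact <- wilcoxon_rank_sum(x, y)$p
    p_norm <- suppressWarnings(
      stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value)
    expect_lt(abs(p_exact - p_norm), 0.02)
  }
})

test_that("fisher and chi-square behave on canonical tables", {
  f <- fisher_exact_2x2(matrix(c(2, 0, 0, 2), nrow = 2))
  expect_equal(f$p, 1 / 3)                  # 3 tables share these margins
  ft <- fisher_exact_2x2(t(matrix(c(1, 3, 4, 2), nrow = 2)))
  expect_equal(ft$p, fisher_exact_2x2(matrix(c(1, 3, 4, 2), nrow = 2))$p)
  chi <- chi_square(matrix(c(10, 10, 10, 10), nrow = 2))
  expect_equal(chi$statistic, 0)
  expect_equal(chi$p, 1)
  expect_error(chi_square(matrix(c(0, 0, 5, 5), nrow = 2)), "margins")
  expect_error(fisher_exact_2x2(matrix(c(1.5, 1, 1, 1), nrow = 2)),
               "integers")
})

test_that("pearson: perfect lines and the covariance formula", {
  x <- 1:10
  expect_equal(pearson_r(x, 2 * x + 1)$r, 1)
  expect_equal(pearson_r(x, -x)$r, -1)
  xf <- withr::with_seed(7, rnorm(20))
  yf <- withr::with_seed(8, rnorm(20))
  direct <- sum((xf - mean(xf)) * (yf - mean(yf))) /
    sqrt(sum((xf - mean(xf))^2) * sum((yf - mean(yf))^2))
  expect_equal(pearson_r(xf, yf)$r, direct, tolerance = 1e-12)
  expect_error(pearson_r(rep(1, 5), 1:5), "variance")
})

test_that("group comparisons: pair counts, symmetry, planted shifts", {
  groups <- data.frame(
    sample_id = paste0("S", 1:30),
    group = factor(rep(c("BRCA_MUT", "WT_HRD_HIGH", "WT_HRD_LOW"),
                       each = 10)))
  # a score identical across samples: all pairwise p = 1
  scores <- data.frame(sample_id = paste0("S", 1:30), flat = 5,
                       shifted = c(rep(0, 10), rep(3, 10), rep(0, 10)) +
                         withr::with_seed(9, rnorm(30, sd = 0.3)))
  cmp <- compare_across_groups(scores, groups)
  expect_equal(sum(cmp$variable == "flat"), 3L)    # 3 pairs per score
  expect_true(all(cmp$p[cmp$variable == "flat"] == 1))
  shifted <- cmp[cmp$variable == "shifted", ]
  expect_lt(shifted$p[shifted$group_a == "WT_HRD_HIGH" &
                        shifted$group_b == "WT_HRD_LOW"], 0.001)
  # binary features go through Fisher per pair
  bf <- matrix(c(rep(1, 10), rep(0, 20)), nrow = 1,
               dimnames = list("TP53", paste0("S", 1:30)))
  cmp2 <- compare_across_groups(scores["sample_id"], groups,
                                binary_features = bf)
  expect_equal(sum(cmp2$test == "fisher"), 3L)
})

test_that("planted immune shifts are detected and unshifted scores are not", {
  hits <- 0; false_hits <- 0
  for (s in 1:5) {
    groups <- data.frame(sample_id = paste0("S", 1:100),
                         group = factor(rep(c("WT_HRD_HIGH", "WT_HRD_LOW"),
                                            each = 50)))
    scores <- data.frame(
      sample_id = paste0("S", 1:100),
      immune = c(rep(2, 50), rep(0, 50)) +
        withr::with_seed(300 + s, rnorm(100)),
      unrelated = withr::with_seed(400 + s, rnorm(100)))
    cmp <- compare_across_groups(scores, groups)
    if (cmp$p[cmp$variable == "immune"] < 0.001) hits <- hits + 1
    if (cmp$p[cmp$variable == "unrelated"] < 0.05) {
      false_hits <- false_hits + 1
    }
  }
  expect_equal(hits, 5L)
  expect_lte(false_hits, 1L)
})

test_that("the pipeline is deterministic and recovers planted groups", {
  cfg <- default_cohort_config(40)
  b1 <- run_pipeline(cfg, seed = 5, n_bootstrap = 10, gsea_n_perm = 100)
  b2 <- run_pipeline(cfg, seed = 5, n_bootstrap = 10, gsea_n_perm = 100)
  expect_identical(b1, b2)                  # bit-identical report bundle
  wt <- b1$truth$intended_group != "BRCA_MUT"
  recovered <- as.character(b1$groups$group[
    match(b1$truth$sample_id[wt], b1$groups$sample_id)])
  expect_gte(mean(recovered == b1$truth$intended_group[wt]), 0.99)
  # group sizes in the report sum to the classified cohort size
  expect_equal(sum(unlist(b1$run_info$group_sizes)), nrow(b1$groups))
  # report files are written and re-written identically
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  run_pipeline(cfg, seed = 5, outdir = d1, n_bootstrap = 10,
               gsea_n_perm = 100)
  run_pipeline(cfg, seed = 5, outdir = d2, n_bootstrap = 10,
               gsea_n_perm = 100)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
})
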