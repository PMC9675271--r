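#' Three-group HRD classification
#'
#' Samples with a BRCA1/2 mutation form the `BRCA_MUT` group regardless
#' of score; wild-type samples are split on the HRD sum: strictly above
#' `threshold` (default 42) is `WT_HRD_HIGH`, at or below is
#' `WT_HRD_LOW`. Samples missing either input are excluded and reported
#' via the `excluded` attribute (with reasons), never silently dropped.
#'
#' @param clinical A `clinical_table` (needs `sample_id`, `brca_status`).
#' @param scars Scar-score data frame from [scar_scores()] (needs
#'   `sample_id`, `hrd_sum`).
#' @param threshold Strict HRD-high threshold.
#' @return Data frame `sample_id`, `group` (factor with the three
#'   levels); attribute `excluded` is a data frame of dropped samples and
#'   reasons.
#' @export
classify_samples <- function(clinical, scars, threshold = 42) {
  m <- merge(clinical[, c("sample_id", "brca_status")],
             scars[, c("sample_id", "hrd_sum")],
             by = "sample_id", all.x = TRUE)
  reason <- ifelse(is.na(m$brca_status), "missing brca_status",
                   ifelse(is.na(m$hrd_sum), "missing hrd_sum", NA))
  excluded <- data.frame(sample_id = m$sample_id[!is.na(reason)],
                         reason = reason[!is.na(reason)],
                         stringsAsFactors = FALSE)
  keep <- m[is.na(reason), , drop = FALSE]
  group <- ifelse(keep$brca_status == "mutated", "BRCA_MUT",
                  ifelse(keep$hrd_sum > threshold,
                         "WT_HRD_HIGH", "WT_HRD_LOW"))
  out <- data.frame(sample_id = keep$sample_id,
                    group = factor(group, levels = c("BRCA_MUT",
                                                     "WT_HRD_HIGH",
                                                     "WT_HRD_LOW")),
                    stringsAsFactors = FALSE)
  attr(out, "excluded") <- excluded
  out
}

#' Declarative cohort filters
#'
#' Applies row filters in order, logging per-rule exclusion counts. Each
#' rule is a list with `column`, `op` (`"=="`, `"!="`, `"%in%"`,
#' `"%not_in%"`) and `value`. Referencing a missing column is an error.
#' Typical use: dropping normal-like intrinsic subtypes and restricting
#' to a pathological subtype before any analysis.
#'
#' @param clinical A `clinical_table` (or any data frame).
#' @param rules List of rules; empty list returns the table unchanged.
#' @return Filtered table; attribute `filter_log` records, per rule, the
#'   number of rows excluded.
#' @examples
#' \dontrun{
#' filter_cohort(clin, list(
#'   list(column = "pam50", op = "!=", value = "normal-like"),
#'   list(column = "subtype", op = "==", value = "ER+/HER2-")))
#' }
#' @export
filter_cohort <- function(clinical, rules = list()) {
  log <- data.frame(column = character(), op = character(),
                    value = character(), excluded = integer(),
                    stringsAsFactors = FALSE)
  out <- clinical
  for (rule in rules) {
    stop_if_not(all(c("column", "op", "value") %in% names(rule)),
                "each rule needs column, op and value")
    stop_if_not(rule$column %in% names(out),
                "filter rule references missing column: ", rule$column)
    x <- out[[rule$column]]
    keep <- switch(rule$op,
                   "==" = x == rule$value,
                   "!=" = x != rule$value,
                   "%in%" = x %in% rule$value,
                   "%not_in%" = !(x %in% rule$value),
                   stop("unknown filter op: ", rule$op, call. = FALSE))
    keep[is.na(keep)] <- FALSE
    log <- rbind(log, data.frame(column = rule$column, op = rule$op,
                                 value = paste(rule$value, collapse = ","),
                                 excluded = sum(!keep),
                                 stringsAsFactors = FALSE))
    out <- out[keep, , drop = FALSE]
  }
  rownames(out) <- NULL
  attr(out, "filter_log") <- log
  out
}

#' Two-group and correlation tests
#'
#' Thin, validated fronts over the standard tests used for group
#' comparisons, returning a uniform `comparison_result` row:
#' `wilcoxon_rank_sum()` is the two-sided rank-sum test (exact
#' enumeration when both groups have at most 8 samples and no ties;
#' otherwise the tie-corrected normal approximation with continuity
#' correction); `fisher_exact_2x2()` sums hypergeometric probabilities of
#' tables at most as probable as the observed one; `chi_square()` is the
#' Pearson statistic with `df = (r-1)(c-1)` (zero margins are an error);
#' `pearson_r()` is the correlation coefficient with its two-sided
#' t-test.
#'
#' @param x,y Numeric vectors (for `wilcoxon_rank_sum` the two groups;
#'   for `pearson_r` paired observations, n >= 3, nonzero variance).
#' @param variable Label recorded in the result row.
#' @return One-row data frame: `variable`, `test`, `statistic`, `p`,
#'   plus group summaries (medians/IQRs or `r`).
#' @export
wilcoxon_rank_sum <- function(x, y, variable = "value") {
  stop_if_not(length(x) >= 1L && length(y) >= 1L,
              "both groups must be nonempty")
  exact <- length(x) <= 8L && length(y) <= 8L
  wt <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE,
                                            correct = TRUE))
  p <- if (all(c(x, y) == x[1L])) {
    1        # no rank information at all
  } else if (exact) {
    wilcox_exact_p(x, y)
  } else {
    wt$p.value
  }
  data.frame(variable = variable, test = "wilcoxon",
             statistic = unname(wt$statistic), p = p,
             median_a = stats::median(x), iqr_a = stats::IQR(x),
             median_b = stats::median(y), iqr_b = stats::IQR(y),
             stringsAsFactors = FALSE)
}

#' @param table Matrix of nonnegative integer counts (2x2 for Fisher).
#' @rdname wilcoxon_rank_sum
#' @export
fisher_exact_2x2 <- function(table, variable = "value") {
  table <- as.matrix(table)
  stop_if_not(all(dim(table) == c(2L, 2L)), "Fisher test needs a 2x2 table")
  stop_if_not(all(table >= 0) && all(table == round(table)),
              "counts must be nonnegative integers")
  ft <- stats::fisher.test(table)
  data.frame(variable = variable, test = "fisher",
             statistic = unname(ft$estimate), p = ft$p.value,
             stringsAsFactors = FALSE)
}

#' @rdname wilcoxon_rank_sum
#' @export
chi_square <- function(table, variable = "value") {
  table <- as.matrix(table)
  stop_if_not(all(table >= 0) && all(table == round(table)),
              "counts must be nonnegative integers")
  stop_if_not(all(rowSums(table) > 0) && all(colSums(table) > 0),
              "chi-square test requires nonzero margins")
  ct <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
  data.frame(variable = variable, test = "chi2",
             statistic = unname(ct$statistic), p = ct$p.value,
             stringsAsFactors = FALSE)
}

#' @rdname wilcoxon_rank_sum
#' @export
pearson_r <- function(x, y, variable = "value") {
  stop_if_not(length(x) == length(y) && length(x) >= 3L,
              "need at least 3 paired observations")
  stop_if_not(stats::sd(x) > 0 && stats::sd(y) > 0,
              "zero variance in x or y")
  ct <- stats::cor.test(x, y, method = "pearson")
  data.frame(variable = variable, test = "pearson",
             statistic = unname(ct$estimate), p = ct$p.value,
             r = unname(ct$estimate), stringsAsFactors = FALSE)
}

#' All pairwise group comparisons of a score table
#'
#' For every score column, runs the two-sided Wilcoxon rank-sum test on
#' every pair of groups (raw p-values, matching the convention of
#' annotating figures with unadjusted Wilcoxon p; a Benjamini-Hochberg
#' column is added as a labeled extension). Optionally, a binary
#' feature-by-sample matrix (e.g. driver-gene mutation calls) is compared
#' per feature and group pair with Fisher's exact test. Pairs in which a
#' group has fewer than 2 usable samples are skipped and logged.
#'
#' @param scores Data frame with `sample_id` plus numeric score columns.
#' @param groups Data frame `sample_id`, `group` (from
#'   [classify_samples()]).
#' @param binary_features Optional 0/1 matrix, features x samples.
#' @return Data frame of comparison rows sorted by variable then pair;
#'   attribute `skipped` logs skipped pairs.
#' @export
compare_across_groups <- function(scores, groups, binary_features = NULL) {
  g <- droplevels(as.factor(groups$group))
  stop_if_not(nlevels(g) >= 2L, "need at least two groups")
  levels_ <- levels(g)
  pairs <- utils::combn(levels_, 2L, simplify = FALSE)
  score_cols <- setdiff(names(scores), "sample_id")
  idx <- match(groups$sample_id, scores$sample_id)
  rows <- list()
  skipped <- list()
  for (col in score_cols) {
    v <- scores[[col]][idx]
    for (pr in pairs) {
      xa <- v[g == pr[1L] & !is.na(v)]
      xb <- v[g == pr[2L] & !is.na(v)]
      if (length(xa) < 2L || length(xb) < 2L) {
        skipped[[length(skipped) + 1L]] <-
          data.frame(variable = col, group_a = pr[1L], group_b = pr[2L],
                     reason = "group with < 2 samples",
                     stringsAsFactors = FALSE)
        next
      }
      r <- wilcoxon_rank_sum(xa, xb, variable = col)
      r$group_a <- pr[1L]; r$group_b <- pr[2L]
      rows[[length(rows) + 1L]] <- r
    }
  }
  if (!is.null(binary_features)) {
    for (f in rownames(binary_features)) {
      v <- binary_features[f, groups$sample_id]
      for (pr in pairs) {
        tab <- rbind(c(sum(v[g == pr[1L]] == 1), sum(v[g == pr[1L]] == 0)),
                     c(sum(v[g == pr[2L]] == 1), sum(v[g == pr[2L]] == 0)))
        r <- fisher_exact_2x2(tab, variable = f)
        r <- data.frame(variable = f, test = "fisher",
                        statistic = r$statistic, p = r$p,
                        median_a = NA, iqr_a = NA, median_b = NA, iqr_b = NA,
                        group_a = pr[1L], group_b = pr[2L],
                        stringsAsFactors = FALSE)
        rows[[length(rows) + 1L]] <- r
      }
    }
  }
  stop_if_not(length(rows) > 0L, "no comparable variable/pair combinations")
  out <- do.call(rbind, rows)
  out <- out[order(out$variable, out$group_a, out$group_b), , drop = FALSE]
  out$p_bh <- stats::p.adjust(out$p, "BH")
  rownames(out) <- NULL
  attr(out, "skipped") <- if (length(skipped)) do.call(rbind, skipped) else
    NULL
  out
}

#' Run the full cohort pipeline on a synthetic cohort
#'
#' Orchestrates every stage on a simulated cohort with planted truth:
#' simulation, scar scoring, signature refitting, expression scoring,
#' three-group classification, pairwise group comparisons, preranked
#' GSEA of WT HRD-high vs WT HRD-low (against the marker panels as gene
#' sets), univariate Cox screens of the expression scores, and — when
#' enough events are present — the bootstrap stability-selection
#' protocol. Deterministic given `seed`. With `outdir` set, per-stage
#' TSV/JSON files and a run log (parameters, seed, exclusion counts) are
#' written.
#'
#' @param config Cohort config (see [default_cohort_config()]).
#' @param seed Master seed.
#' @param outdir Optional output directory (created if needed).
#' @param n_bootstrap Bootstraps for the stability stage (default scaled
#'   down from the protocol's 500 to keep the packaged example quick;
#'   the protocol default in [stability_selection()] remains 500).
#' @param gsea_n_perm Permutations for the GSEA stage.
#' @return A named list (report bundle) with elements `truth`, `scars`,
#'   `exposures`, `scores`, `groups`, `comparisons`, `gsea`,
#'   `cox_univariate`, `stability`, `run_info`.
#' @export
run_pipeline <- function(config = default_cohort_config(), seed = 1,
                         outdir = NULL, n_bootstrap = 50,
                         gsea_n_perm = 200) {
  cohort <- simulate_cohort(config, seed = seed)
  scars <- scar_scores(cohort$profiles, cohort$genome,
                       threshold = config$hrd_threshold)
  exposures <- fit_exposures(cohort$catalogs, cohort$dictionary)
  scores <- score_table(cohort$expression, cohort$panels)
  groups <- classify_samples(cohort$clinical, scars,
                             threshold = config$hrd_threshold)
  comparisons <- compare_across_groups(scores, groups)
  # GSEA: WT HRD-high vs WT HRD-low, marker panels as the set collection
  wt_high <- groups$sample_id[groups$group == "WT_HRD_HIGH"]
  wt_low <- groups$sample_id[groups$group == "WT_HRD_LOW"]
  gsea_res <- NULL
  if (length(wt_high) >= 2L && length(wt_low) >= 2L) {
    ranked <- rank_genes(log2_transform(cohort$expression), wt_high, wt_low)
    sets <- cohort$panels
    gsea_res <- gsea(ranked, sets, n_perm = gsea_n_perm,
                     seed = derive_seed(seed, 11))
  }
  # survival: univariate Cox screen of each score, then stability selection
  clin <- cohort$clinical
  covs <- scores[match(clin$sample_id, scores$sample_id),
                 setdiff(names(scores), "sample_id"), drop = FALSE]
  usable <- vapply(covs, function(v) !anyNA(v) && stats::sd(v) > 0, TRUE)
  covs <- covs[, usable, drop = FALSE]
  cox_uni <- do.call(rbind, lapply(names(covs), function(v) {
    fit <- cox_fit(clin$os_time, clin$os_event, covs[, v, drop = FALSE])
    fit$variable <- v
    fit
  }))
  stability <- NULL
  candidates <- cox_uni$variable[cox_uni$p_wald < 0.10]
  if (length(candidates) >= 2L && sum(clin$os_event) >= 10L) {
    stability <- stability_selection(clin$os_time, clin$os_event,
                                     covs[, candidates, drop = FALSE],
                                     n_bootstrap = n_bootstrap,
                                     seed = derive_seed(seed, 12),
                                     n_folds = 5)
  }
  run_info <- list(seed = seed, n = config$n,
                   n_bootstrap = n_bootstrap, gsea_n_perm = gsea_n_perm,
                   hrd_threshold = config$hrd_threshold,
                   excluded = attr(groups, "excluded"),
                   group_sizes = as.list(table(groups$group)))
  bundle <- list(truth = cohort$truth, scars = scars, exposures = exposures,
                 scores = scores, groups = groups,
                 comparisons = comparisons, gsea = gsea_res,
                 cox_univariate = cox_uni, stability = stability,
                 run_info = run_info)
  if (!is.null(outdir)) write_report_bundle(bundle, outdir)
  bundle
}

write_report_bundle <- function(bundle, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  tab <- function(x, name) {
    if (!is.null(x)) write_tsv_plain(as.data.frame(x),
                                     file.path(outdir, name))
  }
  tab(bundle$truth, "truth.tsv")
  tab(bundle$scars, "scar_scores.tsv")
  tab(bundle$exposures, "exposures.tsv")
  tab(bundle$scores, "expression_scores.tsv")
  tab(bundle$groups, "groups.tsv")
  tab(bundle$comparisons, "comparisons.tsv")
  tab(bundle$gsea, "gsea.tsv")
  tab(bundle$cox_univariate, "cox_univariate.tsv")
  tab(bundle$stability, "stability.tsv")
  jsonlite::write_json(bundle$run_info,
                       file.path(outdir, "run_info.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(outdir)
}
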