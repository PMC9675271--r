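#' Rank genes between two sample groups
#'
#' Builds the preranked list feeding GSEA: per gene, the signed
#' difference of group means of log2 expression (group A minus group B),
#' a two-sided Wilcoxon rank-sum p-value, and its Bonferroni-adjusted
#' value. The list is sorted by decreasing mean difference with ties
#' broken by gene symbol (alphabetical), so the ranking is total and
#' reproducible.
#'
#' @param matrix_log2 An `expression_matrix` on the log2 scale.
#' @param group_a,group_b Character vectors of sample ids (each >= 2).
#' @return A `ranked_list` data frame with columns `gene`, `stat`,
#'   `p_value`, `p_bonferroni`, sorted descending by `stat`.
#' @export
rank_genes <- function(matrix_log2, group_a, group_b) {
  stop_if_not(length(group_a) >= 2L && length(group_b) >= 2L,
              "both groups need at least 2 samples")
  stop_if_not(all(c(group_a, group_b) %in% colnames(matrix_log2)),
              "group sample ids must be columns of the matrix")
  a <- unclass(matrix_log2)[, group_a, drop = FALSE]
  b <- unclass(matrix_log2)[, group_b, drop = FALSE]
  stat <- rowMeans(a) - rowMeans(b)
  exact <- ncol(a) <= 8L && ncol(b) <= 8L
  p <- vapply(seq_len(nrow(a)), function(i) {
    if (all(a[i, 1L] == c(a[i, ], b[i, ]))) return(1)
    if (exact) return(wilcox_exact_p(a[i, ], b[i, ]))
    suppressWarnings(
      stats::wilcox.test(a[i, ], b[i, ], exact = FALSE,
                         correct = TRUE)$p.value)
  }, 0)
  out <- data.frame(gene = rownames(matrix_log2), stat = stat,
                    p_value = p,
                    p_bonferroni = stats::p.adjust(p, "bonferroni"),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$stat, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("ranked_list", "data.frame")
  out
}

#' Weighted Kolmogorov-Smirnov enrichment score
#'
#' The classic preranked GSEA running sum: walking down the ranked list,
#' genes in the set add `|stat|^weight_p / sum over set hits of
#' |stat|^weight_p`, genes outside subtract `1 / (N - n_set)`; the
#' enrichment score (ES) is the signed maximum deviation of the running
#' sum from zero. ES lies in `[-1, 1]`, is invariant to positive
#' rescaling of the statistics, and is negated when the list is reversed.
#'
#' @param ranked A `ranked_list` from [rank_genes()] (or any data frame
#'   with `gene` and `stat` sorted descending).
#' @param set A `gene_set`; at least one member must appear in the list.
#' @param weight_p Weighting exponent on `|stat|` (default 1, the
#'   standard weighted scheme).
#' @return A single ES value.
#' @export
gsea_es <- function(ranked, set, weight_p = 1) {
  hit <- ranked$gene %in% set$genes
  stop_if_not(any(hit), "gene set '", set$name,
              "' has no overlap with the ranked list")
  es_from_hits(ranked$stat, hit, weight_p)
}

# Running-sum core shared by gsea_es and the permutation null.
es_from_hits <- function(stat, hit, weight_p) {
  n <- length(stat)
  nh <- sum(hit)
  if (nh == n) return(1)                  # degenerate: no misses possible
  w <- abs(stat)^weight_p
  wh <- sum(w[hit])
  inc <- numeric(n)
  inc[hit] <- if (wh > 0) w[hit] / wh else 1 / nh
  inc[!hit] <- -1 / (n - nh)
  run <- cumsum(inc)
  run[which.max(abs(run))]
}

#' Permutation-based GSEA for one set
#'
#' Draws `n_perm` random gene-label sets of the same size to form the
#' null ES distribution. `NES = ES / mean(|null ES| of matching sign)`;
#' the nominal p-value is `(1 + k) / (1 + m)` where `m` is the number of
#' null ES with the observed sign and `k` how many of those are at least
#' as extreme. If no null ES shares the observed sign the p-value guard
#' `1/(1+0) = 1` applies and the result is flagged (`sign_flagged`).
#'
#' @inheritParams gsea_es
#' @param n_perm Number of gene-label permutations (>= 100).
#' @param seed RNG seed; identical seeds give identical results.
#' @return One-row data frame: `set`, `size`, `es`, `nes`, `p_nominal`,
#'   `sign_flagged`, `leading_edge` (comma-separated genes up to the ES
#'   extremum).
#' @export
gsea_permute <- function(ranked, set, n_perm = 1000, seed = 1,
                         weight_p = 1) {
  stop_if_not(n_perm >= 100, "n_perm must be at least 100")
  hit <- ranked$gene %in% set$genes
  stop_if_not(any(hit), "gene set '", set$name,
              "' has no overlap with the ranked list")
  n <- length(ranked$stat)
  nh <- sum(hit)
  es <- es_from_hits(ranked$stat, hit, weight_p)
  null_es <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      h <- logical(n)
      h[sample.int(n, nh)] <- TRUE
      es_from_hits(ranked$stat, h, weight_p)
    }, 0)
  })
  same <- if (es >= 0) null_es[null_es >= 0] else null_es[null_es < 0]
  flagged <- length(same) == 0L
  nes <- if (flagged) NA_real_ else es / mean(abs(same))
  p <- (1 + sum(abs(same) >= abs(es))) / (1 + length(same))
  le <- leading_edge(ranked, hit, weight_p)
  data.frame(set = set$name, size = nh, es = es, nes = nes, p_nominal = p,
             sign_flagged = flagged,
             leading_edge = paste(le, collapse = ","),
             stringsAsFactors = FALSE)
}

leading_edge <- function(ranked, hit, weight_p) {
  n <- length(ranked$stat)
  nh <- sum(hit)
  if (nh == n) return(ranked$gene)
  w <- abs(ranked$stat)^weight_p
  wh <- sum(w[hit])
  inc <- numeric(n)
  inc[hit] <- if (wh > 0) w[hit] / wh else 1 / nh
  inc[!hit] <- -1 / (n - nh)
  run <- cumsum(inc)
  peak <- which.max(abs(run))
  if (run[peak] >= 0) {
    ranked$gene[hit & seq_len(n) <= peak]
  } else {
    ranked$gene[hit & seq_len(n) >= peak]
  }
}

#' GSEA over a gene-set collection
#'
#' Runs [gsea_permute()] for each set (deterministic per-set child seeds
#' derived from the master seed) and adds Benjamini-Hochberg q-values
#' across the collection. Sets with no overlap are skipped with a
#' warning.
#'
#' @inheritParams gsea_permute
#' @param sets Named list of `gene_set` objects (e.g. a hallmark GMT via
#'   [read_gmt()]).
#' @return Data frame of per-set results sorted by decreasing `nes`,
#'   with a `q_bh` column.
#' @export
gsea <- function(ranked, sets, n_perm = 1000, seed = 1, weight_p = 1) {
  rows <- list()
  for (i in seq_along(sets)) {
    s <- sets[[i]]
    if (!any(ranked$gene %in% s$genes)) {
      warning("gene set '", s$name, "' has no overlap; skipped",
              call. = FALSE)
      next
    }
    rows[[length(rows) + 1L]] <-
      gsea_permute(ranked, s, n_perm = n_perm,
                   seed = derive_seed(seed, i), weight_p = weight_p)
  }
  stop_if_not(length(rows) > 0L, "no gene set overlaps the ranked list")
  out <- do.call(rbind, rows)
  out$q_bh <- stats::p.adjust(out$p_nominal, "BH")
  out <- out[order(-ifelse(is.na(out$nes), -Inf, out$nes)), , drop = FALSE]
  rownames(out) <- NULL
  out
}
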