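#' Log2 transform of an expression matrix
#'
#' All marker-panel scores operate on `log2(x + 1)` of the linear-scale
#' (RSEM-normalized) values, so zeros map to zero and scores of
#' nonnegative data stay nonnegative.
#'
#' @param matrix An `expression_matrix` (nonnegative).
#' @return An `expression_matrix` of log2(x + 1) values.
#' @export
log2_transform <- function(matrix) {
  stop_if_not(all(matrix >= 0), "expression values must be nonnegative")
  out <- log2(unclass(matrix) + 1)
  class(out) <- c("expression_matrix", class(out))
  out
}

#' Marker-panel scores, metagenes, TIL ratio, proliferation
#'
#' A panel score is the arithmetic mean of log2-transformed expression
#' over the panel's marker genes present in the matrix — the estimator
#' used uniformly here for cell-population abundances, the five immune
#' metagenes (IFN-gamma, ICK, CYTOX, Th1, CTL), the four TIL components
#' and the proliferation signature. A score is only defined when at least
#' one marker gene is present; zero overlap yields a missing score with a
#' warning, never a silent zero.
#'
#' The TIL score summarizes infiltration as
#' `(L + M) / (L + M + S + C)` over the lymphoid, myeloid, stromal and
#' cancer panel scores; with nonnegative (post-log2) components it lies in
#' `[0, 1]`, and it is missing whenever a component is missing or the
#' denominator is zero.
#'
#' @param matrix_log2 An `expression_matrix` already on the log2 scale
#'   (see [log2_transform()]).
#' @param panel A `gene_set` of marker genes.
#' @return `panel_score()`: a data frame `sample_id`, `score`, with
#'   attributes `panel` (name) and `n_found` (markers present).
#' @examples
#' panels <- default_marker_panels()
#' @export
panel_score <- function(matrix_log2, panel) {
  found <- intersect(panel$genes, rownames(matrix_log2))
  if (length(found) == 0L) {
    warning("panel '", panel$name, "': no marker genes present; score is NA",
            call. = FALSE)
    score <- rep(NA_real_, ncol(matrix_log2))
  } else {
    sub <- unclass(matrix_log2)[found, , drop = FALSE]
    score <- colMeans(sub)
  }
  out <- data.frame(sample_id = colnames(matrix_log2), score = score,
                    stringsAsFactors = FALSE)
  attr(out, "panel") <- panel$name
  attr(out, "n_found") <- length(found)
  out
}

#' @param lymphoid,myeloid,stromal,cancer The four 10-gene TIL component
#'   panels.
#' @rdname panel_score
#' @export
til_score <- function(matrix_log2, lymphoid, myeloid, stromal, cancer) {
  comp <- lapply(list(L = lymphoid, M = myeloid, S = stromal, C = cancer),
                 function(p) panel_score(matrix_log2, p)$score)
  num <- comp$L + comp$M
  den <- comp$L + comp$M + comp$S + comp$C
  score <- ifelse(is.na(den) | den == 0, NA_real_, num / den)
  data.frame(sample_id = colnames(matrix_log2), score = score,
             stringsAsFactors = FALSE)
}

#' @rdname panel_score
#' @export
proliferation_score <- function(matrix_log2, panel) {
  panel_score(matrix_log2, panel)
}

#' Score a matrix against a collection of panels
#'
#' Computes one column per panel (marker-mean scores), and — when the
#' panel collection contains the four sets named `TIL_lymphoid`,
#' `TIL_myeloid`, `TIL_stromal`, `TIL_cancer` — a `TIL` ratio column.
#'
#' @param matrix An `expression_matrix` on the linear scale (it is log2
#'   transformed internally), or already-log2 values with
#'   `log2_input = TRUE`.
#' @param panels Named list of `gene_set` panels.
#' @param log2_input Set `TRUE` if `matrix` is already log2-transformed.
#' @return A data frame `sample_id` plus one numeric column per score.
#' @export
score_table <- function(matrix, panels, log2_input = FALSE) {
  m <- if (log2_input) matrix else log2_transform(matrix)
  out <- data.frame(sample_id = colnames(m), stringsAsFactors = FALSE)
  for (p in panels) out[[p$name]] <- panel_score(m, p)$score
  til_names <- c("TIL_lymphoid", "TIL_myeloid", "TIL_stromal", "TIL_cancer")
  if (all(til_names %in% names(panels))) {
    out$TIL <- til_score(m, panels$TIL_lymphoid, panels$TIL_myeloid,
                         panels$TIL_stromal, panels$TIL_cancer)$score
  }
  out
}

#' Default marker panels
#'
#' Loads the marker panels shipped under `extdata/panels`: ten
#' cell-population panels (8 immune + 2 stromal), the five metagenes, the
#' four 10-gene TIL component panels, and a proliferation panel. The
#' shipped gene lists are illustrative defaults assembled from widely
#' used lineage markers; they are plain GMT files meant to be replaced by
#' the user's own curated panels.
#'
#' @return Named list of `gene_set` objects.
#' @export
default_marker_panels <- function() {
  dir <- system.file("extdata", "panels", package = "hrdscape",
                     mustWork = TRUE)
  c(read_gmt(file.path(dir, "cell_populations.gmt"), role = "cell_markers"),
    read_gmt(file.path(dir, "metagenes.gmt"), role = "metagene"),
    read_gmt(file.path(dir, "til_panels.gmt"), role = "cell_markers"),
    read_gmt(file.path(dir, "proliferation.gmt"), role = "metagene"))
}
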