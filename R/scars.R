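#' Genomic-scar scores: LOH, TAI, LST and the HRD sum
#'
#' Tumors that cannot repair double-strand breaks by homologous
#' recombination accumulate characteristic chromosomal scars. Three scar
#' counts quantify this from an allele-specific copy-number profile:
#'
#' * **LOH** — sub-chromosomal loss-of-heterozygosity: segments with
#'   `minor_cn = 0` and total copy number > 0, longer than `min_len`
#'   (default 15 Mb) and strictly shorter than their chromosome
#'   (whole-chromosome LOH is excluded).
#' * **TAI** — telomeric allelic imbalance: segments with
#'   `major_cn != minor_cn`, length at least `min_len` (default 11 Mb),
#'   touching a chromosome end (start 0 or end = chromosome length) and
#'   not overlapping the centromere interval.
#' * **LST** — large-scale state transitions: after smoothing away
#'   segments shorter than `smooth_len` (default 3 Mb, each absorbed into
#'   its longer neighbor, ties to the left, then re-merging), breakpoints
#'   between adjacent segments that differ in copy-number state and are
#'   each at least `min_flank` (default 10 Mb) long. Breakpoints falling
#'   inside the centromere interval are not counted unless
#'   `count_centromeric = TRUE`.
#'
#' The HRD sum is `loh + tai + lst`; samples with a sum strictly above
#' `threshold` (default 42) are called HRD-high, a sum of exactly 42 is
#' HRD-low. All length thresholds are parameters so alternative dialects
#' of the rules are reachable without code change.
#'
#' @param profile A merged or unmerged `segment_profile`; scores merge it
#'   first (merging is idempotent).
#' @param genome A `genome_model`.
#' @param min_len Minimum segment length in bp (strict for LOH, inclusive
#'   for TAI).
#' @return Each `*_score()` returns an integer count.
#' @name scar_scores
NULL

#' Merge adjacent segments with identical copy-number state
#'
#' Adjacent segments on the same chromosome carrying the same
#' `(major_cn, minor_cn)` are fused. Idempotent; preserves the tiling.
#' All scar rules operate on merged profiles, since their length clauses
#' refer to maximal constant-state runs.
#'
#' @inheritParams scar_scores
#' @return A `segment_profile` with no equal-state adjacencies.
#' @export
merge_equal_segments <- function(profile) {
  pieces <- lapply(split(seq_len(nrow(profile)), profile$chrom), function(idx) {
    s <- profile[idx, , drop = FALSE]
    s <- s[order(s$start), , drop = FALSE]
    if (nrow(s) > 1L) {
      same <- s$major_cn[-1L] == s$major_cn[-nrow(s)] &
        s$minor_cn[-1L] == s$minor_cn[-nrow(s)]
      run <- cumsum(c(1L, !same))
      s <- data.frame(chrom = s$chrom[!duplicated(run)],
                      start = tapply(s$start, run, min),
                      end = tapply(s$end, run, max),
                      major_cn = s$major_cn[!duplicated(run)],
                      minor_cn = s$minor_cn[!duplicated(run)],
                      stringsAsFactors = FALSE)
    }
    s
  })
  out <- do.call(rbind, pieces)
  out <- out[order(match(out$chrom, unique(profile$chrom)), out$start), ,
             drop = FALSE]
  rownames(out) <- NULL
  attr(out, "sample_id") <- sample_id(profile)
  class(out) <- c("segment_profile", "data.frame")
  out
}

#' @rdname scar_scores
#' @export
loh_score <- function(profile, genome, min_len = 15e6) {
  p <- merge_equal_segments(profile)
  len <- p$end - p$start
  chrlen <- chrom_length(genome, p$chrom)
  sum(p$minor_cn == 0 & p$major_cn > 0 & len > min_len & len < chrlen)
}

#' @rdname scar_scores
#' @export
tai_score <- function(profile, genome, min_len = 11e6) {
  p <- merge_equal_segments(profile)
  n <- 0L
  for (i in seq_len(nrow(p))) {
    if (p$major_cn[i] == p$minor_cn[i]) next
    if (p$end[i] - p$start[i] < min_len) next
    chrlen <- chrom_length(genome, p$chrom[i])
    if (p$start[i] != 0 && p$end[i] != chrlen) next
    cen <- centromere_interval(genome, p$chrom[i])
    if (p$start[i] < cen[2L] && p$end[i] > cen[1L]) next  # overlaps centromere
    n <- n + 1L
  }
  n
}

#' @param min_flank Minimum length of each segment flanking a counted
#'   breakpoint, in bp.
#' @param smooth_len Segments shorter than this are absorbed before
#'   breakpoints are counted, in bp.
#' @param count_centromeric Count breakpoints that fall inside the
#'   centromere interval (default `FALSE`).
#' @rdname scar_scores
#' @export
lst_score <- function(profile, genome, min_flank = 10e6, smooth_len = 3e6,
                      count_centromeric = FALSE) {
  p <- merge_equal_segments(profile)
  n <- 0L
  for (chrom in unique(p$chrom)) {
    s <- smooth_segments(p[p$chrom == chrom, , drop = FALSE], smooth_len)
    if (nrow(s) < 2L) next
    cen <- centromere_interval(genome, chrom)
    lens <- s$end - s$start
    for (i in seq_len(nrow(s) - 1L)) {
      bp <- s$end[i]
      if (!count_centromeric && bp >= cen[1L] && bp <= cen[2L]) next
      if (lens[i] >= min_flank && lens[i + 1L] >= min_flank) n <- n + 1L
    }
  }
  n
}

# Absorb segments shorter than smooth_len into their longer neighbor
# (ties: left neighbor), shortest segment first (ties: leftmost), re-merging
# equal states after each absorption. Single-chromosome data frame in/out.
smooth_segments <- function(s, smooth_len) {
  s <- s[order(s$start), , drop = FALSE]
  repeat {
    if (nrow(s) <= 1L) break
    lens <- s$end - s$start
    short <- which(lens < smooth_len)
    if (length(short) == 0L) break
    i <- short[which.min(lens[short])]
    if (i == 1L) {
      j <- 2L
    } else if (i == nrow(s)) {
      j <- nrow(s) - 1L
    } else {
      j <- if (lens[i - 1L] >= lens[i + 1L]) i - 1L else i + 1L
    }
    # neighbor j annexes segment i's interval
    s$start[j] <- min(s$start[j], s$start[i])
    s$end[j] <- max(s$end[j], s$end[i])
    s <- s[-i, , drop = FALSE]
    # re-merge equal adjacent states
    if (nrow(s) > 1L) {
      same <- s$major_cn[-1L] == s$major_cn[-nrow(s)] &
        s$minor_cn[-1L] == s$minor_cn[-nrow(s)]
      run <- cumsum(c(1L, !same))
      if (anyDuplicated(run)) {
        s <- data.frame(chrom = s$chrom[!duplicated(run)],
                        start = tapply(s$start, run, min),
                        end = tapply(s$end, run, max),
                        major_cn = s$major_cn[!duplicated(run)],
                        minor_cn = s$minor_cn[!duplicated(run)],
                        stringsAsFactors = FALSE)
      }
    }
  }
  rownames(s) <- NULL
  s
}

#' Score one profile or a whole cohort
#'
#' @param profiles A `segment_profile` or a named list of them.
#' @param genome A `genome_model`.
#' @param loh_min_len,tai_min_len,lst_min_flank,lst_smooth_len Length
#'   parameters forwarded to the three component rules (bp).
#' @param threshold HRD-high calling threshold on the sum (strict `>`).
#' @param count_centromeric See [lst_score()].
#' @return A data frame with columns `sample_id`, `loh`, `tai`, `lst`,
#'   `hrd_sum`, `hrd_high`.
#' @examples
#' g <- toy_genome()
#' sim <- simulate_scar_profile(g, k_loh = 2, k_tai = 1, k_lst = 3, seed = 1)
#' scar_scores(sim$profile, g)
#' @export
scar_scores <- function(profiles, genome,
                        loh_min_len = 15e6, tai_min_len = 11e6,
                        lst_min_flank = 10e6, lst_smooth_len = 3e6,
                        threshold = 42, count_centromeric = FALSE) {
  if (inherits(profiles, "segment_profile")) profiles <- list(profiles)
  rows <- lapply(profiles, function(p) {
    m <- merge_equal_segments(p)
    loh <- loh_score(m, genome, min_len = loh_min_len)
    tai <- tai_score(m, genome, min_len = tai_min_len)
    lst <- lst_score(m, genome, min_flank = lst_min_flank,
                     smooth_len = lst_smooth_len,
                     count_centromeric = count_centromeric)
    data.frame(sample_id = sample_id(p), loh = loh, tai = tai, lst = lst,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$hrd_sum <- hrd_sum(out$loh, out$tai, out$lst)
  out$hrd_high <- classify_hrd(out$hrd_sum, threshold = threshold)
  out
}

#' @param loh,tai,lst Nonnegative component counts.
#' @rdname scar_scores
#' @export
hrd_sum <- function(loh, tai, lst) {
  stop_if_not(all(loh >= 0) && all(tai >= 0) && all(lst >= 0),
              "scar components must be nonnegative")
  loh + tai + lst
}

#' @param hrd_sum_value HRD sum(s).
#' @param threshold Strict threshold: sums above it are HRD-high, sums at
#'   or below it (including exactly 42) are HRD-low.
#' @rdname scar_scores
#' @export
classify_hrd <- function(hrd_sum_value, threshold = 42) {
  stop_if_not(all(hrd_sum_value >= 0), "HRD sum must be nonnegative")
  hrd_sum_value > threshold
}
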