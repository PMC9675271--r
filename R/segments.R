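#' Allele-specific copy-number segment profiles
#'
#' A segment profile is the substrate of genomic-scar scoring: one sample's
#' tiling of the genome by segments carrying integer allele-specific copy
#' numbers. Internally a profile is a data frame with columns `chrom`,
#' `start`, `end` (0-based, half-open), `major_cn`, `minor_cn`, plus a
#' `sample_id` attribute. Invariants enforced at construction:
#' `start < end`, `0 <= minor_cn <= major_cn`, every chromosome of the
#' genome model that appears is tiled completely by sorted, non-overlapping
#' segments from 0 to the chromosome length. Complete tiling is required
#' because telomere-touching (the TAI rule) is undefined with gaps.
#'
#' @param sample_id Sample identifier.
#' @param segments Data frame with columns `chrom`, `start`, `end`,
#'   `major_cn`, `minor_cn` in the internal 0-based half-open convention.
#' @param genome A `genome_model` (see [read_genome()]).
#' @return A validated `segment_profile`.
#' @export
segment_profile <- function(sample_id, segments, genome) {
  stop_if_not(is.character(sample_id) && length(sample_id) == 1L &&
                nzchar(sample_id), "sample_id must be a non-empty string")
  need <- c("chrom", "start", "end", "major_cn", "minor_cn")
  missing <- setdiff(need, names(segments))
  stop_if_not(length(missing) == 0L, "missing segment column(s): ",
              paste(missing, collapse = ", "))
  seg <- as.data.frame(segments)[need]
  seg$chrom <- as.character(seg$chrom)
  for (col in c("start", "end", "major_cn", "minor_cn")) {
    seg[[col]] <- as.numeric(seg[[col]])
  }
  unknown <- setdiff(unique(seg$chrom), genome$chrom)
  stop_if_not(length(unknown) == 0L, "sample ", sample_id,
              ": unknown chromosome(s): ", paste(unknown, collapse = ", "))
  stop_if_not(all(seg$start < seg$end),
              "sample ", sample_id, ": segment with start >= end")
  stop_if_not(all(seg$minor_cn >= 0 & seg$minor_cn <= seg$major_cn),
              "sample ", sample_id,
              ": copy numbers must satisfy 0 <= minor_cn <= major_cn")
  stop_if_not(all(seg$major_cn == round(seg$major_cn) &
                    seg$minor_cn == round(seg$minor_cn)),
              "sample ", sample_id, ": copy numbers must be integers")
  # canonical order: chromosome in genome order, then start
  seg <- seg[order(match(seg$chrom, genome$chrom), seg$start), , drop = FALSE]
  rownames(seg) <- NULL
  for (chrom in unique(seg$chrom)) {
    s <- seg[seg$chrom == chrom, , drop = FALSE]
    len <- chrom_length(genome, chrom)
    ok <- s$start[1L] == 0 &&
      s$end[nrow(s)] == len &&
      (nrow(s) == 1L || all(s$start[-1L] == s$end[-nrow(s)]))
    stop_if_not(ok, "sample ", sample_id, ", chromosome ", chrom,
                ": segments must tile [0, ", format(len, scientific = FALSE),
                ") with no gaps or overlaps")
  }
  attr(seg, "sample_id") <- sample_id
  class(seg) <- c("segment_profile", "data.frame")
  seg
}

#' @param x A `segment_profile`.
#' @rdname segment_profile
#' @export
sample_id <- function(x) attr(x, "sample_id")

#' Read and write allele-specific segment tables
#'
#' The on-disk dialect is a headered TSV with columns `sample`, `chrom`,
#' `start`, `end`, `major_cn`, `minor_cn`; coordinates are 1-based and
#' inclusive on both ends (the common SEG convention) and are converted to
#' the internal 0-based half-open convention on read. The reader enforces
#' every profile invariant, naming the offending sample and chromosome on
#' failure; `write_segments()` inverts the conversion so that
#' write-then-read is an identity.
#'
#' @param path TSV path.
#' @param genome A `genome_model` used to validate chromosome names and
#'   complete tiling.
#' @return `read_segments()`: a named list of `segment_profile` objects,
#'   one per sample, in order of first appearance.
#' @export
read_segments <- function(path, genome) {
  df <- read_tsv_strict(path, c("sample", "chrom", "start", "end",
                                "major_cn", "minor_cn"))
  df$start <- as.numeric(df$start) - 1   # 1-based inclusive -> 0-based half-open
  df$end <- as.numeric(df$end)
  samples <- unique(df$sample)
  profiles <- lapply(samples, function(s) {
    segment_profile(s, df[df$sample == s, , drop = FALSE], genome)
  })
  names(profiles) <- samples
  profiles
}

#' @param profiles A named list of `segment_profile` objects (or one).
#' @rdname read_segments
#' @export
write_segments <- function(profiles, path) {
  if (inherits(profiles, "segment_profile")) profiles <- list(profiles)
  rows <- lapply(profiles, function(p) {
    data.frame(sample = sample_id(p), chrom = p$chrom,
               start = format(p$start + 1, scientific = FALSE, trim = TRUE),
               end = format(p$end, scientific = FALSE, trim = TRUE),
               major_cn = p$major_cn, minor_cn = p$minor_cn,
               stringsAsFactors = FALSE)
  })
  write_tsv_plain(do.call(rbind, rows), path)
}
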