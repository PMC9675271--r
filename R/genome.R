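#' Genome models
#'
#' A genome model is a data frame with one row per chromosome and columns
#' `chrom` (unique name), `length` (base pairs), `centromere_start` and
#' `centromere_end` (base pairs, `0 < centromere_start < centromere_end <
#' length`). It supplies the chromosome lengths that define telomeres
#' (positions 0 and `length`) and the centromere interval used by the
#' telomeric-allelic-imbalance and large-scale-transition rules.
#'
#' Two models ship with the package as plain TSV under `extdata`:
#' `genome_toy.tsv`, a 5-chromosome toy genome used throughout the tests,
#' and `genome_hg19_like.tsv`, an approximate 22-autosome table with
#' hg19-scale lengths and centromere bounds. Both are plain files and can
#' be replaced by any table in the same dialect.
#'
#' @param path Path to a genome TSV with columns `chrom`, `length`,
#'   `centromere_start`, `centromere_end`.
#' @return A validated `genome_model` data frame.
#' @examples
#' g <- toy_genome()
#' chrom_length(g, "chr2")
#' @export
read_genome <- function(path) {
  df <- read_tsv_strict(path, c("chrom", "length",
                                "centromere_start", "centromere_end"))
  validate_genome(df)
}

#' @rdname read_genome
#' @export
toy_genome <- function() {
  read_genome(system.file("extdata", "genome_toy.tsv",
                          package = "hrdscape", mustWork = TRUE))
}

#' @rdname read_genome
#' @export
hg19_like_genome <- function() {
  read_genome(system.file("extdata", "genome_hg19_like.tsv",
                          package = "hrdscape", mustWork = TRUE))
}

validate_genome <- function(df) {
  stop_if_not(is.data.frame(df) && nrow(df) > 0L, "empty genome model")
  stop_if_not(!anyDuplicated(df$chrom), "duplicate chromosome names")
  df$chrom <- as.character(df$chrom)
  for (col in c("length", "centromere_start", "centromere_end")) {
    df[[col]] <- as.numeric(df[[col]])
  }
  bad <- !(df$centromere_start > 0 &
             df$centromere_start < df$centromere_end &
             df$centromere_end < df$length)
  stop_if_not(!any(bad), "invalid centromere bounds for chromosome(s): ",
              paste(df$chrom[bad], collapse = ", "))
  class(df) <- c("genome_model", "data.frame")
  df
}

#' @param genome A `genome_model`.
#' @param chrom Chromosome name.
#' @rdname read_genome
#' @export
chrom_length <- function(genome, chrom) {
  i <- match(chrom, genome$chrom)
  stop_if_not(!anyNA(i), "unknown chromosome(s): ",
              paste(chrom[is.na(i)], collapse = ", "))
  genome$length[i]
}

centromere_interval <- function(genome, chrom) {
  i <- match(chrom, genome$chrom)
  stop_if_not(!is.na(i), "unknown chromosome: ", chrom)
  c(genome$centromere_start[i], genome$centromere_end[i])
}
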