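#' The canonical 96 single-base-substitution channels
#'
#' Mutation catalogs and signature dictionaries are indexed by the 96
#' trinucleotide substitution channels in the COSMIC lexicographic order:
#' the six pyrimidine substitution classes `C>A, C>G, C>T, T>A, T>C, T>G`
#' in that order, and within each class the 16 flanking contexts with the
#' 5' base varying slowest (`A, C, G, T`) and the 3' base fastest. Channel
#' names follow the `X[R>A]Y` convention, e.g. `"A[C>A]A"` is the first
#' channel and `"T[T>G]T"` the last.
#'
#' @return Character vector of the 96 channel names, in canonical order.
#' @examples
#' head(sbs96_channels())
#' @export
sbs96_channels <- function() {
  subs <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
  bases <- c("A", "C", "G", "T")
  out <- character(0)
  for (s in subs) {
    for (p5 in bases) {
      for (p3 in bases) {
        out <- c(out, paste0(p5, "[", s, "]", p3))
      }
    }
  }
  out
}
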