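# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# RNG state. All exported stochastic operations route their randomness
# through this so that a given seed is a complete determinism contract.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single non-missing number", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Deterministic child seed derived from a master seed; keeps results
# insensitive to how many draws earlier stages consumed. Stays < 2^31.
derive_seed <- function(seed, index) {
  (as.double(seed) * 48271 + as.double(index) * 65537) %% 2147483647
}

stop_if_not <- function(cond, ...) {
  if (!isTRUE(cond)) stop(..., call. = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Exact two-sided rank-sum p-value by enumeration of all assignments of
# the pooled (mid)ranks to group A; valid with ties, symmetric in groups.
wilcox_exact_p <- function(x, y) {
  r <- rank(c(x, y))
  na <- length(x)
  n <- length(r)
  w_obs <- sum(r[seq_len(na)])
  mu <- na * (n + 1) / 2
  combs <- utils::combn(n, na)
  w_all <- colSums(matrix(r[combs], nrow = na))
  mean(abs(w_all - mu) >= abs(w_obs - mu) - 1e-9)
}

read_tsv_strict <- function(path, required = character()) {
  stop_if_not(file.exists(path), "file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE,
                          quote = "", comment.char = "")
  missing <- setdiff(required, names(df))
  stop_if_not(length(missing) == 0L,
              "missing column(s) in ", path, ": ",
              paste(missing, collapse = ", "))
  df
}

write_tsv_plain <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
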