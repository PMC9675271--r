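#' Mutation catalogs over the 96 substitution channels
#'
#' A catalog set is an integer matrix with one row per sample and the 96
#' canonical channels (see [sbs96_channels()]) as columns; all counts are
#' nonnegative. On disk: headered TSV with a `sample` column followed by
#' the 96 channel columns in canonical order.
#'
#' @param counts Matrix (or coercible) of nonnegative counts, samples in
#'   rows; columns must be the 96 canonical channels (reordered if needed).
#' @return A validated `catalog96` matrix.
#' @export
catalog96 <- function(counts) {
  m <- as.matrix(counts)
  chans <- sbs96_channels()
  stop_if_not(ncol(m) == 96L, "catalog must have 96 channel columns")
  if (!is.null(colnames(m))) {
    stop_if_not(setequal(colnames(m), chans),
                "catalog columns must be the 96 canonical channels")
    m <- m[, chans, drop = FALSE]
  } else {
    colnames(m) <- chans
  }
  stop_if_not(!is.null(rownames(m)) && !anyDuplicated(rownames(m)),
              "catalog rows must carry unique sample ids")
  stop_if_not(all(is.finite(m)) && all(m >= 0),
              "catalog counts must be nonnegative")
  stop_if_not(all(m == round(m)), "catalog counts must be integers")
  storage.mode(m) <- "double"
  class(m) <- c("catalog96", class(m))
  m
}

#' @param path TSV path.
#' @rdname catalog96
#' @export
read_catalog96 <- function(path) {
  df <- read_tsv_strict(path, "sample")
  stop_if_not(!anyDuplicated(df$sample), "duplicate sample ids in ", path)
  m <- as.matrix(df[setdiff(names(df), "sample")])
  rownames(m) <- df$sample
  catalog96(m)
}

#' @param catalog A `catalog96`.
#' @rdname catalog96
#' @export
write_catalog96 <- function(catalog, path) {
  df <- data.frame(sample = rownames(catalog), unclass(catalog),
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv_plain(df, path)
}

#' Signature dictionaries
#'
#' A signature dictionary maps signature names to 96-channel frequency
#' vectors, each summing to 1 (checked to 1e-8). Internally a matrix with
#' signatures in rows and the canonical channels as columns. The reader
#' accepts both orientations: rows-as-signatures (a `signature` column
#' followed by channel columns) and the COSMIC layout (rows are channels,
#' columns are signatures), detected from the header.
#'
#' @param freqs Matrix of per-channel frequencies, signatures in rows.
#' @return A validated `signature_dictionary` matrix.
#' @export
signature_dictionary <- function(freqs) {
  m <- as.matrix(freqs)
  chans <- sbs96_channels()
  stop_if_not(ncol(m) == 96L && setequal(colnames(m), chans),
              "dictionary columns must be the 96 canonical channels")
  m <- m[, chans, drop = FALSE]
  stop_if_not(!is.null(rownames(m)) && !anyDuplicated(rownames(m)),
              "signature names must be unique")
  stop_if_not(all(is.finite(m)) && all(m >= 0),
              "signature frequencies must be nonnegative")
  sums <- rowSums(m)
  stop_if_not(all(abs(sums - 1) < 1e-8),
              "each signature must sum to 1 (tolerance 1e-8); offending: ",
              paste(rownames(m)[abs(sums - 1) >= 1e-8], collapse = ", "))
  class(m) <- c("signature_dictionary", class(m))
  m
}

#' @param path TSV path (either orientation).
#' @rdname signature_dictionary
#' @export
read_signature_dictionary <- function(path) {
  df <- read_tsv_strict(path)
  chans <- sbs96_channels()
  if ("signature" %in% names(df)) {
    m <- as.matrix(df[setdiff(names(df), "signature")])
    rownames(m) <- df$signature
  } else {
    # COSMIC layout: first column holds channel names, rest are signatures
    key <- names(df)[1L]
    stop_if_not(setequal(df[[key]], chans),
                "first column of ", path,
                " must hold the 96 canonical channel names")
    m <- t(as.matrix(df[setdiff(names(df), key)]))
    colnames(m) <- df[[key]]
  }
  signature_dictionary(m)
}

#' @param dictionary A `signature_dictionary`.
#' @rdname signature_dictionary
#' @export
write_signature_dictionary <- function(dictionary, path) {
  df <- data.frame(signature = rownames(dictionary), unclass(dictionary),
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv_plain(df, path)
}

#' Expression matrices
#'
#' Nonnegative gene-by-sample values on the linear (RSEM-normalized)
#' scale; gene symbols and sample ids are unique. On disk: headered TSV
#' with a `gene` column followed by one column per sample.
#'
#' @param values Numeric matrix, genes in rows, samples in columns.
#' @return A validated `expression_matrix`.
#' @export
expression_matrix <- function(values) {
  m <- as.matrix(values)
  stop_if_not(!is.null(rownames(m)) && !anyDuplicated(rownames(m)),
              "gene symbols must be unique rownames")
  stop_if_not(!is.null(colnames(m)) && !anyDuplicated(colnames(m)),
              "sample ids must be unique colnames")
  stop_if_not(all(is.finite(m)) && all(m >= 0),
              "expression values must be nonnegative and finite")
  class(m) <- c("expression_matrix", class(m))
  m
}

#' @param path TSV path.
#' @rdname expression_matrix
#' @export
read_expression <- function(path) {
  df <- read_tsv_strict(path, "gene")
  stop_if_not(!anyDuplicated(df$gene), "duplicate gene symbols in ", path)
  m <- as.matrix(df[setdiff(names(df), "gene")])
  rownames(m) <- df$gene
  expression_matrix(m)
}

#' @param matrix An `expression_matrix`.
#' @rdname expression_matrix
#' @export
write_expression <- function(matrix, path) {
  df <- data.frame(gene = rownames(matrix), unclass(matrix),
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv_plain(df, path)
}

#' Clinical tables
#'
#' Per-sample clinical records: `sample_id`, `brca_status` (one of
#' `"mutated"`/`"WT"`), optional `pam50`, `subtype`, `t_stage`, `n_stage`,
#' survival endpoints (`os_time`/`os_event`, `pfi_time`/`pfi_event`; times
#' in months, events in 0/1), `tmb`, and arbitrary numeric covariates.
#'
#' @param df Data frame of clinical records.
#' @return Validated `clinical_table` data frame.
#' @export
clinical_table <- function(df) {
  stop_if_not(all(c("sample_id", "brca_status") %in% names(df)),
              "clinical table needs sample_id and brca_status columns")
  stop_if_not(!anyDuplicated(df$sample_id), "duplicate sample ids")
  stop_if_not(!anyNA(df$brca_status) &&
                all(df$brca_status %in% c("mutated", "WT")),
              "brca_status must be 'mutated' or 'WT' for every sample")
  for (ep in c("os", "pfi")) {
    tcol <- paste0(ep, "_time"); ecol <- paste0(ep, "_event")
    if (tcol %in% names(df)) {
      stop_if_not(all(df[[tcol]] >= 0, na.rm = TRUE),
                  tcol, " must be nonnegative")
    }
    if (ecol %in% names(df)) {
      stop_if_not(all(df[[ecol]] %in% c(0, 1) | is.na(df[[ecol]])),
                  ecol, " must be 0/1")
    }
  }
  df <- as.data.frame(df)
  rownames(df) <- NULL
  class(df) <- c("clinical_table", "data.frame")
  df
}

#' @param path TSV path.
#' @rdname clinical_table
#' @export
read_clinical <- function(path) {
  clinical_table(read_tsv_strict(path, c("sample_id", "brca_status")))
}

#' @param table A `clinical_table`.
#' @rdname clinical_table
#' @export
write_clinical <- function(table, path) {
  write_tsv_plain(as.data.frame(table), path)
}

#' Gene sets and marker panels (GMT format)
#'
#' Standard GMT: one set per line, tab-separated `name`, `description`,
#' then gene symbols. Lines with fewer than one gene are rejected; genes
#' must be unique within a set. A marker panel is simply a gene set whose
#' role is to mark a cell population, metagene, or pathway.
#'
#' @param name Set name.
#' @param genes Character vector of gene symbols (unique, nonempty).
#' @param description Free-text description (GMT second field).
#' @param role Optional role tag, e.g. `"hallmark"`, `"cell_markers"`,
#'   `"metagene"`.
#' @return A `gene_set` list with elements `name`, `description`, `genes`,
#'   `role`; `read_gmt()` returns a named list of them.
#' @export
gene_set <- function(name, genes, description = "", role = "gene_set") {
  stop_if_not(is.character(name) && length(name) == 1L && nzchar(name),
              "gene set name must be a non-empty string")
  stop_if_not(length(genes) >= 1L, "gene set '", name, "' is empty")
  stop_if_not(!anyDuplicated(genes),
              "gene set '", name, "' has duplicate genes")
  structure(list(name = name, description = description,
                 genes = as.character(genes), role = role),
            class = "gene_set")
}

#' @param path GMT path.
#' @rdname gene_set
#' @export
read_gmt <- function(path, role = "gene_set") {
  stop_if_not(file.exists(path), "file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(line) {
    parts <- strsplit(line, "\t", fixed = TRUE)[[1L]]
    stop_if_not(length(parts) >= 3L,
                "GMT line with fewer than one gene: ", parts[1L])
    gene_set(parts[1L], parts[-(1:2)], description = parts[2L], role = role)
  })
  names(sets) <- vapply(sets, `[[`, "", "name")
  stop_if_not(!anyDuplicated(names(sets)), "duplicate set names in ", path)
  sets
}

#' @param sets A list of `gene_set` objects.
#' @rdname gene_set
#' @export
write_gmt <- function(sets, path) {
  if (inherits(sets, "gene_set")) sets <- list(sets)
  lines <- vapply(sets, function(s) {
    paste(c(s$name, s$description, s$genes), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}
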