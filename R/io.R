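# Gzip detected by magic bytes so plain and .gz sidecars both work.
is_gzipped <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", n = 2L)
  length(magic) == 2L && magic[1] == as.raw(0x1f) && magic[2] == as.raw(0x8b)
}

open_text <- function(path) {
  if (is_gzipped(path)) gzfile(path, "rt") else file(path, "rt")
}

read_sidecar <- function(path, what) {
  con <- open_text(path)
  on.exit(close(con))
  lines <- readLines(con)
  if (length(lines) == 0L) return(character())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  # 10x 'genes'/'features' sidecars carry id<TAB>symbol[<TAB>type]; the
  # pipeline is symbol-keyed, so prefer the second column when present.
  if (what == "genes" && all(lengths(fields) >= 2L)) {
    vapply(fields, `[[`, character(1), 2L)
  } else {
    vapply(fields, `[[`, character(1), 1L)
  }
}

#' Read a 10x-style MatrixMarket triplet into a `cell_matrix`
#'
#' Reads a MatrixMarket coordinate file plus gene and barcode sidecar TSVs
#' (the 10x Genomics `matrix.mtx` / `genes.tsv` (or `features.tsv`) /
#' `barcodes.tsv` convention; gene sidecars with an id column use the symbol
#' column). All three files may be gzipped. The result is oriented genes
#' as rows, cells as columns, on the `raw` layer.
#'
#' @param matrix_path Path to the MatrixMarket coordinate file.
#' @param genes_path,barcodes_path Sidecar TSVs matching the matrix rows
#'   and columns respectively.
#' @return A `cell_matrix` with `layer = "raw"`.
#' @export
read_counts_mtx <- function(matrix_path, genes_path, barcodes_path) {
  for (p in c(matrix_path, genes_path, barcodes_path)) {
    if (!file.exists(p)) abort(paste0("file not found: ", p))
  }
  m <- if (is_gzipped(matrix_path)) {
    Matrix::readMM(gzfile(matrix_path))
  } else {
    Matrix::readMM(matrix_path)
  }
  g <- read_sidecar(genes_path, "genes")
  b <- read_sidecar(barcodes_path, "barcodes")
  if (nrow(m) != length(g)) {
    abort(sprintf("matrix declares %d rows but gene sidecar has %d entries",
                  nrow(m), length(g)))
  }
  if (ncol(m) != length(b)) {
    abort(sprintf("matrix declares %d columns but barcode sidecar has %d entries",
                  ncol(m), length(b)))
  }
  dimnames(m) <- list(g, b)
  cell_matrix(m, layer = "raw")
}

#' Read a dense count table into a `cell_matrix`
#'
#' @param path Rectangular TSV or CSV (by extension; gzip by magic bytes)
#'   with a header row and identifiers in the first column.
#' @param orientation `"genes-by-cells"` (default) when rows are genes, or
#'   `"cells-by-genes"` when rows are cells; the result is always canonical
#'   genes-by-cells.
#' @return A `cell_matrix` with `layer = "raw"`.
#' @export
read_counts_dense <- function(path,
                              orientation = c("genes-by-cells", "cells-by-genes")) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  sep <- if (grepl("\\.csv(\\.gz)?$", path)) "," else "\t"
  con <- open_text(path)
  on.exit(close(con))
  df <- tryCatch(
    read.delim(con, sep = sep, header = TRUE, check.names = FALSE,
               stringsAsFactors = FALSE, fill = FALSE),
    error = function(e) abort(paste0("malformed table (ragged rows?): ",
                                     conditionMessage(e)))
  )
  ids <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- ids
  if (orientation == "cells-by-genes") m <- base::t(m)
  cell_matrix(m, layer = "raw")
}

#' Write per-cell call/score tables to CSV
#'
#' Writes the standard calls CSV with columns `barcode`, `rho_max`,
#' `total_immune_expression`, `linear_score`, `is_immune`,
#' `signature_type`, `category`, `tcell_subtype` (blank when not
#' applicable). Accepts either a score table ([score_cells()]) or a full
#' call table ([annotate_cells()]); missing annotation columns are emitted
#' blank.
#'
#' @param calls A tibble of per-cell results.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_calls <- function(calls, path) {
  cols <- c("barcode", "rho_max", "total_immune_expression", "linear_score",
            "is_immune", "signature_type", "category", "tcell_subtype")
  out <- tibble::as_tibble(calls)
  for (col in setdiff(cols, names(out))) out[[col]] <- NA_character_
  out <- out[, cols]
  out$tcell_subtype[is.na(out$tcell_subtype)] <- ""
  readr::write_csv(out, path, na = "")
  invisible(path)
}

#' @rdname write_calls
#' @export
read_calls <- function(path) {
  readr::read_csv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    barcode = readr::col_character(),
                    rho_max = readr::col_double(),
                    total_immune_expression = readr::col_double(),
                    linear_score = readr::col_double(),
                    is_immune = readr::col_logical(),
                    signature_type = readr::col_character(),
                    category = readr::col_character(),
                    tcell_subtype = readr::col_character()
                  ))
}

#' Write a `cell_matrix` as a MatrixMarket triplet with sidecars
#'
#' @param m A `cell_matrix`.
#' @param dir Output directory (created if absent); writes `matrix.mtx`,
#'   `genes.tsv`, `barcodes.tsv`.
#' @return `dir`, invisibly.
#' @export
write_counts_mtx <- function(m, dir) {
  stopifnot(inherits(m, "cell_matrix"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(m$counts, file.path(dir, "matrix.mtx"))
  writeLines(genes(m), file.path(dir, "genes.tsv"))
  writeLines(barcodes(m), file.path(dir, "barcodes.tsv"))
  invisible(dir)
}

#' Read a per-cell label/annotation table
#'
#' @param path TSV with a `barcode` column and any subset of `cell_type`,
#'   `is_immune`, `sample`, `group`.
#' @return A tibble keyed by unique `barcode`.
#' @export
read_labels <- function(path) {
  df <- tibble::as_tibble(read.delim(path, header = TRUE,
                                     stringsAsFactors = FALSE))
  if (!"barcode" %in% names(df)) abort("label table needs a 'barcode' column")
  if (anyDuplicated(df$barcode)) abort("duplicate barcodes in label table")
  df
}
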