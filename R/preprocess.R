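#' Quality filter: drop low-count cells
#'
#' Removes cells whose total raw count is below `min_total`; a cell with
#' total exactly `min_total` is retained. Gene set and barcode order are
#' unchanged. Idempotent.
#'
#' @param m A `cell_matrix` on the `raw` layer.
#' @param min_total Minimum total count per cell (default 500).
#' @return A filtered `cell_matrix`, still on the `raw` layer.
#' @export
filter_cells <- function(m, min_total = 500) {
  stopifnot(inherits(m, "cell_matrix"))
  if (m$layer != "raw") abort("filter_cells expects the raw layer")
  if (min_total < 0) abort("min_total must be >= 0")
  keep <- Matrix::colSums(m$counts) >= min_total
  out <- m
  out$counts <- m$counts[, keep, drop = FALSE]
  out
}

#' Total-count normalization
#'
#' Scales each cell so its total equals `scale` (default 10,000), turning
#' entries into relative expression on a common per-cell budget. Sparsity
#' pattern per cell is unchanged. Cells with zero total are a precondition
#' violation: filter first.
#'
#' @param m A `cell_matrix` on the `raw` layer.
#' @param scale Target per-cell total (default 10,000).
#' @return A `cell_matrix` on the `normalized` layer.
#' @export
normalize_cells <- function(m, scale = 10000) {
  stopifnot(inherits(m, "cell_matrix"))
  if (scale <= 0) abort("scale must be > 0")
  totals <- Matrix::colSums(m$counts)
  if (any(totals == 0)) {
    abort("zero-total cell(s) present; run filter_cells() first")
  }
  out <- m
  out$counts <- m$counts %*% Matrix::Diagonal(x = scale / totals)
  dimnames(out$counts) <- dimnames(m$counts)
  out$counts <- methods::as(out$counts, "CsparseMatrix")
  out$layer <- "normalized"
  out
}

#' Log-normalization
#'
#' Entrywise natural-log `log1p` of the normalized values (the dominant
#' single-cell convention: `log(1 + x)` of counts scaled to 10,000).
#' Requires [normalize_cells()] to have been applied.
#'
#' @param m A `cell_matrix` on the `normalized` layer.
#' @return A `cell_matrix` on the `lognormalized` layer.
#' @export
log_normalize <- function(m) {
  stopifnot(inherits(m, "cell_matrix"))
  if (m$layer != "normalized") {
    abort("log_normalize expects the normalized layer; run normalize_cells() first")
  }
  out <- m
  out$counts@x <- log1p(out$counts@x)
  out$layer <- "lognormalized"
  out
}
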