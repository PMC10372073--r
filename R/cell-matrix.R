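#' Gene-by-cell count container
#'
#' A light wrapper around a sparse `dgCMatrix` holding genes as rows and
#' cell barcodes as columns, plus a `layer` tag recording which processing
#' stage the values are on: `"raw"` (integral counts), `"normalized"`
#' (per-cell totals scaled to a common target), or `"lognormalized"`
#' (log1p of the normalized values).
#'
#' @param counts A matrix or sparse Matrix, genes x cells, with row and
#'   column names.
#' @param layer One of `"raw"`, `"normalized"`, `"lognormalized"`.
#' @return A `cell_matrix` object (list with elements `counts`, `layer`).
#' @export
cell_matrix <- function(counts, layer = c("raw", "normalized", "lognormalized")) {
  layer <- match.arg(layer)
  counts <- methods::as(methods::as(methods::as(counts, "dMatrix"),
                                    "generalMatrix"), "CsparseMatrix")
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    abort("counts must carry gene rownames and barcode colnames")
  }
  if (anyDuplicated(gene_key(rownames(counts)))) {
    dup <- rownames(counts)[duplicated(gene_key(rownames(counts)))]
    abort(paste0("duplicate gene symbol(s): ", paste(unique(dup), collapse = ", ")))
  }
  if (anyDuplicated(colnames(counts))) abort("duplicate cell barcodes")
  x <- counts@x
  if (length(x) && min(x) < 0) abort("negative values in count matrix")
  if (layer == "raw" && length(x) && any(x != floor(x))) {
    abort("raw layer requires integral counts")
  }
  structure(list(counts = counts, layer = layer), class = "cell_matrix")
}

#' @export
print.cell_matrix <- function(x, ...) {
  cat(sprintf("<cell_matrix> %d genes x %d cells, layer=%s, nnz=%d\n",
              nrow(x$counts), ncol(x$counts), x$layer,
              length(x$counts@x)))
  invisible(x)
}

#' @export
dim.cell_matrix <- function(x) dim(x$counts)

#' @rdname cell_matrix
#' @param m Object to coerce.
#' @export
as_cell_matrix <- function(m, layer = "raw") {
  if (inherits(m, "cell_matrix")) return(m)
  cell_matrix(m, layer = layer)
}

#' Gene and barcode accessors
#' @param m A `cell_matrix`.
#' @return Character vector of gene symbols / cell barcodes.
#' @export
genes <- function(m) rownames(m$counts)

#' @rdname genes
#' @export
barcodes <- function(m) colnames(m$counts)
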