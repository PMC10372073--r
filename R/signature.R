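#' The 22 standard leukocyte signature column labels
#'
#' Column labels of the standard 22-type leukocyte signature matrix (LM22),
#' in its canonical order. Used as the default column vocabulary for the
#' type-to-category map and by the synthetic generator when it emits an
#' LM22-shaped stand-in.
#'
#' @return Character vector of length 22.
#' @export
lm22_types <- function() {
  c(
    "B cells naive", "B cells memory", "Plasma cells",
    "T cells CD8", "T cells CD4 naive", "T cells CD4 memory resting",
    "T cells CD4 memory activated", "T cells follicular helper",
    "T cells regulatory (Tregs)", "T cells gamma delta",
    "NK cells resting", "NK cells activated",
    "Monocytes",
    "Macrophages M0", "Macrophages M1", "Macrophages M2",
    "Dendritic cells resting", "Dendritic cells activated",
    "Mast cells resting", "Mast cells activated",
    "Eosinophils", "Neutrophils"
  )
}

#' Immune categories used by the annotator
#'
#' `immune_categories()` returns the nine categories assigned by maximum
#' profile correlation (T cells unsplit); `output_categories()` returns the
#' ten final categories, with the T-cell category split into CD4+ and CD8+.
#'
#' @return Character vector.
#' @export
immune_categories <- function() {
  c("B cell", "plasma cell", "T cell", "NK cell", "monocyte",
    "dendritic cell", "macrophage", "neutrophil", "other myeloid")
}

#' @rdname immune_categories
#' @export
output_categories <- function() {
  c("B cell", "plasma cell", "CD4+ T cell", "CD8+ T cell", "NK cell",
    "monocyte", "dendritic cell", "macrophage", "neutrophil",
    "other myeloid")
}

#' Default mapping from signature columns to immune categories
#'
#' Collapses the 22 signature column types onto the nine immune categories:
#' naive and memory B cells map to "B cell"; all seven T-cell columns map to
#' "T cell" (split into CD4+/CD8+ downstream by the boosted classifier);
#' resting/activated NK to "NK cell"; the three macrophage polarization
#' states to "macrophage"; resting/activated dendritic cells to
#' "dendritic cell"; mast cells and eosinophils to "other myeloid".
#' Override with a two-column table of your own (see [read_category_map()]).
#'
#' @return A tibble with columns `type` and `category`.
#' @export
default_category_map <- function() {
  tibble::tibble(
    type = lm22_types(),
    category = c(
      "B cell", "B cell", "plasma cell",
      rep("T cell", 7L),
      "NK cell", "NK cell",
      "monocyte",
      rep("macrophage", 3L),
      "dendritic cell", "dendritic cell",
      "other myeloid", "other myeloid", "other myeloid",
      "neutrophil"
    )
  )
}

#' Category map covering an arbitrary set of signature types
#'
#' Types matching the standard 22 labels map through
#' [default_category_map()]; any other label maps to itself, so generic
#' (e.g. synthetic) signatures annotate directly by column label.
#'
#' @param types Character vector of signature column labels.
#' @return A tibble with columns `type` and `category`.
#' @export
category_map_for <- function(types) {
  std <- default_category_map()
  i <- match(types, std$type)
  tibble::tibble(type = types,
                 category = ifelse(is.na(i), types, std$category[i]))
}

#' Read a type-to-category map override
#'
#' @param path Two-column headerless or headered TSV: signature column label,
#'   category. Categories must be drawn from [immune_categories()].
#' @return A tibble with columns `type` and `category`.
#' @export
read_category_map <- function(path) {
  raw <- read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                    colClasses = "character")
  if (ncol(raw) != 2L) {
    abort("category map must have exactly two tab-separated columns")
  }
  if (identical(tolower(raw[1, 1]), "type")) raw <- raw[-1, , drop = FALSE]
  cmap <- tibble::tibble(type = trimws(raw[[1]]), category = trimws(raw[[2]]))
  bad <- setdiff(cmap$category, immune_categories())
  if (length(bad) > 0) {
    abort(paste0("unknown categories in map: ", paste(bad, collapse = ", ")))
  }
  if (anyDuplicated(cmap$type)) abort("duplicate type labels in category map")
  cmap
}

new_signature <- function(values, genes, types) {
  dimnames(values) <- list(genes, types)
  structure(list(genes = genes, types = types, values = values),
            class = "immune_signature")
}

validate_signature <- function(sig) {
  v <- sig$values
  if (!all(v %in% c(0, 1))) {
    bad <- which(array(!(v %in% c(0, 1)), dim(v)), arr.ind = TRUE)[1, ]
    abort(sprintf("non-binary entry at gene '%s', type '%s'",
                  sig$genes[bad[1]], sig$types[bad[2]]))
  }
  keys <- gene_key(sig$genes)
  if (anyDuplicated(keys)) {
    abort(paste0("duplicate gene symbol(s): ",
                 paste(unique(sig$genes[duplicated(keys)]), collapse = ", ")))
  }
  if (anyDuplicated(sig$types)) abort("duplicate type labels")
  empty <- colSums(v) == 0
  if (any(empty)) {
    abort(paste0("signature column(s) with no marker genes: ",
                 paste(sig$types[empty], collapse = ", ")))
  }
  sig
}

#' Construct a binarized signature matrix object
#'
#' @param values Numeric gene-by-type matrix with entries in \{0, 1\}.
#' @param genes,types Row/column labels; taken from `dimnames(values)` when
#'   omitted.
#' @return An `immune_signature` object.
#' @export
immune_signature <- function(values, genes = rownames(values),
                             types = colnames(values)) {
  values <- as.matrix(values)
  if (is.null(genes) || is.null(types)) {
    abort("gene and type labels are required")
  }
  storage.mode(values) <- "double"
  validate_signature(new_signature(values, as.character(genes),
                                   as.character(types)))
}

#' @export
print.immune_signature <- function(x, ...) {
  cat(sprintf("<immune_signature> %d genes x %d types, %d marker entries\n",
              length(x$genes), length(x$types), sum(x$values)))
  invisible(x)
}

#' @export
dim.immune_signature <- function(x) dim(x$values)

#' Read a binarized leukocyte signature matrix from TSV
#'
#' Expects a header row of type labels, a first column of gene symbols, and
#' a strictly binary body (0/1). Duplicate gene symbols (case-insensitive),
#' non-binary entries, and all-zero columns are rejected; gene order is
#' preserved from the file.
#'
#' @param path Path to the signature TSV (gzip detected by extension).
#' @return An `immune_signature` object.
#' @export
read_signature <- function(path) {
  if (!file.exists(path)) abort(paste0("signature file not found: ", path))
  df <- read.delim(path, header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE)
  if (ncol(df) < 2L) abort("signature file needs a gene column and >=1 type column")
  genes <- as.character(df[[1]])
  body <- df[, -1, drop = FALSE]
  types <- colnames(body)
  values <- as.matrix(body)
  if (!is.numeric(values)) {
    suppressWarnings(num <- matrix(as.numeric(values), nrow(values)))
    if (anyNA(num)) {
      bad <- which(array(is.na(num), dim(num)), arr.ind = TRUE)[1, ]
      abort(sprintf("non-numeric entry '%s' at gene '%s', type '%s'",
                    values[bad[1], bad[2]], genes[bad[1]], types[bad[2]]))
    }
    values <- num
  }
  if (!all(values %in% c(0, 1))) {
    bad <- which(array(!(values %in% c(0, 1)), dim(values)),
                 arr.ind = TRUE)[1, ]
    abort(sprintf("non-binary entry '%s' at gene '%s', type '%s'",
                  format(values[bad[1], bad[2]]), genes[bad[1]], types[bad[2]]))
  }
  immune_signature(values, genes = genes, types = types)
}

#' Write a signature matrix to TSV
#'
#' Inverse of [read_signature()]: round-trips the binary matrix exactly.
#'
#' @param sig An `immune_signature`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_signature <- function(sig, path) {
  stopifnot(inherits(sig, "immune_signature"))
  df <- data.frame(gene = sig$genes, check.names = FALSE,
                   stringsAsFactors = FALSE)
  df[sig$types] <- as.data.frame(sig$values, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Binarize a continuous signature matrix by row maximum
#'
#' Helper for users holding the published continuous signature: gene g is
#' marked 1 for type k iff k attains the row maximum of g (ties mark every
#' maximizing type). This is a pragmatic stand-in, not a published
#' binarization rule; supplying an already-binarized file is the canonical
#' input path.
#'
#' @param values Continuous gene-by-type matrix with dimnames.
#' @return An `immune_signature`.
#' @export
binarize_signature <- function(values) {
  values <- as.matrix(values)
  rmax <- apply(values, 1L, max)
  bin <- (values == rmax) * 1
  immune_signature(bin, genes = rownames(values), types = colnames(values))
}

#' Number of marker genes in one signature column
#'
#' @param sig An `immune_signature`.
#' @param type_label A column label of `sig`.
#' @return Integer count of 1-entries in that column.
#' @export
marker_count <- function(sig, type_label) {
  stopifnot(inherits(sig, "immune_signature"))
  j <- match(type_label, sig$types)
  if (is.na(j)) abort(paste0("unknown signature type: ", type_label))
  as.integer(sum(sig$values[, j]))
}

#' Map a signature column label to its immune category
#'
#' @param cmap A category map tibble (`type`, `category`), e.g.
#'   [default_category_map()].
#' @param type_label Signature column label.
#' @return The category string.
#' @export
map_to_category <- function(cmap, type_label) {
  i <- match(type_label, cmap$type)
  if (anyNA(i)) {
    abort(paste0("type label(s) not in category map: ",
                 paste(type_label[is.na(i)], collapse = ", ")))
  }
  cmap$category[i]
}
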