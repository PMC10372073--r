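#' Run the whole annotation pipeline end to end
#'
#' Filter low-count cells, normalize, score both gate metrics, apply the
#' linear immune rule, annotate immune cells by maximum profile
#' correlation, optionally refine T cells with a trained CD4/CD8 model,
#' and profile per-sample composition. Writes `calls.csv`,
#' `composition.csv`, and `manifest.json` into `out_dir`; on any stage
#' failure partial outputs are removed.
#'
#' @param m A raw `cell_matrix` (from [read_counts_mtx()] /
#'   [read_counts_dense()]).
#' @param sig An `immune_signature` or a path readable by
#'   [read_signature()].
#' @param out_dir Output directory (created). `NULL` skips writing and
#'   just returns the tables.
#' @param min_total QC filter threshold (default 500).
#' @param scale Normalization target (default 10,000).
#' @param params [boundary_params()] (defaults to the published
#'   constants).
#' @param cmap Category map; defaults to [category_map_for()] over the
#'   signature's types.
#' @param tmodel Optional `tcell_model` or a model directory path.
#' @param sample_of Optional barcode -> sample mapping for composition
#'   profiling; unmapped runs report one pooled pseudo-sample `"all"`.
#' @param allow_sparse_signature Passed to [score_cells()].
#' @return Invisibly, a list with `calls`, `composition`, `manifest`.
#' @export
run_pipeline <- function(m, sig, out_dir = NULL, min_total = 500,
                         scale = 10000, params = boundary_params(),
                         cmap = NULL, tmodel = NULL,
                         sample_of = NULL, allow_sparse_signature = FALSE) {
  stopifnot(inherits(m, "cell_matrix"))
  if (is.character(sig)) sig <- read_signature(sig)
  if (is.character(tmodel)) tmodel <- load_tcell_model(tmodel)
  if (is.null(cmap)) cmap <- category_map_for(sig$types)

  written <- character(0)
  stage <- "filter"
  result <- tryCatch({
    n_input <- ncol(m$counts)
    filtered <- filter_cells(m, min_total = min_total)
    stage <- "normalize"
    normalized <- normalize_cells(filtered, scale = scale)
    stage <- "score"
    scores <- score_cells(normalized, sig, params = params,
                          allow_sparse_signature = allow_sparse_signature)
    stage <- "annotate"
    calls <- annotate_cells(scores, cmap = cmap, tmodel = tmodel,
                            m = normalized)
    stage <- "composition"
    smap <- sample_of
    if (is.null(smap)) {
      smap <- stats::setNames(rep("all", nrow(calls)), calls$barcode)
    }
    comp <- composition_of(calls, smap)
    manifest <- list(
      package = as.character(utils::packageVersion("immunocall")),
      params = list(min_total = min_total, scale = scale,
                    A = params$A, theta = params$theta,
                    tcell_refined = !is.null(tmodel)),
      n_cells = list(input = n_input,
                     after_filter = ncol(filtered$counts),
                     immune = sum(calls$is_immune),
                     t_refined = sum(!is.na(calls$tcell_subtype))),
      signature = list(n_genes = length(sig$genes),
                       n_types = length(sig$types),
                       missing_genes = attr(scores, "missing_genes"))
    )
    if (!is.null(out_dir)) {
      stage <- "write"
      dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
      p1 <- file.path(out_dir, "calls.csv"); written <- c(written, p1)
      write_calls(calls, p1)
      p2 <- file.path(out_dir, "composition.csv"); written <- c(written, p2)
      readr::write_csv(comp, p2)
      p3 <- file.path(out_dir, "manifest.json"); written <- c(written, p3)
      jsonlite::write_json(manifest, p3, auto_unbox = TRUE, digits = NA)
    }
    list(calls = calls, composition = comp, manifest = manifest)
  }, error = function(e) {
    unlink(written)
    abort(paste0("pipeline failed at stage '", stage, "': ",
                 conditionMessage(e)))
  })
  invisible(result)
}
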