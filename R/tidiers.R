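#' Broom-style tidiers for fitted objects
#'
#' `tidy()` on a `boundary_fit` returns the fitted rule's terms; on a
#' `tcell_model`, the stage-1 gain importance of every gene with its
#' selection status; on a `tcell_cv`, the per-round accuracies.
#' `glance()` returns one-row model summaries.
#'
#' @param x A `boundary_fit`, `tcell_model`, or `tcell_cv` object.
#' @param ... Unused.
#' @return A tibble.
#' @name immunocall-tidiers
NULL

#' @rdname immunocall-tidiers
#' @export
tidy.boundary_fit <- function(x, ...) {
  tibble::tibble(term = c("A", "theta"),
                 estimate = c(x$params$A, x$params$theta))
}

#' @rdname immunocall-tidiers
#' @export
glance.boundary_fit <- function(x, ...) {
  tibble::tibble(auc = x$auc, sensitivity = x$sensitivity,
                 specificity = x$specificity, youden = x$youden,
                 n_immune = x$n_immune, n_nonimmune = x$n_nonimmune)
}

#' @rdname immunocall-tidiers
#' @export
tidy.tcell_model <- function(x, ...) {
  dplyr::arrange(
    dplyr::mutate(x$importance,
                  selected = .data$gene %in% x$selected_genes),
    dplyr::desc(.data$gain))
}

#' @rdname immunocall-tidiers
#' @export
glance.tcell_model <- function(x, ...) {
  tibble::tibble(n_cells = x$manifest$n_cells,
                 n_cd4 = x$manifest$n_cd4, n_cd8 = x$manifest$n_cd8,
                 n_genes_input = x$manifest$n_genes_input,
                 n_genes_selected = x$manifest$n_genes_selected)
}

#' @rdname immunocall-tidiers
#' @export
tidy.tcell_cv <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}

#' @rdname immunocall-tidiers
#' @export
glance.tcell_cv <- function(x, ...) {
  tibble::tibble(rounds = nrow(x),
                 mean_accuracy = mean(x$accuracy),
                 min_accuracy = min(x$accuracy),
                 max_accuracy = max(x$accuracy))
}
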