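#' Plot cells in the (rho_max, T) decision plane
#'
#' Scatter of the two gate metrics with the linear decision boundary
#' `A * rho_max + T = theta` overlaid, colored by the immune call.
#'
#' @param scores A score table from [score_cells()].
#' @param params [boundary_params()] used for the boundary line.
#' @return A ggplot object.
#' @export
plot_score_plane <- function(scores, params = attr(scores, "params") %||%
                               boundary_params()) {
  ggplot2::ggplot(scores,
                  ggplot2::aes(x = .data$rho_max,
                               y = .data$total_immune_expression,
                               colour = .data$is_immune)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.6) +
    ggplot2::geom_abline(intercept = params$theta, slope = -params$A,
                         linetype = "dashed") +
    ggplot2::labs(x = "maximum correlation coefficient",
                  y = "total immune gene expression",
                  colour = "immune") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.immc_roc <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$fpr,
                                       y = .data$sensitivity)) +
    ggplot2::geom_step() +
    ggplot2::geom_abline(linetype = "dotted") +
    ggplot2::labs(x = "1 - specificity", y = "sensitivity",
                  title = sprintf("ROC (AUC = %.3f)", attr(object, "auc"))) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.immc_roc
#' @param roc An `immc_roc` object from [roc_curve()].
#' @export
plot_roc <- function(roc) autoplot(roc)

#' Stacked per-sample composition bars
#'
#' @param comp Composition table from [composition_of()].
#' @return A ggplot object.
#' @export
plot_composition <- function(comp) {
  cat_cols <- setdiff(names(comp),
                      c("sample", "n_cells", "n_immune", "frac_non_immune"))
  long <- tidyr::pivot_longer(comp[, c("sample", cat_cols)],
                              cols = dplyr::all_of(cat_cols),
                              names_to = "category",
                              values_to = "proportion")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$sample,
                                     y = .data$proportion,
                                     fill = .data$category)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "proportion of immune cells") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}
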