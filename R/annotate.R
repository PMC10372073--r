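#' Annotate scored cells into immune categories
#'
#' Applies the gating order of the workflow: cells failing the immune gate
#' are labeled `non-immune` and never typed; immune cells are assigned the
#' category of their maximum-correlation signature column via the category
#' map; cells landing in the T-cell category are optionally refined into
#' CD4+/CD8+ by a trained boosted classifier (using log-normalized
#' expression over the model's selected genes, absent genes zero-filled).
#' Deterministic given its inputs.
#'
#' @param scores A score table from [score_cells()].
#' @param cmap Category map tibble (default [default_category_map()]).
#' @param tmodel Optional [train_tcell()] model for CD4/CD8 refinement.
#' @param m The `cell_matrix` the scores were computed on (`normalized`
#'   layer); required when `tmodel` is given.
#' @return A tibble of calls: `barcode`, `rho_max`,
#'   `total_immune_expression`, `linear_score`, `is_immune`,
#'   `signature_type`, `category`, `tcell_subtype` (NA unless refined),
#'   `tcell_score` (classifier margin, NA unless refined).
#' @export
annotate_cells <- function(scores, cmap = default_category_map(),
                           tmodel = NULL, m = NULL) {
  scores <- tibble::as_tibble(scores)
  needed <- c("barcode", "rho_max", "signature_type",
              "total_immune_expression", "linear_score", "is_immune")
  missing_cols <- setdiff(needed, names(scores))
  if (length(missing_cols) > 0) {
    abort(paste0("score table lacks column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  out <- scores[needed]
  out$category <- ifelse(out$is_immune,
                         map_to_category(cmap, out$signature_type),
                         "non-immune")
  out$signature_type[!out$is_immune] <- NA_character_
  out$tcell_subtype <- NA_character_
  out$tcell_score <- NA_real_

  is_t <- out$category == "T cell"
  if (any(is_t) && !is.null(tmodel)) {
    if (is.null(m)) {
      abort("CD4/CD8 refinement requires the cell_matrix the scores came from")
    }
    sub <- m
    sub$counts <- m$counts[, match(out$barcode[is_t], barcodes(m)),
                           drop = FALSE]
    pred <- predict_tcell(tmodel, log_normalize(sub))
    out$tcell_subtype[is_t] <- pred$label
    out$tcell_score[is_t] <- pred$margin
    out$category[is_t] <- paste0(pred$label, "+ T cell")
  }
  out
}

#' Per-sample immune composition
#'
#' Proportions of each immune category among a sample's immune cells
#' (rows sum to 1 over the category columns); the non-immune fraction is
#' reported separately as `frac_non_immune`. Samples with zero immune
#' cells get NaN proportions and are flagged.
#'
#' @param calls A call table from [annotate_cells()].
#' @param sample_of Either a named character vector (barcode -> sample) or
#'   a data frame with columns `barcode` and `sample`; every barcode in
#'   `calls` must be mapped.
#' @param categories Category columns to report; defaults to the
#'   categories present among the immune calls, in standard order.
#' @return A wide tibble: `sample`, one proportion column per category,
#'   `n_cells`, `n_immune`, `frac_non_immune`.
#' @export
composition_of <- function(calls, sample_of, categories = NULL) {
  calls <- tibble::as_tibble(calls)
  if (is.data.frame(sample_of)) {
    sample_of <- stats::setNames(as.character(sample_of$sample),
                                 sample_of$barcode)
  }
  smp <- sample_of[calls$barcode]
  if (anyNA(smp)) {
    abort(paste0("barcode(s) without a sample assignment: ",
                 paste(head(calls$barcode[is.na(smp)], 5), collapse = ", ")))
  }
  if (is.null(categories)) {
    std <- c(output_categories(), "T cell")
    seen <- unique(calls$category[calls$is_immune])
    categories <- c(intersect(std, seen), setdiff(seen, std))
  }
  df <- tibble::tibble(sample = unname(smp),
                       category = calls$category,
                       is_immune = calls$is_immune)
  per_sample <- df |>
    dplyr::group_by(.data$sample) |>
    dplyr::summarise(n_cells = dplyr::n(),
                     n_immune = sum(.data$is_immune),
                     .groups = "drop")
  props <- df |>
    dplyr::filter(.data$is_immune) |>
    dplyr::count(.data$sample, .data$category) |>
    dplyr::group_by(.data$sample) |>
    dplyr::mutate(prop = .data$n / sum(.data$n)) |>
    dplyr::ungroup() |>
    dplyr::select(-"n") |>
    tidyr::pivot_wider(names_from = "category", values_from = "prop",
                       values_fill = 0)
  out <- dplyr::left_join(per_sample, props, by = "sample")
  for (cat in setdiff(categories, names(out))) out[[cat]] <- 0
  # samples with no immune cells have undefined proportions
  none <- out$n_immune == 0L
  out[none, categories] <- NaN
  out$frac_non_immune <- 1 - out$n_immune / out$n_cells
  out[, c("sample", categories, "n_cells", "n_immune", "frac_non_immune")]
}
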