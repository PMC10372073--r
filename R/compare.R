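#' Two-group comparison of per-sample immune composition
#'
#' For each category column of a composition table, compares the two
#' groups' per-sample proportions with a two-sided Mann-Whitney U test:
#' exact enumeration when both groups have at most 8 samples and the
#' values are tie-free, otherwise the normal approximation with tie
#' correction and continuity correction. The direction reports which
#' group has the larger mean. Raw p-values are reported by default;
#' Benjamini-Hochberg adjustment is available via `fdr = TRUE`.
#'
#' @param comp A composition table from [composition_of()] (wide: one
#'   proportion column per category).
#' @param groups Either a named vector (sample -> group) or a data frame
#'   with columns `sample` and `group`; exactly two groups, each with at
#'   least two samples.
#' @param categories Columns to test; defaults to the category columns
#'   present in `comp`.
#' @param fdr Add a `p_adjusted` column (Benjamini-Hochberg).
#' @return A tibble: `category`, `mean_<groupA>`, `mean_<groupB>`,
#'   `higher_in`, `p_value` (and `p_adjusted` when `fdr`).
#' @export
compare_groups <- function(comp, groups, categories = NULL, fdr = FALSE) {
  comp <- tibble::as_tibble(comp)
  if (is.data.frame(groups)) {
    groups <- stats::setNames(as.character(groups$group), groups$sample)
  }
  g <- groups[comp$sample]
  if (anyNA(g)) abort("every sample in the composition table needs a group")
  lev <- sort(unique(g))
  if (length(lev) != 2L) abort("exactly two groups required")
  if (any(table(g) < 2L)) abort("each group needs at least 2 samples")
  if (is.null(categories)) {
    categories <- setdiff(names(comp),
                          c("sample", "n_cells", "n_immune",
                            "frac_non_immune"))
  }
  rows <- lapply(categories, function(cat) {
    xa <- comp[[cat]][g == lev[1]]
    xb <- comp[[cat]][g == lev[2]]
    xa <- xa[is.finite(xa)]; xb <- xb[is.finite(xb)]
    if (length(xa) < 2L || length(xb) < 2L) {
      return(tibble::tibble(category = cat, mean_a = NA_real_,
                            mean_b = NA_real_, higher_in = NA_character_,
                            p_value = NA_real_))
    }
    tie_free <- !any(duplicated(c(xa, xb)))
    exact <- length(xa) <= 8L && length(xb) <= 8L && tie_free
    p <- if (identical(xa, xb) ||
             (length(unique(c(xa, xb))) == 1L)) {
      1.0
    } else {
      suppressWarnings(
        stats::wilcox.test(xa, xb, alternative = "two.sided",
                           exact = exact, correct = TRUE)$p.value)
    }
    ma <- mean(xa); mb <- mean(xb)
    tibble::tibble(
      category = cat, mean_a = ma, mean_b = mb,
      higher_in = if (ma == mb) "tie" else if (ma > mb) lev[1] else lev[2],
      p_value = min(1, p))
  })
  out <- dplyr::bind_rows(rows)
  names(out)[names(out) == "mean_a"] <- paste0("mean_", lev[1])
  names(out)[names(out) == "mean_b"] <- paste0("mean_", lev[2])
  if (fdr) out$p_adjusted <- stats::p.adjust(out$p_value, method = "BH")
  out
}
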