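#' Binomial accuracy with a normal-approximation confidence interval
#'
#' Point estimate `n_correct / n_total` with a Wald interval
#' `p +/- z * sqrt(p (1 - p) / n)` clipped to `[0, 1]`; a Wilson score
#' interval is available via `method = "wilson"`.
#'
#' @param n_correct,n_total Counts, `0 <= n_correct <= n_total`,
#'   `n_total > 0`.
#' @param level Confidence level (default 0.95).
#' @param method `"wald"` (default) or `"wilson"`.
#' @return A tibble with columns `accuracy`, `lo`, `hi`.
#' @export
accuracy_ci <- function(n_correct, n_total, level = 0.95,
                        method = c("wald", "wilson")) {
  method <- match.arg(method)
  if (any(n_total <= 0)) abort("n_total must be positive")
  if (any(n_correct < 0) || any(n_correct > n_total)) {
    abort("need 0 <= n_correct <= n_total")
  }
  p <- n_correct / n_total
  z <- stats::qnorm(1 - (1 - level) / 2)
  if (method == "wald") {
    half <- z * sqrt(p * (1 - p) / n_total)
    lo <- pmax(0, p - half); hi <- pmin(1, p + half)
  } else {
    denom <- 1 + z^2 / n_total
    center <- (p + z^2 / (2 * n_total)) / denom
    half <- z * sqrt(p * (1 - p) / n_total + z^2 / (4 * n_total^2)) / denom
    lo <- pmax(0, center - half); hi <- pmin(1, center + half)
  }
  tibble::tibble(accuracy = p, lo = lo, hi = hi)
}

#' Confusion matrix of calls against truth
#'
#' Counts indexed (true, predicted) over a fixed category vocabulary.
#' Every call barcode must be present in the truth table, and every truth
#' label must be in the vocabulary.
#'
#' @param calls Call table with `barcode` and `category`.
#' @param truth Truth table with `barcode` and `category` (or
#'   `cell_type`).
#' @param vocabulary Category labels indexing both axes; defaults to
#'   `output_categories()` plus `"T cell"` and `"non-immune"`.
#' @return An integer matrix, rows = true, columns = predicted.
#' @export
confusion <- function(calls, truth,
                      vocabulary = c(output_categories(), "T cell",
                                     "non-immune")) {
  calls <- tibble::as_tibble(calls)
  truth <- tibble::as_tibble(truth)
  tcol <- intersect(c("category", "cell_type"), names(truth))[1]
  if (is.na(tcol)) abort("truth needs a 'category' or 'cell_type' column")
  i <- match(calls$barcode, truth$barcode)
  if (anyNA(i)) {
    abort(paste0("call barcode(s) missing from truth: ",
                 paste(head(calls$barcode[is.na(i)], 5), collapse = ", ")))
  }
  true_lab <- truth[[tcol]][i]
  bad <- setdiff(unique(true_lab), vocabulary)
  if (length(bad) > 0) {
    abort(paste0("truth label(s) outside vocabulary: ",
                 paste(bad, collapse = ", ")))
  }
  table(factor(true_lab, levels = vocabulary),
        factor(calls$category, levels = vocabulary),
        dnn = c("true", "predicted"))
}

#' Sensitivity and specificity of the immune gate
#'
#' Sensitivity = proportion of truly immune cells called immune;
#' specificity = proportion of truly non-immune cells called non-immune.
#'
#' @param calls Call (or score) table with `barcode` and `is_immune`.
#' @param truth Truth table with `barcode` and `is_immune`.
#' @return A tibble with `sensitivity` and `specificity`.
#' @export
gate_metrics <- function(calls, truth) {
  i <- match(calls$barcode, truth$barcode)
  if (anyNA(i)) abort("call barcode(s) missing from truth")
  truly <- as.logical(truth$is_immune[i])
  called <- as.logical(calls$is_immune)
  if (length(unique(truly)) < 2L) {
    abort("truth must contain both immune and non-immune cells")
  }
  tibble::tibble(
    sensitivity = mean(called[truly]),
    specificity = mean(!called[!truly])
  )
}

#' Per-dataset evaluation report
#'
#' Bundles overall accuracy with its confidence interval, the confusion
#' matrix, and the immune-gate sensitivity/specificity.
#'
#' @inheritParams confusion
#' @param level Confidence level for the accuracy interval.
#' @return An `eval_report` list: `accuracy` (tibble), `confusion`,
#'   `gate` (tibble, present when truth carries `is_immune`).
#' @export
evaluate_calls <- function(calls, truth,
                           vocabulary = c(output_categories(), "T cell",
                                          "non-immune"),
                           level = 0.95) {
  cm <- confusion(calls, truth, vocabulary)
  acc <- accuracy_ci(sum(diag(cm)), sum(cm), level = level)
  gate <- if ("is_immune" %in% names(truth)) {
    gate_metrics(calls, truth)
  } else NULL
  structure(list(accuracy = acc, confusion = cm, gate = gate),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> accuracy %.1f%% [%.1f-%.1f%%] over %d cells\n",
              100 * x$accuracy$accuracy, 100 * x$accuracy$lo,
              100 * x$accuracy$hi, sum(x$confusion)))
  if (!is.null(x$gate)) {
    cat(sprintf("  immune gate: sensitivity %.1f%%, specificity %.1f%%\n",
                100 * x$gate$sensitivity, 100 * x$gate$specificity))
  }
  invisible(x)
}
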