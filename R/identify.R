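#' Parameters of the linear immune-identification rule
#'
#' The immune gate declares a cell immune when
#' `A * rho_max + T > theta`, where `rho_max` is the maximum Pearson
#' correlation of the cell's normalized expression to the signature
#' profiles and `T` is the total normalized expression over signature
#' genes. Defaults are the published constants `A = 1580.7`,
#' `theta = 413`, applied unchanged across datasets; refitting
#' ([fit_boundary()]) is an explicit optional step.
#'
#' @param A Slope weight on `rho_max`.
#' @param theta Decision threshold.
#' @return A `boundary_params` object.
#' @export
boundary_params <- function(A = 1580.7, theta = 413) {
  stopifnot(is.finite(A), is.finite(theta))
  structure(list(A = A, theta = theta), class = "boundary_params")
}

#' @export
print.boundary_params <- function(x, ...) {
  cat(sprintf("<boundary_params> A=%g, theta=%g\n", x$A, x$theta))
  invisible(x)
}

#' Apply the linear immune rule to bare metric values
#'
#' Evaluates `A * rho_max + T` and the strict decision
#' `linear_score > theta` for given metric values, without touching a
#' count matrix. This is the decision rule itself; [score_cells()] uses
#' it after computing the metrics.
#'
#' @param rho_max Maximum correlation coefficient(s).
#' @param total_expr Total immune gene expression value(s).
#' @param params A [boundary_params()] object.
#' @return A tibble with `linear_score` and `is_immune`.
#' @export
immune_gate <- function(rho_max, total_expr, params = boundary_params()) {
  score <- params$A * rho_max + total_expr
  tibble::tibble(linear_score = score, is_immune = score > params$theta)
}

#' Restrict a count matrix to the signature gene basis
#'
#' Reorders rows onto the signature's gene order (case-insensitive symbol
#' match); signature genes absent from the input become all-zero rows so
#' that the correlation basis is a fixed `G`-gene vector space regardless
#' of dataset coverage. The number of missing genes is attached as
#' attribute `missing_genes`.
#'
#' @param m A `cell_matrix` on the `normalized` layer.
#' @param sig An `immune_signature`.
#' @param allow_sparse_signature Permit more than half of the signature
#'   genes to be missing (otherwise an error).
#' @return A `cell_matrix` with exactly the signature's genes as rows.
#' @export
align_to_signature <- function(m, sig, allow_sparse_signature = FALSE) {
  stopifnot(inherits(m, "cell_matrix"), inherits(sig, "immune_signature"))
  idx <- match(gene_key(sig$genes), gene_key(genes(m)))
  n_missing <- sum(is.na(idx))
  if (n_missing == length(sig$genes)) {
    abort("no signature genes found in the count matrix")
  }
  if (n_missing > 0.5 * length(sig$genes) && !allow_sparse_signature) {
    abort(sprintf(
      "%d of %d signature genes missing from input; pass allow_sparse_signature = TRUE to proceed",
      n_missing, length(sig$genes)))
  }
  aligned <- Matrix::sparseMatrix(
    i = integer(), j = integer(), x = double(),
    dims = c(length(sig$genes), ncol(m$counts)),
    dimnames = list(sig$genes, barcodes(m)))
  present <- !is.na(idx)
  aligned[present, ] <- m$counts[idx[present], , drop = FALSE]
  out <- m
  out$counts <- methods::as(aligned, "CsparseMatrix")
  attr(out, "missing_genes") <- n_missing
  out
}

#' Pearson correlations of cells to the signature profiles
#'
#' Correlates each cell's normalized expression over the signature genes
#' with every binary signature column. Zero-variance cases (constant cell
#' vector, or constant column) return 0 by convention — "no evidence" —
#' so all-zero cells are gated on `T` alone.
#'
#' @param x A numeric vector over the signature genes, a genes-by-cells
#'   matrix on that basis, or an aligned `cell_matrix`.
#' @param sig An `immune_signature`.
#' @return An `N x K` matrix of correlation coefficients.
#' @export
profile_correlations <- function(x, sig) {
  stopifnot(inherits(sig, "immune_signature"))
  if (inherits(x, "cell_matrix")) x <- x$counts
  if (is.null(dim(x))) x <- matrix(x, ncol = 1L)
  if (nrow(x) != length(sig$genes)) {
    abort(sprintf("expected %d rows (signature genes), got %d",
                  length(sig$genes), nrow(x)))
  }
  r <- suppressWarnings(stats::cor(as.matrix(x), sig$values))
  r[!is.finite(r)] <- 0
  r
}

#' Score cells with the two immune-gate metrics
#'
#' Computes, per cell, the maximum correlation coefficient to the
#' signature profiles (`rho_max`, argmax recorded as `signature_type`,
#' first column wins on ties), the total immune gene expression `T`
#' (sum of normalized expression over signature genes, bounded by the
#' normalization scale), the linear score `A * rho_max + T`, and the
#' immune flag `linear_score > theta` (strict).
#'
#' @param m A `cell_matrix` on the `normalized` layer.
#' @param sig An `immune_signature`.
#' @param params A [boundary_params()] object.
#' @param allow_sparse_signature Passed to [align_to_signature()].
#' @return A tibble with columns `barcode`, `rho_max`, `signature_type`,
#'   `total_immune_expression`, `linear_score`, `is_immune`; the full
#'   `N x K` correlation matrix is attached as attribute `rho`.
#' @export
score_cells <- function(m, sig, params = boundary_params(),
                        allow_sparse_signature = FALSE) {
  stopifnot(inherits(m, "cell_matrix"))
  if (m$layer != "normalized") {
    abort("score_cells expects the normalized layer; run normalize_cells() first")
  }
  aligned <- align_to_signature(m, sig,
                                allow_sparse_signature = allow_sparse_signature)
  total_expr <- as.numeric(Matrix::colSums(aligned$counts))
  rho <- profile_correlations(aligned, sig)
  j_max <- max.col(rho, ties.method = "first")
  rho_max <- rho[cbind(seq_len(nrow(rho)), j_max)]
  gate <- immune_gate(rho_max, total_expr, params)
  out <- tibble::tibble(
    barcode = barcodes(m),
    rho_max = rho_max,
    signature_type = sig$types[j_max],
    total_immune_expression = total_expr,
    linear_score = gate$linear_score,
    is_immune = gate$is_immune
  )
  attr(out, "rho") <- rho
  attr(out, "params") <- params
  attr(out, "missing_genes") <- attr(aligned, "missing_genes")
  out
}

#' ROC curve and AUC for a binary score
#'
#' Sweeps the decision threshold over the distinct score values
#' (predicting positive when `score >= threshold`) and returns the
#' monotone staircase of (sensitivity, 1 - specificity). The trapezoid
#' AUC equals the pairwise-concordance AUC with ties counted 1/2.
#'
#' @param scores Numeric scores, larger meaning more positive.
#' @param labels Logical (or 0/1) true-class labels; both classes required.
#' @return A tibble with columns `threshold`, `sensitivity`, `fpr`
#'   (class `immc_roc`), with the AUC as attribute `auc` (also via
#'   [auc()]).
#' @export
roc_curve <- function(scores, labels) {
  labels <- as.logical(labels)
  if (length(scores) != length(labels)) abort("scores and labels differ in length")
  if (anyNA(scores) || anyNA(labels)) abort("NA in scores or labels")
  n_pos <- sum(labels); n_neg <- sum(!labels)
  if (n_pos == 0L || n_neg == 0L) abort("labels must contain both classes")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; l <- labels[ord]
  last_of_tie <- c(s[-1] != s[-length(s)], TRUE)
  tp <- cumsum(l)[last_of_tie]
  fp <- cumsum(!l)[last_of_tie]
  out <- tibble::tibble(
    threshold = c(Inf, s[last_of_tie]),
    sensitivity = c(0, tp / n_pos),
    fpr = c(0, fp / n_neg)
  )
  auc <- sum(diff(out$fpr) *
               (out$sensitivity[-1] + out$sensitivity[-nrow(out)]) / 2)
  attr(out, "auc") <- auc
  class(out) <- c("immc_roc", class(out))
  out
}

#' @rdname roc_curve
#' @param roc An `immc_roc` object.
#' @export
auc <- function(roc) attr(roc, "auc")

#' Fit the linear immune boundary by Youden's J
#'
#' Grid search over the slope `A` and threshold `theta` maximizing
#' Youden's J = sensitivity + specificity - 1 on labeled
#' (`rho_max`, `T`) clouds, with a coarse pass followed by a 10x local
#' refinement around the optimum. Ties are broken toward smaller `A`,
#' then smaller `theta`. The ROC/AUC is computed on the linear score
#' `A * rho_max + T` at the selected slope (threshold sweep at fixed
#' slope).
#'
#' @param immune,nonimmune Data frames with columns `rho_max` and
#'   `total_immune_expression` (or `T`) for the two classes.
#' @param A_range,theta_range Search intervals; defaults `[0, 5000]` and
#'   `[0, 10000]`.
#' @param n_grid Coarse grid size per axis (default 101).
#' @return A `boundary_fit` object: `params`, `sensitivity`,
#'   `specificity`, `youden`, `auc`, `roc`, and the training sizes.
#' @export
fit_boundary <- function(immune, nonimmune,
                         A_range = c(0, 5000), theta_range = c(0, 10000),
                         n_grid = 101L) {
  get_xy <- function(df, who) {
    df <- tibble::as_tibble(df)
    tcol <- intersect(c("total_immune_expression", "T"), names(df))[1]
    if (is.na(tcol) || !"rho_max" %in% names(df)) {
      abort(paste0(who, " needs columns rho_max and total_immune_expression"))
    }
    if (nrow(df) == 0L) abort(paste0(who, " is empty"))
    list(rho = df$rho_max, t = df[[tcol]])
  }
  pos <- get_xy(immune, "immune")
  neg <- get_xy(nonimmune, "nonimmune")
  if (n_grid < 2L || diff(A_range) < 0 || diff(theta_range) < 0) {
    abort("degenerate search grid")
  }

  best <- list(J = -Inf, A = NA_real_, theta = NA_real_,
               sens = NA_real_, spec = NA_real_)
  sweep_grid <- function(A_vals, theta_vals, best) {
    # A ascending then theta ascending; strict improvement only, so ties
    # resolve toward smaller A, then smaller theta
    for (A in A_vals) {
      sp <- sort(A * pos$rho + pos$t)
      sn <- sort(A * neg$rho + neg$t)
      sens <- 1 - findInterval(theta_vals, sp) / length(sp)  # P(score > theta)
      spec <- findInterval(theta_vals, sn) / length(sn)      # P(score <= theta)
      J <- sens + spec - 1
      j <- which.max(J)
      if (J[j] > best$J + 1e-12) {
        best <- list(J = J[j], A = A, theta = theta_vals[j],
                     sens = sens[j], spec = spec[j])
      }
    }
    best
  }
  A_vals <- seq(A_range[1], A_range[2], length.out = n_grid)
  th_vals <- seq(theta_range[1], theta_range[2], length.out = n_grid)
  best <- sweep_grid(A_vals, th_vals, best)
  # local refinement at 10x resolution around the coarse optimum
  A_step <- if (n_grid > 1) diff(A_range) / (n_grid - 1) else 0
  th_step <- if (n_grid > 1) diff(theta_range) / (n_grid - 1) else 0
  refine <- function(center, step, lim) {
    seq(max(lim[1], center - step), min(lim[2], center + step),
        length.out = 21L)
  }
  best <- sweep_grid(refine(best$A, A_step, A_range),
                     refine(best$theta, th_step, theta_range), best)

  scores <- c(best$A * pos$rho + pos$t, best$A * neg$rho + neg$t)
  labels <- c(rep(TRUE, length(pos$rho)), rep(FALSE, length(neg$rho)))
  roc <- roc_curve(scores, labels)
  structure(list(
    params = boundary_params(A = best$A, theta = best$theta),
    sensitivity = best$sens, specificity = best$spec,
    youden = best$J, auc = auc(roc), roc = roc,
    n_immune = length(pos$rho), n_nonimmune = length(neg$rho)
  ), class = "boundary_fit")
}

#' @export
print.boundary_fit <- function(x, ...) {
  cat(sprintf(
    "<boundary_fit> A=%g theta=%g | sens=%.3f spec=%.3f J=%.3f AUC=%.3f\n",
    x$params$A, x$params$theta, x$sensitivity, x$specificity, x$youden, x$auc))
  invisible(x)
}
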