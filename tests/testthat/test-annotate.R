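mk_scores <- function(types, immune = TRUE) {
  n <- length(types)
  tibble::tibble(
    barcode = paste0("c", seq_len(n)),
    rho_max = 0.8, signature_type = types,
    total_immune_expression = ifelse(immune, 5000, 100),
    linear_score = 1580.7 * 0.8 + ifelse(immune, 5000, 100),
    is_immune = rep(immune, n))
}

test_that("gating order: non-immune cells are never typed", {
  sc <- mk_scores(c("NK cells activated", "T cells CD8"), immune = FALSE)
  sc$is_immune <- c(FALSE, TRUE)
  calls <- annotate_cells(sc)
  expect_identical(calls$category, c("non-immune", "T cell"))
  expect_true(is.na(calls$signature_type[1]))
  # with refinement off, T cells stay unsplit
  sc2 <- mk_scores("NK cells activated")
  expect_identical(annotate_cells(sc2)$category, "NK cell")
  # pure function: identical repeated output
  expect_identical(annotate_cells(sc), annotate_cells(sc))
})

test_that("T-cell refinement replaces the unsplit label using the model", {
  src <- small_tcell_sources(seed = 13)
  ts <- assemble_training_set(src, 100, seed = 2)
  model <- train_tcell(ts$matrix, ts$labels, fast_tcell_config(seed = 2))

  # score T cells from one CD8 source against a signature whose T column
  # is the CD8 marker block, so they gate immune and type as T cell
  genes_t <- genes(src[[3]]$matrix)
  v <- matrix(0, length(genes_t), 2,
              dimnames = list(genes_t, c("T cells CD8", "B cells naive")))
  v[26:50, 1] <- 1  # CD8 marker block
  v[51:60, 2] <- 1
  sig <- immune_signature(v)
  m <- src[[3]]$matrix
  norm <- normalize_cells(filter_cells(m, 0))
  sc <- score_cells(norm, sig, allow_sparse_signature = TRUE)
  calls <- annotate_cells(sc, cmap = default_category_map(),
                          tmodel = model, m = norm)
  refined <- calls[calls$category %in% c("CD4+ T cell", "CD8+ T cell"), ]
  expect_gt(nrow(refined), 0)
  expect_identical(unique(refined$tcell_subtype[refined$category ==
                                                  "CD8+ T cell"]), "CD8")
  expect_gt(mean(refined$category == "CD8+ T cell"), 0.9)
  # requesting refinement without the matrix is a configuration error
  expect_error(annotate_cells(sc, tmodel = model), "requires the cell_matrix")
})

test_that("composition rows are stochastic over immune categories", {
  calls <- tibble::tibble(
    barcode = paste0("c", 1:5),
    rho_max = 0.5, total_immune_expression = 5000, linear_score = 5800,
    is_immune = c(TRUE, TRUE, TRUE, TRUE, FALSE),
    signature_type = "x",
    category = c("B cell", "B cell", "CD8+ T cell", "NK cell", "non-immune"),
    tcell_subtype = NA_character_, tcell_score = NA_real_)
  smap <- setNames(rep("s1", 5), calls$barcode)
  comp <- composition_of(calls, smap)
  expect_equal(comp$`B cell`, 0.5)
  expect_equal(comp$`CD8+ T cell`, 0.25)
  expect_equal(comp$`NK cell`, 0.25)
  expect_equal(comp$frac_non_immune, 0.2)
  cat_cols <- setdiff(names(comp), c("sample", "n_cells", "n_immune",
                                     "frac_non_immune"))
  expect_equal(sum(comp[1, cat_cols]), 1, tolerance = 1e-9)

  # two identical samples produce identical rows
  calls2 <- dplyr::mutate(calls, barcode = paste0("d", 1:5))
  both <- dplyr::bind_rows(calls, calls2)
  smap2 <- setNames(rep(c("s1", "s2"), each = 5), both$barcode)
  comp2 <- composition_of(both, smap2)
  expect_equal(comp2[1, -1], comp2[2, -1])

  # a sample with zero immune cells is flagged with NaN proportions
  calls_n <- dplyr::mutate(calls, is_immune = FALSE, category = "non-immune")
  comp3 <- composition_of(calls_n, smap,
                          categories = c("B cell", "NK cell"))
  expect_true(all(is.nan(unlist(comp3[1, c("B cell", "NK cell")]))))
  # unmapped barcode is an error
  expect_error(composition_of(calls, smap[-1]), "without a sample")
})
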