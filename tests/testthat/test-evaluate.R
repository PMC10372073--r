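test_that("Wald interval matches the hand-computed formula and boundaries", {
  expect_equal(accuracy_ci(100, 100),
               tibble::tibble(accuracy = 1, lo = 1, hi = 1))
  expect_equal(accuracy_ci(0, 10),
               tibble::tibble(accuracy = 0, lo = 0, hi = 0))
  ci <- accuracy_ci(930, 1000)
  half <- qnorm(0.975) * sqrt(0.93 * 0.07 / 1000)
  expect_equal(ci$accuracy, 0.93)
  expect_equal(ci$lo, 0.93 - half, tolerance = 1e-12)
  expect_equal(ci$hi, 0.93 + half, tolerance = 1e-12)
  # width shrinks toward zero with n at fixed p
  widths <- sapply(c(1e2, 1e4, 1e6), function(n) {
    ci <- accuracy_ci(round(0.8 * n), n); ci$hi - ci$lo
  })
  expect_true(all(diff(widths) < 0))
  expect_equal(widths[3], 0, tolerance = 1e-2)
  # Wilson variant stays inside [0,1] and differs from Wald at small n
  w <- accuracy_ci(9, 10, method = "wilson")
  expect_true(w$lo > 0 && w$hi < 1)
  expect_error(accuracy_ci(5, 0), "positive")
  expect_error(accuracy_ci(11, 10), "n_correct")
})

test_that("confusion matrices count (true, predicted) pairs exactly", {
  calls <- tibble::tibble(barcode = c("a", "b", "c"),
                          category = c("B cell", "T cell", "B cell"))
  truth <- tibble::tibble(barcode = c("a", "b", "c"),
                          category = c("B cell", "B cell", "B cell"))
  cm <- confusion(calls, truth)
  expect_equal(sum(cm), 3)
  expect_equal(cm["B cell", "B cell"], 2)
  expect_equal(cm["B cell", "T cell"], 1)
  # perfect predictions are diagonal; trace/total equals overall accuracy
  cm2 <- confusion(calls, dplyr::rename(calls, cell_type = category))
  expect_equal(sum(diag(cm2)), 3)
  withr::with_seed(8, {
    vocab <- c("B cell", "T cell", "NK cell")
    tr <- tibble::tibble(barcode = paste0("x", 1:50),
                         category = sample(vocab, 50, TRUE))
    cl <- tibble::tibble(barcode = tr$barcode,
                         category = sample(vocab, 50, TRUE))
    cm3 <- confusion(cl, tr, vocabulary = vocab)
    expect_equal(sum(diag(cm3)) / sum(cm3), mean(cl$category == tr$category))
    # row sums equal per-true-class counts
    expect_equal(as.vector(rowSums(cm3)),
                 as.vector(table(factor(tr$category, vocab))))
  })
  expect_error(confusion(calls, truth[1:2, ]), "missing from truth")
  truth_bad <- truth; truth_bad$category[1] <- "astrocyte"
  expect_error(confusion(calls, truth_bad), "outside vocabulary")
})

test_that("gate sensitivity/specificity are the immune-wise proportions", {
  calls <- tibble::tibble(barcode = paste0("c", 1:5),
                          is_immune = c(TRUE, TRUE, FALSE, FALSE, TRUE))
  truth <- tibble::tibble(barcode = paste0("c", 1:5),
                          is_immune = c(TRUE, TRUE, TRUE, FALSE, FALSE))
  gm <- gate_metrics(calls, truth)
  expect_equal(gm$sensitivity, 2 / 3)
  expect_equal(gm$specificity, 1 / 2)
  all_right <- gate_metrics(truth, truth)
  expect_equal(unlist(all_right), c(sensitivity = 1, specificity = 1))
  flipped <- dplyr::mutate(truth, is_immune = !is_immune)
  expect_equal(unlist(gate_metrics(flipped, truth)),
               c(sensitivity = 0, specificity = 0))
  expect_error(gate_metrics(calls, dplyr::mutate(truth, is_immune = TRUE)),
               "both immune and non-immune")
})

test_that("evaluate_calls bundles accuracy, confusion and gate metrics", {
  s <- small_sim(seed = 77)
  res <- run_pipeline(s$sim$matrix, s$cfg$signature, min_total = 0)
  rep <- evaluate_calls(res$calls, s$sim$truth,
                        vocabulary = c(s$cfg$signature$types, "non-immune"))
  expect_s3_class(rep, "eval_report")
  expect_equal(sum(rep$confusion), nrow(res$calls))
  expect_equal(rep$accuracy$accuracy,
               sum(diag(rep$confusion)) / sum(rep$confusion))
  expect_true(rep$gate$sensitivity >= 0 && rep$gate$specificity >= 0)
})
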