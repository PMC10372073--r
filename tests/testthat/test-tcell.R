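test_that("training pools the configured cells per source deterministically", {
  src <- small_tcell_sources(seed = 3)
  ts <- assemble_training_set(src, 100, seed = 9)
  expect_equal(length(ts$labels), 400L)
  expect_equal(sum(ts$labels == "CD4"), 200L)
  expect_identical(ts$matrix$layer, "lognormalized")
  # per-cell totals were scaled to 10,000 before the log
  expect_equal(unname(Matrix::colSums(expm1(ts$matrix$counts))),
               rep(10000, 400), tolerance = 1e-6)
  ts2 <- assemble_training_set(src, 100, seed = 9)
  expect_identical(ts$picked, ts2$picked)
  expect_identical(as.matrix(ts$matrix$counts), as.matrix(ts2$matrix$counts))
  # exhaustive sampling is order-canonical
  ts3 <- assemble_training_set(src, 150, seed = 1)
  expect_identical(ts3$picked[[1]], 1:150)
  expect_error(assemble_training_set(src, 151, seed = 1), "151 requested")
})

test_that("two-stage fit selects separating genes and reaches perfect resubstitution", {
  src <- small_tcell_sources(seed = 13)
  ts <- assemble_training_set(src, 120, seed = 4)
  cfg <- fast_tcell_config(seed = 4)
  model <- train_tcell(ts$matrix, ts$labels, cfg)
  # the informative genes are the two marker blocks (TG0001..TG0050)
  marker_frac <- mean(model$selected_genes %in% sprintf("TG%04d", 1:50))
  expect_gt(marker_frac, 0.8)
  pred <- predict_tcell(model, ts$matrix)
  expect_gt(mean(pred$label == ts$labels), 0.99)
  # feature-selection soundness against the stage-1 importances
  imp <- model$importance
  expect_true(all(imp$gain[imp$gene %in% model$selected_genes] > 1e-7))
  expect_true(all(imp$gain[!imp$gene %in% model$selected_genes] <= 1e-7))
  # selection threshold is strict: a gene at exactly the cutoff is dropped
  g_top <- imp$gain[match(model$selected_genes[1], imp$gene)]
  cfg_at <- cfg; cfg_at$importance_threshold <- g_top
  model_at <- train_tcell(ts$matrix, ts$labels, cfg_at)
  expect_false(model$selected_genes[1] %in% model_at$selected_genes)
  # degenerate input
  expect_error(train_tcell(ts$matrix, rep("CD4", length(ts$labels)), cfg),
               "both CD4 and CD8")
})

test_that("training and prediction are deterministic under a fixed seed", {
  src <- small_tcell_sources(seed = 8)
  ts <- assemble_training_set(src, 100, seed = 6)
  cfg <- fast_tcell_config(seed = 6)
  m1 <- train_tcell(ts$matrix, ts$labels, cfg)
  m2 <- train_tcell(ts$matrix, ts$labels, cfg)
  expect_identical(m1$selected_genes, m2$selected_genes)
  expect_identical(predict_tcell(m1, ts$matrix)$margin,
                   predict_tcell(m2, ts$matrix)$margin)
})

test_that("prediction zero-fills absent genes and handles edge inputs", {
  src <- small_tcell_sources(seed = 8)
  ts <- assemble_training_set(src, 100, seed = 6)
  model <- train_tcell(ts$matrix, ts$labels, fast_tcell_config(seed = 6))
  # all-zero cell: a valid label on the model's prior side, no crash
  zero <- matrix(0, 1, length(model$selected_genes),
                 dimnames = list("z1", model$selected_genes))
  p0 <- predict_tcell(model, zero)
  expect_true(p0$label %in% c("CD4", "CD8"))
  # duplicated cell gets identical outputs
  two <- rbind(zero, zero); rownames(two) <- c("z1", "z2")
  p2 <- predict_tcell(model, two)
  expect_identical(p2$margin[1], p2$margin[2])
  # a matrix missing half the genes still predicts (zero-filled)
  keep <- model$selected_genes[seq_len(ceiling(length(model$selected_genes) / 2))]
  sub <- ts$matrix
  sub$counts <- sub$counts[keep, , drop = FALSE]
  expect_silent(predict_tcell(model, sub))
})

test_that("repeated-resampling CV separates signal from a permutation null", {
  src <- small_tcell_sources(seed = 13)
  cfg <- fast_tcell_config(seed = 7)
  cv <- cross_validate_tcell(src, 100, cfg, rounds = 3)
  expect_true(all(cv$accuracy >= 0.99))
  expect_equal(glance(cv)$mean_accuracy, mean(cv$accuracy))
  cv2 <- cross_validate_tcell(src, 100, cfg, rounds = 3)
  expect_identical(cv$accuracy, cv2$accuracy)
  # null sources: no class signal at all -> chance-level accuracy
  null_src <- simulate_tcell_sources(n_sources_cd4 = 2, n_sources_cd8 = 2,
                                     cells_per_source = 150, n_genes = 120,
                                     mu_marker = 1, mu_cross = 1,
                                     batch_effect_sd = 0, seed = 19)
  cv_null <- cross_validate_tcell(null_src, 100, cfg, rounds = 2)
  expect_lt(abs(glance(cv_null)$mean_accuracy - 0.5), 0.1)
  expect_error(cross_validate_tcell(src, 150, cfg), "test remainder")
})

test_that("a saved model reloads with identical predictions and manifest", {
  src <- small_tcell_sources(seed = 23)
  ts <- assemble_training_set(src, 80, seed = 11)
  model <- train_tcell(ts$matrix, ts$labels, fast_tcell_config(seed = 11))
  dir <- withr::local_tempdir()
  save_tcell_model(model, dir)
  expect_true(file.exists(file.path(dir, "model.json")))
  back <- load_tcell_model(dir)
  expect_identical(back$selected_genes, model$selected_genes)
  expect_equal(predict_tcell(back, ts$matrix)$margin,
               predict_tcell(model, ts$matrix)$margin, tolerance = 1e-6)
  expect_identical(glance(back), glance(model))
  td <- tidy(model)
  expect_true(all(td$selected == (td$gain > model$config$importance_threshold)))
})
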