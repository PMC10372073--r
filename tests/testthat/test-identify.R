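test_that("the linear rule is strict at the threshold and monotone", {
  p <- boundary_params()
  expect_equal(p$A, 1580.7)
  expect_equal(p$theta, 413)
  g <- immune_gate(c(0, 0, 1, 0.2), c(412, 414, 0, 50), p)
  expect_identical(g$is_immune, c(FALSE, TRUE, TRUE, FALSE))
  expect_equal(g$linear_score[4], 1580.7 * 0.2 + 50)
  # exactly at theta is non-immune (strict >)
  expect_false(immune_gate(0, 413, p)$is_immune)
  # monotone in each metric with the other held fixed
  expect_true(all(diff(immune_gate(seq(0, 1, 0.1), 100, p)$linear_score) > 0))
  expect_true(all(diff(immune_gate(0.3, seq(0, 500, 50), p)$linear_score) > 0))
})

test_that("profile correlations match a brute-force Pearson oracle", {
  sig <- toy_signature()
  # scaled copy of a binary column correlates perfectly with it
  expect_equal(unname(profile_correlations(c(7, 0, 0), sig)[1, "TypeA"]), 1)
  # constant vector: zero-variance convention returns 0
  expect_equal(unname(profile_correlations(c(3, 3, 3), sig)[1, ]), c(0, 0))
  # 4-gene case against the textbook formula
  sig4 <- immune_signature(matrix(c(0, 0, 1, 1), 4, 1,
                                  dimnames = list(paste0("g", 1:4), "T1")))
  expect_equal(unname(profile_correlations(c(1, 2, 3, 4), sig4)[1, 1]),
               pearson_brute(c(1, 2, 3, 4), c(0, 0, 1, 1)),
               tolerance = 1e-12)
  # randomized agreement at tight tolerance
  withr::with_seed(99, {
    for (i in 1:200) {
      g <- sample(5:30, 1)
      x <- rpois(g, 3) * runif(g)
      col <- rbinom(g, 1, 0.4)
      if (sum(col) == 0) col[1] <- 1
      s <- immune_signature(matrix(col, g, 1,
                                   dimnames = list(paste0("g", 1:g), "T")))
      expect_equal(unname(profile_correlations(x, s)[1, 1]),
                   pearson_brute(x, col), tolerance = 1e-10)
    }
  })
})

test_that("alignment zero-fills missing signature genes and reports them", {
  sig <- toy_signature()
  m <- toy_counts(cbind(c(5, 3), c(1, 1)), genes = c("G2", "g1"))
  n <- normalize_cells(m, 10)
  a <- align_to_signature(n, sig)
  expect_identical(rownames(a$counts), sig$genes)  # signature order
  expect_equal(unname(as.matrix(a$counts)[, 1]), c(3.75, 6.25, 0))
  expect_identical(attr(a, "missing_genes"), 1L)
  # >50% missing requires an explicit override
  m2 <- toy_counts(matrix(c(1L, 1L), 1, 2, dimnames = list("g1", c("a", "b"))))
  n2 <- normalize_cells(m2, 10)
  expect_error(align_to_signature(n2, sig), "allow_sparse_signature")
  expect_silent(align_to_signature(n2, sig, allow_sparse_signature = TRUE))
  m3 <- toy_counts(matrix(c(1L, 1L), 1, 2, dimnames = list("zz", c("a", "b"))))
  expect_error(align_to_signature(normalize_cells(m3, 10), sig),
               "no signature genes")
})

test_that("score_cells ties rho and T together and is permutation-invariant", {
  s <- small_sim(seed = 21)
  norm <- normalize_cells(filter_cells(s$sim$matrix), 10000)
  sc <- score_cells(norm, s$cfg$signature)
  expect_identical(nrow(sc), ncol(norm$counts))
  expect_true(all(sc$total_immune_expression >= 0 &
                    sc$total_immune_expression <= 10000 + 1e-6))
  expect_equal(sc$linear_score,
               1580.7 * sc$rho_max + sc$total_immune_expression)
  expect_identical(sc$is_immune, sc$linear_score > 413)
  rho <- attr(sc, "rho")
  expect_equal(sc$rho_max, unname(apply(rho, 1, max)))
  # shuffling gene rows leaves every record unchanged
  perm <- withr::with_seed(4, sample(nrow(norm$counts)))
  shuffled <- norm
  shuffled$counts <- norm$counts[perm, ]
  sc2 <- score_cells(shuffled, s$cfg$signature)
  expect_equal(sc2, sc, ignore_attr = TRUE)
  # all-zero normalized input is gated by T alone through the rho=0 convention
  expect_error(score_cells(s$sim$matrix, s$cfg$signature), "normalized layer")
})

test_that("ROC staircase AUC equals brute-force concordance, ties at half", {
  expect_equal(auc(roc_curve(c(3, 2, 1), c(1, 1, 0))), 1)
  expect_equal(auc(roc_curve(c(1, 1), c(1, 0))), 0.5)
  expect_error(roc_curve(c(1, 2), c(1, 1)), "both classes")
  withr::with_seed(31, {
    for (i in 1:50) {
      n <- 20
      scores <- sample(1:8, n, replace = TRUE)  # many ties
      labels <- rbinom(n, 1, 0.5)
      if (length(unique(labels)) < 2) labels[1:2] <- c(0, 1)
      expect_equal(auc(roc_curve(scores, labels)),
                   auc_brute(scores, labels), tolerance = 1e-12)
    }
  })
})

test_that("AUC also agrees with pROC as a second independent route", {
  withr::with_seed(47, {
    for (i in 1:20) {
      n <- 40
      scores <- rnorm(n) + rep(c(0, 1), each = n / 2)
      labels <- rep(c(0, 1), each = n / 2)
      ours <- auc(roc_curve(scores, labels))
      ref <- as.numeric(pROC::auc(pROC::roc(
        response = labels, predictor = scores, quiet = TRUE,
        direction = "<", levels = c(0, 1))))
      expect_equal(ours, ref, tolerance = 1e-12)
    }
  })
})

test_that("boundary fitting recovers separable clouds and breaks ties low", {
  immune <- tibble::tibble(rho_max = rep(0.9, 30),
                           total_immune_expression = rep(9000, 30))
  nonimm <- tibble::tibble(rho_max = rep(0.05, 30),
                           total_immune_expression = rep(100, 30))
  fit <- fit_boundary(immune, nonimm)
  expect_equal(fit$sensitivity, 1)
  expect_equal(fit$specificity, 1)
  expect_equal(fit$auc, 1)
  expect_equal(fit$youden, 1)
  # perfect separation already at A = 0: smallest A, then smallest theta wins
  expect_equal(fit$params$A, 0)
  expect_equal(fit$params$theta, 100)
  expect_error(fit_boundary(immune[0, ], nonimm), "empty")
  expect_error(fit_boundary(immune, nonimm, n_grid = 1), "degenerate")
})

test_that("identical score distributions give chance-level AUC", {
  withr::with_seed(17, {
    x <- tibble::tibble(rho_max = runif(400),
                        total_immune_expression = runif(400, 0, 1000))
    y <- tibble::tibble(rho_max = runif(400),
                        total_immune_expression = runif(400, 0, 1000))
    fit <- fit_boundary(x, y)
    expect_lt(abs(fit$auc - 0.5), 0.08)
  })
})

test_that("boundary_fit tidiers expose the fitted rule", {
  immune <- tibble::tibble(rho_max = runif(20, 0.5, 1),
                           total_immune_expression = runif(20, 3000, 9000))
  nonimm <- tibble::tibble(rho_max = runif(20, 0, 0.2),
                           total_immune_expression = runif(20, 0, 300))
  fit <- fit_boundary(immune, nonimm)
  td <- tidy(fit)
  expect_identical(td$term, c("A", "theta"))
  gl <- glance(fit)
  expect_named(gl, c("auc", "sensitivity", "specificity", "youden",
                     "n_immune", "n_nonimmune"))
})
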