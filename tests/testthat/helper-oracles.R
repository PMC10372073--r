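# Independent oracles, deliberately naive and separate from the package code.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Textbook Pearson correlation from the raw sum formula.
pearson_brute <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  num <- n * sum(x * y) - sx * sy
  den <- sqrt(n * sum(x^2) - sx^2) * sqrt(n * sum(y^2) - sy^2)
  if (den == 0) return(0)
  num / den
}

# AUC as the pairwise concordance fraction (ties count 1/2), O(n^2).
auc_brute <- function(scores, labels) {
  pos <- scores[as.logical(labels)]
  neg <- scores[!as.logical(labels)]
  total <- 0
  for (p in pos) total <- total + sum(p > neg) + 0.5 * sum(p == neg)
  total / (length(pos) * length(neg))
}

# Small fixtures ------------------------------------------------------------

toy_signature <- function() {
  v <- matrix(c(1, 0,
                0, 1,
                0, 0), nrow = 3, byrow = TRUE)
  immune_signature(v, genes = c("g1", "g2", "g3"),
                   types = c("TypeA", "TypeB"))
}

toy_counts <- function(values, genes = NULL, cells = NULL, layer = "raw") {
  m <- as.matrix(values)
  if (is.null(genes)) genes <- rownames(m) %||% paste0("g", seq_len(nrow(m)))
  if (is.null(cells)) cells <- colnames(m) %||% paste0("c", seq_len(ncol(m)))
  dimnames(m) <- list(genes, cells)
  cell_matrix(m, layer = layer)
}

small_sim <- function(seed = 7, n_per_type = 60, n_nonimmune = 80) {
  cfg <- sim_config(signature = generate_signature(90, 3, 20),
                    n_immune_per_type = n_per_type,
                    n_nonimmune = n_nonimmune,
                    n_genes_background = 150, seed = seed)
  list(cfg = cfg, sim = simulate_cells(cfg))
}

small_tcell_sources <- function(seed = 3) {
  simulate_tcell_sources(n_sources_cd4 = 2, n_sources_cd8 = 2,
                         cells_per_source = 150, n_genes = 120,
                         seed = seed)
}

fast_tcell_config <- function(seed = 5) {
  tcell_config(n_rounds = 80, early_stopping = 20, seed = seed)
}
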