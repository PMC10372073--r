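#' Generate a block-structured binary signature stand-in
#'
#' Builds a gene-by-type binary matrix with disjoint marker blocks of
#' `markers_per_type` genes per type; any remaining genes are all-zero
#' rows (markers of no type), mirroring the shape of the 547-gene,
#' 22-type leukocyte signature without claiming its content. The layout
#' is deterministic; `seed` is accepted for interface symmetry with the
#' other generators.
#'
#' @param n_genes Total rows.
#' @param n_types Number of type columns.
#' @param markers_per_type Markers per type; `n_types * markers_per_type`
#'   must not exceed `n_genes`.
#' @param seed Unused (the layout is deterministic).
#' @param type_labels Column labels; defaults to [lm22_types()] when
#'   `n_types == 22`, else `Type1..K`.
#' @return An `immune_signature`.
#' @export
generate_signature <- function(n_genes, n_types, markers_per_type,
                               seed = NULL, type_labels = NULL) {
  if (n_types * markers_per_type > n_genes) {
    abort("n_types * markers_per_type exceeds n_genes")
  }
  if (n_types < 1 || markers_per_type < 1) abort("need >= 1 type and marker")
  if (is.null(type_labels)) {
    type_labels <- if (n_types == 22L) lm22_types() else
      paste0("Type", seq_len(n_types))
  }
  stopifnot(length(type_labels) == n_types)
  v <- matrix(0, n_genes, n_types)
  for (k in seq_len(n_types)) {
    v[(k - 1L) * markers_per_type + seq_len(markers_per_type), k] <- 1
  }
  genes <- sprintf("SG%04d", seq_len(n_genes))
  immune_signature(v, genes = genes, types = type_labels)
}

spread_counts <- function(total, k) {
  base <- total %/% k
  extra <- total %% k
  base + c(rep(1L, extra), rep(0L, k - extra))
}

#' Simulation configuration for labeled immune / non-immune cells
#'
#' Negative-binomial counts with gene-independent dispersion,
#' Bernoulli dropout, and multiplicative lognormal library-size factors —
#' the simplest generative model reproducing single-cell over-dispersion
#' and the immune vs non-immune separation of the two gate metrics.
#' An immune cell of type k draws its type's marker genes at `mu_marker`,
#' other signature genes at `mu_offsignature`, background genes at
#' `mu_background`; a non-immune cell draws signature genes at a low mean
#' and concentrates mass on background genes so its expected normalized
#' signature mass is `nonimmune_marker_fraction * scale`. Defaults put
#' immune cells' total immune gene expression around 2,000-6,000 and
#' non-immune cells' below ~300, straddling the published threshold 413.
#'
#' @param signature An `immune_signature`; default a 547x22 block
#'   stand-in with 24 markers per type.
#' @param n_immune_per_type Immune cells per signature type (single
#'   number recycled, or vector of length K). Default spreads 10,000
#'   cells over the types.
#' @param n_nonimmune Non-immune cells (default 3,000).
#' @param n_genes_background Non-signature genes (default 1,500).
#' @param mu_marker,mu_offsignature,mu_background Raw-count means.
#' @param nonimmune_signature_mu Mean on signature genes for non-immune
#'   cells.
#' @param nonimmune_marker_fraction Expected fraction of a non-immune
#'   cell's normalized mass on signature genes.
#' @param dispersion NB size parameter (Inf = Poisson).
#' @param dropout_rate Bernoulli zero-inflation probability in `[0, 1)`.
#' @param library_sdlog sdlog of the per-cell lognormal library factor.
#' @param n_samples Cells are assigned round-robin to this many sample
#'   ids (for composition profiling).
#' @param seed Master seed; all randomness derives from it.
#' @return A `sim_config` list.
#' @export
sim_config <- function(signature = generate_signature(547L, 22L, 24L),
                       n_immune_per_type = NULL,
                       n_nonimmune = 3000L,
                       n_genes_background = 1500L,
                       mu_marker = 20, mu_offsignature = 0.5,
                       mu_background = 1,
                       nonimmune_signature_mu = 0.1,
                       nonimmune_marker_fraction = 0.02,
                       dispersion = 2, dropout_rate = 0.3,
                       library_sdlog = 0.4, n_samples = 1L, seed = 1L) {
  stopifnot(inherits(signature, "immune_signature"),
            mu_marker > 0, mu_offsignature > 0, mu_background > 0,
            dropout_rate >= 0, dropout_rate < 1, dispersion > 0,
            nonimmune_marker_fraction >= 0, nonimmune_marker_fraction < 1)
  k <- length(signature$types)
  if (is.null(n_immune_per_type)) {
    n_immune_per_type <- spread_counts(10000L, k)
  } else if (length(n_immune_per_type) == 1L) {
    n_immune_per_type <- rep(as.integer(n_immune_per_type), k)
  }
  stopifnot(length(n_immune_per_type) == k)
  structure(list(signature = signature,
                 n_immune_per_type = as.integer(n_immune_per_type),
                 n_nonimmune = as.integer(n_nonimmune),
                 n_genes_background = as.integer(n_genes_background),
                 mu_marker = mu_marker, mu_offsignature = mu_offsignature,
                 mu_background = mu_background,
                 nonimmune_signature_mu = nonimmune_signature_mu,
                 nonimmune_marker_fraction = nonimmune_marker_fraction,
                 dispersion = dispersion, dropout_rate = dropout_rate,
                 library_sdlog = library_sdlog,
                 n_samples = as.integer(n_samples),
                 seed = as.integer(seed)),
            class = "sim_config")
}

# NB draws (Poisson in the size->Inf limit) with dropout, as a sparse block.
draw_block <- function(mu_vec, n_cells, dispersion, dropout, lib_factors) {
  g <- length(mu_vec)
  mu <- outer(mu_vec, lib_factors)  # g x n expected counts
  x <- if (is.infinite(dispersion)) {
    stats::rpois(g * n_cells, lambda = as.vector(mu))
  } else {
    stats::rnbinom(g * n_cells, size = dispersion, mu = as.vector(mu))
  }
  if (dropout > 0) {
    x <- x * (stats::runif(g * n_cells) >= dropout)
  }
  methods::as(Matrix::Matrix(matrix(as.double(x), g, n_cells), sparse = TRUE),
              "CsparseMatrix")
}

#' Simulate a labeled immune / non-immune count matrix
#'
#' @param cfg A [sim_config()].
#' @return List with `matrix` (a raw `cell_matrix`) and `truth` (tibble
#'   `barcode`, `cell_type` — signature type label or `"non-immune"` —
#'   `category`, `is_immune`, `sample`).
#' @export
simulate_cells <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  sig <- cfg$signature
  n_sig <- length(sig$genes)
  bg_genes <- sprintf("BG%04d", seq_len(cfg$n_genes_background))
  all_genes <- c(sig$genes, bg_genes)
  k <- length(sig$types)

  blocks <- vector("list", k + 1L)
  types_out <- character(0)
  withr::with_seed(cfg$seed, {
    for (j in seq_len(k)) {
      n <- cfg$n_immune_per_type[j]
      if (n == 0L) { blocks[[j]] <- NULL; next }
      mu_sig <- ifelse(sig$values[, j] == 1, cfg$mu_marker,
                       cfg$mu_offsignature)
      mu_vec <- c(mu_sig, rep(cfg$mu_background, cfg$n_genes_background))
      lib <- stats::rlnorm(n, meanlog = 0, sdlog = cfg$library_sdlog)
      blocks[[j]] <- draw_block(mu_vec, n, cfg$dispersion,
                                cfg$dropout_rate, lib)
      types_out <- c(types_out, rep(sig$types[j], n))
    }
    if (cfg$n_nonimmune > 0L) {
      f <- cfg$nonimmune_marker_fraction
      if (f > 0) {
        mu_sig_ni <- cfg$nonimmune_signature_mu
        sig_mass <- n_sig * mu_sig_ni
        mu_bg_ni <- sig_mass * (1 - f) / (f * cfg$n_genes_background)
      } else {
        mu_sig_ni <- 0
        mu_bg_ni <- cfg$mu_background
      }
      mu_vec <- c(rep(mu_sig_ni, n_sig),
                  rep(mu_bg_ni, cfg$n_genes_background))
      mu_vec[mu_vec == 0] <- 1e-12  # NB mean must be positive
      lib <- stats::rlnorm(cfg$n_nonimmune, meanlog = 0,
                           sdlog = cfg$library_sdlog)
      blocks[[k + 1L]] <- draw_block(mu_vec, cfg$n_nonimmune,
                                     cfg$dispersion, cfg$dropout_rate, lib)
      types_out <- c(types_out, rep("non-immune", cfg$n_nonimmune))
    }
  })
  counts <- do.call(cbind, blocks[!vapply(blocks, is.null, logical(1))])
  n_total <- ncol(counts)
  barcodes <- sprintf("cell%06d", seq_len(n_total))
  dimnames(counts) <- list(all_genes, barcodes)
  cmap <- category_map_for(sig$types)
  is_imm <- types_out != "non-immune"
  truth <- tibble::tibble(
    barcode = barcodes,
    cell_type = types_out,
    category = ifelse(is_imm, map_to_category_vec(cmap, types_out),
                      "non-immune"),
    is_immune = is_imm,
    sample = paste0("sample", (seq_len(n_total) - 1L) %% cfg$n_samples + 1L)
  )
  list(matrix = cell_matrix(counts, layer = "raw"), truth = truth)
}

# vectorised category lookup tolerating the "non-immune" placeholder
map_to_category_vec <- function(cmap, types) {
  out <- rep(NA_character_, length(types))
  hit <- types %in% cmap$type
  out[hit] <- map_to_category(cmap, types[hit])
  out
}

#' Simulate multi-study CD4/CD8 T-cell sources
#'
#' Emulates the between-study heterogeneity that motivates pooled
#' training: every source gets its own per-gene multiplicative lognormal
#' batch factor (shared by all its cells), CD4 sources elevate the CD4
#' marker block and CD8 sources the CD8 block, and counts follow the same
#' NB + dropout + library-size model as [simulate_cells()].
#'
#' @param n_sources_cd4,n_sources_cd8 Numbers of sources per class
#'   (defaults 10 and 5, the published training design).
#' @param cells_per_source Cells per source (default 1,500, so drawing
#'   1,000 leaves a held-out remainder).
#' @param n_genes Gene universe size (default 600).
#' @param cd4_markers,cd8_markers Disjoint marker gene index vectors;
#'   defaults to the first two blocks of 25 genes.
#' @param mu_marker Mean of a class's own markers (default 15).
#' @param mu_cross Mean of the opposite class's markers (default 0.2).
#' @param mu_background Background gene mean (default 1).
#' @param dispersion,dropout_rate,library_sdlog As in [sim_config()].
#' @param batch_effect_sd sdlog of the per-source per-gene batch factor.
#' @param seed Master seed.
#' @return Named list of `list(matrix = <cell_matrix raw>, label)`
#'   entries, suitable for [assemble_training_set()] /
#'   [cross_validate_tcell()].
#' @export
simulate_tcell_sources <- function(n_sources_cd4 = 10L, n_sources_cd8 = 5L,
                                   cells_per_source = 1500L, n_genes = 600L,
                                   cd4_markers = 1:25, cd8_markers = 26:50,
                                   mu_marker = 15, mu_cross = 0.2,
                                   mu_background = 1, dispersion = 2,
                                   dropout_rate = 0.3, library_sdlog = 0.4,
                                   batch_effect_sd = 0.3, seed = 1L) {
  if (length(intersect(cd4_markers, cd8_markers)) > 0) {
    abort("cd4_markers and cd8_markers must be disjoint")
  }
  if (max(c(cd4_markers, cd8_markers)) > n_genes) {
    abort("marker indices exceed n_genes")
  }
  gene_names <- sprintf("TG%04d", seq_len(n_genes))
  labels <- c(rep("CD4", n_sources_cd4), rep("CD8", n_sources_cd8))
  src_names <- c(sprintf("CD4_%d", seq_len(n_sources_cd4)),
                 sprintf("CD8_%d", seq_len(n_sources_cd8)))
  out <- vector("list", length(labels))
  withr::with_seed(as.integer(seed), {
    for (s in seq_along(labels)) {
      own <- if (labels[s] == "CD4") cd4_markers else cd8_markers
      other <- if (labels[s] == "CD4") cd8_markers else cd4_markers
      mu_vec <- rep(mu_background, n_genes)
      mu_vec[own] <- mu_marker
      mu_vec[other] <- mu_cross
      batch <- stats::rlnorm(n_genes, meanlog = 0, sdlog = batch_effect_sd)
      lib <- stats::rlnorm(cells_per_source, meanlog = 0,
                           sdlog = library_sdlog)
      counts <- draw_block(mu_vec * batch, cells_per_source, dispersion,
                           dropout_rate, lib)
      dimnames(counts) <- list(
        gene_names, sprintf("%s-c%05d", src_names[s],
                            seq_len(cells_per_source)))
      out[[s]] <- list(matrix = cell_matrix(counts, layer = "raw"),
                       label = labels[s])
    }
  })
  stats::setNames(out, src_names)
}
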