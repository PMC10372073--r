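# immunocall

Identify and annotate immune cells in single-cell RNA-seq count matrices.

Mixed specimens — blood, tumors, inflamed tissue — contain immune and
non-immune cells, and clustering-based annotation of them is notoriously
study-specific: the same cell type from two datasets often refuses to
co-cluster. immunocall instead scores every cell against a fixed
binarized leukocyte signature matrix (the 547-gene × 22-type LM22 gene
set, consumed as 0/1 marker membership) and makes all decisions with two
per-cell statistics:

* **ρ_max** — the maximum Pearson correlation between the cell's
  normalized expression over the signature genes and any of the 22 binary
  type profiles;
* **T** — the total immune gene expression: the cell's summed normalized
  expression over the signature genes (each cell is scaled to a total of
  10,000, so T ∈ [0, 10000]).

A cell is called **immune** when the linear rule

```
A · ρ_max + T > θ        (defaults A = 1580.7, θ = 413)
```

holds — the constants are fixed across datasets, no per-study retraining.
Immune cells are then typed by the signature column attaining ρ_max,
collapsed onto nine categories (B cell, plasma cell, T cell, NK cell,
monocyte, macrophage, dendritic cell, neutrophil, other myeloid), and
T cells can be refined into **CD4+ / CD8+** by a gradient-boosted tree
classifier (depth-3 trees, η = 0.01, gain-importance feature selection at
a strict 1e-7 cutoff, refit on the selected genes). Per-sample immune
composition and rank-based two-group comparison (Mann–Whitney U) complete
the pipeline. A negative-binomial synthetic-data generator with known
ground truth makes every stage testable offline.

It is intended for immunologists and computational biologists who want a
deterministic, reference-based immune annotation that behaves identically
across 10x-style and plate-based datasets.

## Worked example

Simulate a labeled mixture with a 3-type toy signature, run the pipeline,
and evaluate against the known truth:

```r
library(immunocall)

sig <- generate_signature(n_genes = 90, n_types = 3, markers_per_type = 20,
                          type_labels = c("B cells naive", "T cells CD8",
                                          "NK cells resting"))
cfg <- sim_config(signature = sig, n_immune_per_type = 300, n_nonimmune = 200,
                  n_genes_background = 400, seed = 1)
sim <- simulate_cells(cfg)

res <- run_pipeline(sim$matrix, sig, min_total = 300)
dplyr::count(res$calls, category)
#> # A tibble: 4 × 2
#>   category       n
#>   <chr>      <int>
#> 1 B cell       292
#> 2 NK cell      293
#> 3 T cell       296
#> 4 non-immune    82

truth <- sim$truth[match(res$calls$barcode, sim$truth$barcode), ]
auc(roc_curve(res$calls$linear_score, truth$is_immune))
#> [1] 1

evaluate_calls(res$calls, truth,
               vocabulary = c("B cell", "T cell", "NK cell", "non-immune"))
#> <eval_report> accuracy 97.0% [95.9-98.1%] over 963 cells
#>   immune gate: sensitivity 100.0%, specificity 73.9%
```

Reading the output: of the 1,100 simulated cells, 963 survive the QC
filter; the linear score separates immune from non-immune cells perfectly
in rank terms (AUC 1), every truly immune cell passes the gate
(sensitivity 100%), and 97% of all cells receive their true label. The
published θ = 413 was calibrated for full-transcriptome data, so on this
small toy matrix some non-immune cells exceed it (specificity 73.9%) —
`fit_boundary()` refits (A, θ) by Youden's J when a dataset-specific
boundary is wanted.

Real 10x data enters through `read_counts_mtx("matrix.mtx", "genes.tsv",
"barcodes.tsv")` (gzipped files fine), dense tables through
`read_counts_dense()`, and a binarized signature TSV through
`read_signature()`. The same pipeline is available from the shell:

```sh
exec/immunocall run --counts matrix.mtx --genes genes.tsv \
    --barcodes barcodes.tsv --signature lm22_binary.tsv --out results/
```

Training and applying the CD4/CD8 classifier:

```r
src <- simulate_tcell_sources(seed = 1)             # 10 CD4 + 5 CD8 sources
ts  <- assemble_training_set(src, per_source_n = 1000, seed = 1)
model <- train_tcell(ts$matrix, ts$labels)           # two-stage fit
cv  <- cross_validate_tcell(src, 1000, tcell_config(seed = 1))
glance(cv)                                           # five-round mean accuracy
save_tcell_model(model, "tcell_model/")              # JSON manifest + booster
```

Passing `tmodel =` to `run_pipeline()` (or `--tcell-model` on the CLI)
replaces "T cell" calls with "CD4+ T cell" / "CD8+ T cell".

## Package layout

* `R/signature.R` — signature matrix IO/validation, 22→9 category map
* `R/cell-matrix.R`, `R/io.R` — sparse counts container, MTX/dense/CSV IO
* `R/preprocess.R` — QC filter, total-count and log normalization
* `R/identify.R` — gate metrics, linear rule, ROC/AUC, boundary fitting
* `R/annotate.R` — typing, gating order, composition profiling
* `R/tcell.R` — boosted CD4/CD8 classifier (train / select / CV / persist)
* `R/simulate.R` — synthetic signature, mixture, and multi-source T cells
* `R/evaluate.R`, `R/compare.R` — accuracy CIs, confusion, group tests
* `R/pipeline.R`, `exec/immunocall` — end-to-end runner and CLI
* `vignettes/immunocall-methods.Rmd` — the model, assumptions, and
  numerical choices in detail
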