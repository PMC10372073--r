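---
title: "Methods: immune cell identification and annotation in immunocall"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: immune cell identification and annotation in immunocall}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Single-cell RNA-seq of blood and solid tissue yields a mixture of immune
and non-immune cells. Clustering-based annotation is driven as much by
study-specific batch signatures as by cell identity, so the same cell type
from two studies often lands in different clusters. immunocall instead
scores every cell against a fixed, dataset-independent reference — a
binarized leukocyte signature matrix of 547 marker genes by 22 immune cell
types (the LM22 gene set, consumed as 0/1 marker membership) — and makes
all decisions with two simple per-cell statistics. This keeps the decision
rule identical across datasets and platforms and requires no per-study
retraining.

## The model

### Preprocessing

Cells with total raw count below 500 are removed (a cell at exactly 500 is
kept), each retained cell is scaled to a total of 10,000, and — only where
the boosted classifier is involved — values are `log1p`-transformed
(natural log). No gene-level filtering is applied. The 10,000 target makes
every downstream quantity a relative expression on a common per-cell
budget.

### The immune gate

For each cell two metrics are computed on the signature gene basis:

* $\rho_{\max}$ — the maximum over the 22 signature columns of the Pearson
  correlation between the cell's normalized expression over the 547
  signature genes and the binary column profile. Unitless, in $[-1, 1]$.
* $T$ — the total immune gene expression: the sum of the cell's normalized
  expression over the signature genes. Because of the per-cell budget,
  $T \in [0, 10{,}000]$ and equals 10,000 only if all of a cell's reads
  fall on signature genes.

A cell is called immune when

$$A \cdot \rho_{\max} + T > \theta,$$

with defaults $A = 1580.7$ and $\theta = 413$ — the published constants,
applied unchanged to every dataset. The inequality is strict: a cell whose
score is exactly $\theta$ is non-immune. `fit_boundary()` can refit
$(A, \theta)$ on labeled clouds by maximizing Youden's
$J = \text{sensitivity} + \text{specificity} - 1$, but refitting is an
explicit, optional step and never happens implicitly.

### Typing and CD4/CD8 refinement

Gating precedes typing: a cell failing the linear rule is labeled
`non-immune` and never typed. An immune cell takes the signature column
attaining $\rho_{\max}$, collapsed onto nine categories (B cell, plasma
cell, T cell, NK cell, monocyte, macrophage, dendritic cell, neutrophil,
other myeloid) by a user-overridable map; the shipped default sends the
seven T-cell columns to "T cell", the three macrophage polarization states
to "macrophage", and mast cells plus eosinophils to "other myeloid".

Cells in the T-cell category can be refined into CD4+ or CD8+ by a
gradient-boosted tree classifier operating on log-normalized expression.
Training follows the published recipe: pool cells sampled from multiple
CD4 and CD8 sources (by default 1,000 from each of 10 CD4 and 5 CD8
sources, 15,000 cells), fit with `max_depth = 3`, `eta = 0.01`,
`lambda = 0`, `gamma = 0.1`, `alpha = 0.5`, `subsample = 0.5`, keep the
genes whose gain-based feature importance is strictly greater than
$10^{-7}$, and refit on the kept genes only. The refit model is what is
deployed; the alternative of applying the full-gene model was rejected
because a model whose input contract is its selected gene list is easier
to persist, validate, and apply to datasets with different gene coverage.

Cross-validation mirrors the published scheme as well: each of five rounds
re-draws the per-source training sample and tests on all cells left out of
the draw, reporting per-round and mean accuracy.

## Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| `min_total` | 500 | raw counts | published QC cut; "less than 500" removed, 500 kept |
| `scale` | 10,000 | counts | published per-cell budget; bounds $T$ |
| `A` | 1580.7 | counts per correlation unit | published slope of the linear rule |
| `theta` | 413 | normalized counts | published decision threshold |
| `importance_threshold` | $10^{-7}$ | gain fraction | published cutoff, strict `>` |
| `n_rounds` | 500 | boosting rounds | unstated in the recipe; chosen with early stopping (10% validation split, patience 50) so the effective count adapts to the data |
| `nthread` | 1 | threads | determinism; threading is a speed knob, not part of the model |

## Numerical choices

* **Zero-variance correlation.** A constant cell vector (e.g. all zeros on
  the signature basis) has undefined Pearson correlation; immunocall
  returns 0 — "no evidence" — so such cells are gated on $T$ alone.
* **Argmax ties** break toward the earlier signature column, so typing is
  deterministic.
* **Missing signature genes** are zero-filled rather than dropped: the
  correlation basis stays the fixed 547-gene space, which keeps $\theta$
  comparable across datasets with different gene coverage. More than half
  the basis missing is an error unless explicitly allowed.
* **ROC construction** sweeps the decision threshold over distinct score
  values at fixed slope $A$; the trapezoid area equals the
  pairwise-concordance AUC with ties counted one half (verified against an
  $O(n^2)$ oracle in the tests).
* **Boundary fitting** is a coarse 101×101 grid over
  $A \in [0, 5000]$, $\theta \in [0, \text{scale}]$ followed by one 10×
  local refinement; ties in $J$ resolve toward smaller $A$, then smaller
  $\theta$, so the flattest, lowest boundary among equals is returned.
* **Group comparison** of per-sample composition uses the two-sided
  Mann–Whitney U test: exact enumeration when both groups have at most 8
  samples and no ties, otherwise the tie-corrected normal approximation
  with continuity correction. At the branch boundary ($m = n = 8$) the
  approximation tracks the exact p-value to about 0.011 in the worst case
  — the two branches cannot be made to agree more tightly with the
  standard corrections, which is acceptable at the sample sizes where the
  approximation is actually used. No multiplicity correction is applied
  by default; Benjamini–Hochberg is available behind a flag.
* **Confidence intervals** on accuracies are Wald
  ($p \pm z\sqrt{p(1-p)/n}$, clipped to $[0,1]$), matching the very-large-$n$
  presentation style of the original study; Wilson is available.
* **CD8 is the positive class** of the binary classifier (alphabetical
  order, recorded here so margins are interpretable).
* **Binarization helper.** The published signature is continuous and its
  binarization rule is not stated; the canonical input is therefore an
  already-binarized file, and `binarize_signature()` (mark a gene for every
  type attaining its row maximum) is offered as a labelled stand-in only.

## What the synthetic generator emulates — and what it does not

The generator exists so every stage of the pipeline is testable offline
with known ground truth. It draws negative-binomial counts with a
gene-independent dispersion, Bernoulli dropout, and multiplicative
lognormal library-size factors. Immune cells of type $k$ elevate type
$k$'s marker block; non-immune cells concentrate their mass on background
genes so that their expected normalized signature mass is a small,
configurable fraction. Defaults (547×22 block signature with 24 markers
per type, 1,500 background genes, `mu_marker = 20`,
`mu_offsignature = 0.5`, `mu_background = 1`, dispersion 2, dropout 0.3,
library sdlog 0.4, non-immune signature fraction 0.02) put immune cells'
$T$ around 2,000–6,000 and non-immune cells' below ~300, straddling
$\theta = 413$ the way the published metric distributions do. T-cell
sources add a per-source lognormal batch factor (sdlog 0.3) shared by all
of a source's cells, emulating the between-study heterogeneity that
motivates pooled training; 10 CD4 and 5 CD8 sources of 1,500 cells each
leave a held-out remainder after 1,000-cell draws.

The generator deliberately omits transcriptome-wide co-expression
structure, ambient RNA, doublets, and realistic marker overlap between
related cell types (its marker blocks are disjoint). Synthetic recovery
results therefore demonstrate that the implementation is correct and that
the method works when its assumptions hold — they do not certify the
published real-data accuracies, which were measured on millions of cells
from 66 external studies and are out of scope here.

## Problem sizes used by the test-suite and acceptance script

Most unit tests run on matrices of tens to hundreds of cells built in
code. The synthetic-recovery checks use the generator defaults — 10,000
immune plus 3,000 non-immune cells for the gate and annotation, and the
full 15-source, 1,000-cells-per-source design for five rounds of
classifier cross-validation — which the package processes in a few
minutes on a single thread. The composition-comparison calibration uses
2,000 simulated two-group (6 vs 6 samples) comparisons.

## Known limitations

* The 22→9 category collapse is a pragmatic default; finer subtypes
  (memory B, regulatory T) are deliberately not assigned because maximum
  profile correlation does not resolve them reliably.
* The immune gate assumes the normalization budget of 10,000; scores and
  $\theta$ are not transferable to other budgets without refitting.
* The boosted classifier is binary CD4/CD8 and presumes its input cells
  are T cells; it will happily label anything it is given.
* `binarize_signature()` is a stand-in, not the published binarization.
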