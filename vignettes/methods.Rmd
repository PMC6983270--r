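---
title: "Deconvolution-based doublet detection: model, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deconvolution-based doublet detection: model, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(decondoublet)
```

## The problem

Droplet and well-based single-cell RNA-seq co-captures two cells in a single
library at appreciable rates. Heterotypic doublets — two cells of distinct
type — produce hybrid expression profiles that unsupervised clustering can
mistake for novel cell states. The complication is that genuinely hybrid
transcriptomes also exist: transitional states and mixed-lineage progenitors
co-express two programs. A detector that flags every hybrid profile will
discard exactly the cells developmental studies care most about.

`decondoublet` addresses both sides. Every cell is deconvolved against
reference cluster signatures into a *deconvolution cell profile* (DCP): a
vector of non-negative fractional contributions summing to one. Cells whose
DCP looks more like that of a synthetic cell-pair mixture than like any
reference centroid are flagged (*remove*), flagged cells are grouped by their
top two contributing clusters (*recluster*), and flagged clusters that
uniquely express genes no reference cluster expresses are returned to singlet
status (*rescue*), on the reasoning that a mixture of two cells cannot
express genes neither parent expresses.

## Model and procedure

**References and cluster merging.** Input clusters $C_1,\dots,C_K$ (from an
ICGS- or Seurat-style workflow) are summarized by centroids (per-gene means;
default) or marginal medoids (per-gene medians) over the supplied marker
genes. Let $r_{ij}$ be the Pearson correlation of signatures $i$ and $j$.
Clusters are merged when $r_{ij} \ge \rho_T$ with

$$\rho_T = \operatorname{mean}\{r_{ij}\} + \rho' \cdot \operatorname{sd}\{r_{ij}\},$$

computed over the off-diagonal upper triangle (including the unit diagonal
would inflate both moments when $K$ is small). The binary matrix
$B_{ij} = [r_{ij} \ge \rho_T]$ is partitioned by Markov clustering
(expansion 2, inflation 2, self-loops, convergence below $10^{-6}$ in max
norm); merged signatures are recomputed from the pooled member cells rather
than averaged from old signatures, so downstream deconvolution sees true
merged centroids. If no pair passes the threshold the partition is the
identity and Markov clustering is skipped.

With exactly two clusters the dispersion of a single correlation is
undefined, and substituting zero would make the threshold equal $r_{12}$ —
forcing a merge at any $\rho'$. Two-cluster inputs therefore never merge
unless their signatures are identical, which matches how the method behaves
in practice on two-population (e.g. species-mixing) designs.

**Synthetic doublets.** For each unordered pair of merged clusters, member
cells are sampled uniformly *with replacement* (keeping small clusters
usable) and their log-expression averaged: an even 50/50 set and, unless
`only50`, 70/30 and 30/70 sets ("one", "two"), `num_doubs = 100` profiles
per set by default. For datasets beyond ~1000 cells, about 10% of the cell
count per set is a reasonable choice. Because sampling is random, repeated
runs differ slightly; the pipeline exposes `n_runs` with an intersection
consensus for users who want to trade sensitivity for specificity.

**Deconvolution.** Each profile $y$ is decomposed against the signature
matrix $S$ by solving

$$\hat x = \arg\min_x \|S x - y\|^2 \quad \text{s.t.}\ x \ge 0,\ \textstyle\sum_i x_i = 1,$$

with an active-set method for the equality-constrained non-negative
least-squares problem (KKT solve on the passive set; most-negative-weight
dropping; dual-feasibility re-entry). Weights in $(-10^{-9}, 0)$ are clipped
and the vector renormalized. Note the simplex constraint ties the fit to the
profile's scale: rescaling $y$ defines a different (still exactly solved)
problem, which is why deconvolution operates on the common log-normalized
scale of the marker table. A `zscore` column-scaling mode is available for
data whose signatures differ grossly in magnitude.

**Remove.** Each cell's DCP is compared with every reference centroid's DCP
and every synthetic set's mean DCP — Pearson correlation when there are more
than two references, negative Euclidean distance with exactly two (length-2
simplex vectors make correlation degenerate at $\pm 1$). A cell whose best
match is synthetic becomes a putative doublet; exact ties resolve toward the
singlet interpretation (conservative).

**Recluster.** Putative doublets sharing the same two highest DCP
contributors form doublet clusters labelled `a|b` (ids ascending), with the
weight-class suffix (`.even`, `.one`, `.two`) of the best-matching synthetic
set appended in 30/70 mode for finer-grained rescue.

**Rescue.** For each doublet cluster $Z_j$ against the post-removal clusters
$A^*_1,\dots,A^*_n$, a gene is *uniquely expressed* when (1) the overall
one-way ANOVA across $\{Z_j, A^*_i\}$ has $p \le 0.05$, (2) every
Tukey-adjusted comparison of $Z_j$ with each $A^*_i$ has $p \le 0.05$, and
(3) $Z_j$'s mean strictly exceeds every $A^*_i$'s. A cluster with at least
`min_uniq` unique genes (default 4 on marker genes, 30 when scanning the
full gene list) is rescued whole — rescue is all-or-none at the cluster
level, following the cluster-level definition of the test; the significance
level is fixed at 0.05 and deliberately not exposed as a knob. The ANOVA and
Tukey-Kramer statistics are computed from per-group sizes, sums and sums of
squares over 1,000-gene blocks, which is algebraically identical to the
direct per-gene tests (the suite verifies agreement to $10^{-8}$ and bitwise
independence of block boundaries) but runs in a single pass over arbitrarily
large matrices.

## Parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| `rhop` ($\rho'$) | 1.0 | Merge-threshold scaling; typical range 0.5–1.5. Lower merges more clusters. Under-merging similar clusters deflates specificity (synthetics between near-identical clusters look like singlets); over-merging hides real doublet pairs. `sweep_rho_prime()` tabulates partitions across a grid. |
| `only50` | `FALSE` | `TRUE` restricts synthetics to even mixtures: higher specificity, lower sensitivity. The 30/70 default is appropriate when many doublets are expected (overloaded runs). |
| `num_doubs` | 100 | Synthetic profiles per (pair, weight) set. |
| `min_uniq` ($U$) | 4 (30 full) | Unique genes required to rescue a doublet cluster. The final-doublet set is monotone non-decreasing in $U$. |
| `mode` | centroid | Medoids only help when doublets contribute visibly to cluster means (doublet fraction above ~25% of a cluster). |
| `remove_cc` | `FALSE` | Hypergeometric screen of each gene cluster against a bundled, user-overridable cell-cycle symbol list (GMT), BH-adjusted across gene clusters at 0.05; significant clusters are dropped entirely. The universe is the marker gene table. |
| `seed`, `n_runs` | 1, 1 | Run $r$ uses `seed + r - 1` for synthetic sampling; everything else is deterministic, so two runs with one seed are byte-identical. |

## What the simulator emulates — and what it does not

`simulate_dataset()` builds cluster-structured log-normalized expression:
disjoint 50-gene marker blocks (lift 3.0 log units), Gaussian noise
(sd 0.5, truncated at zero), and a per-cell lognormal
transcriptional-activity factor (sd 0.2 in log units) standing in for
cell-to-cell RNA-content differences. Spiked heterotypic doublets combine
two parent cells *on the molecule scale* ($2^x - 1$, then re-logged), each
parent keeping its own activity factor — a physical doublet adds
transcripts, not log values, and this is what makes real even mixtures
deconvolve asymmetrically (the familiar 30/70 peak) and gives the 30/70
synthetic mode its sensitivity edge over `only50`. A log-space mixing mode
is retained for robustness checks. Homotypic doublets mix two cells of one
cluster and are, by construction, nearly indistinguishable from singlets —
the method does not claim to find them, and the suite asserts that it indeed
does not. Transitional cells express both parent programs at half lift under
a *single* shared activity factor (one cell, one transcriptome size) plus
`n_unique_genes` genes silent everywhere else; they receive a parent
cluster's label in the groups file, as an unsupervised workflow that lumps a
transitional state with its nearest parent would — had they formed their own
labelled cluster they would be their own deconvolution reference and never
be flagged in the first place.

The simulator does not emulate UMI depth gradients, ambient RNA
contamination, batch effects, dropout structure, or gene-gene correlation
beyond the block design. Passing recovery tests on these fixtures therefore
demonstrates the machinery (deconvolution geometry, decision rules, rescue
logic) under clean separability — the regime the method itself assumes
("accurate clustering of the data") — not performance on noisy real tissue.

Default fixture geometry: 2 populations × 500 singlets, 100 spiked
even-weight doublets, 50 transitional cells where enabled. These sizes keep
the full suite under a minute per scenario while leaving all the decision
margins wide; the suite and the acceptance script state their own sizes
explicitly.

## Numerical choices and degenerate inputs

- Active-set solver: KKT systems are solved directly; a singular passive-set
  system (duplicate signatures) falls back to a ridge of $10^{-10}\,
  \mathrm{tr}(S^\top S)$. Rank-deficient signature matrices warn but return
  a solution. All-zero profiles are rejected.
- Zero-variance signature columns make correlations undefined; those entries
  are set to 0 with a warning.
- Markov clustering resolves overlapping attractors by assigning nodes to
  the lowest-indexed cluster; non-convergence raises an error with the
  residual rather than returning a partial partition.
- Genes with zero variance across all rescue groups yield $F = 0$, $p = 1$
  (never unique); zero within-group degrees of freedom yields a warning and
  undefined p-values.
- Exact similarity ties in the remove step resolve toward singlet status.
- In the between-group sum of squares, reductions use `rowSums` rather than
  BLAS matrix products so results are bitwise identical across gene-block
  heights and scheduling.
- Display rounding of percentages and F1 is half-up
  (`round_half_up()`), matching how published benchmark tables round;
  internal values keep full precision.

## Known limitations

- Homotypic doublets and doublets of highly similar states are not
  detectable by construction.
- Rescue is all-or-none per doublet cluster; a per-cell unique-gene
  expression filter within rescued clusters is not implemented, as no
  quantitative definition of such a filter is established.
- Multiplets of more than two cells are out of scope.
- Performance depends on the quality of the upstream clustering and on
  $\rho'$; the package provides the sweep table and run log for auditing
  but no automatic $\rho'$ selection.

## A worked example

```{r example, eval = FALSE}
sim <- simulate_dataset(simulation_params(seed = 7))
res <- run_pipeline(run_config(sim$marker, seed = 7))
res
confusion(res$bundle$final_doublets_groups$cell,
          sim$truth$cell[sim$truth$type == "heterotypic_doublet"],
          sim$truth$cell)
```

The README shows the printed output of this exact run.
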