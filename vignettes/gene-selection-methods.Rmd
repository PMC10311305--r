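---
title: "Label-guided random-forest gene selection: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Label-guided random-forest gene selection: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scGeneForest)
```

## The problem

Clustering single-cell RNA-seq data works far better on a small set of genes
that actually discriminate cell types than on the full transcriptome, where
thousands of genes contribute only technical and biological noise.
Variance-based selections (highly variable genes) ignore how a gene's
expression is distributed *across* putative cell types. scGeneForest instead
asks directly: if we had cell labels, which genes would a classifier rely on
to reproduce them? Since true labels are unknown at selection time, the
package predicts provisional labels by clustering, balances the predicted
classes, and scores genes by how much they contribute to
classifying cells into those labels.

The pipeline is:

1. **Preprocess** — drop genes detected in fewer than `min_cells = 3` cells,
   divide each cell by its depth-based size factor (depth / median depth),
   transform as `log2(x + 1)`.
2. **Predict labels** — PCA to 50 components, Euclidean 15-nearest-neighbour
   graph, spectral partition of the normalized Laplacian into `n` clusters.
3. **Balance** — pick the cluster whose size is nearest `c / n` as the
   *central* cluster; SMOTE-oversample smaller (rare) clusters up to the
   central size; keep the 80% of each larger (major) cluster closest to its
   centroid.
4. **Score** — a forest of decision trees, each grown on *all* cells with a
   random gene subspace, averaged Gini-impurity importance per gene.
5. **Select** — keep genes with importance at or above mu + 3 sigma, then scan the
   importance-ordered list removing any gene whose Pearson correlation with
   a higher-ranked survivor exceeds the dynamic threshold
   `h' = v + v'/(L + 1)`.

## The importance model

At a tree node holding `w` cells with class counts `n_C`, the Gini impurity
is `I = 1 - sum_C (n_C / w)^2`. A binary split into children `(l, r)` earns
the absolute, cell-count-weighted decrease

```
N = w I - w_l I_l - w_r I_r,
```

which is non-negative for any genuine split because weighted Gini is
concave. A tree's importance for gene `i` is the sum of `N` over nodes split
on `i`, normalized by the sum over all internal nodes, so each splitting
tree distributes exactly one unit of importance. The forest importance is
the plain average over trees, with a gene outside a tree's subspace
contributing zero for that tree.

Two deliberate departures from textbook random forests follow the method's
definition rather than library defaults:

* **No bootstrap.** Every tree is trained on all cells, so every tree sees
  the same (predicted) labels and label noise is not resampled.
* **Per-tree gene subspaces.** Each tree draws `ceiling(sqrt(g))` genes once
  and only splits on those, rather than re-drawing candidates at every node.

The second point drives the forest-size default. With per-tree subspaces a
gene is evaluated by about `n_trees * sqrt(g) / g` trees — at `g = 2000` and
100 trees that is barely two trees per gene, and a tenth of all genes never
enter any subspace, which makes individual importances Monte-Carlo noise.
The default is therefore `n_trees = 500`, keeping the evidence above roughly
ten trees per gene for datasets up to a few thousand (filtered) genes; for
much larger gene counts, scale `n_trees` with `sqrt(g)` or use
`subspace = "all"`-style larger subspaces. Trees are grown to purity with no
depth cap; splits are midpoints between consecutive distinct values, and a
best split must improve weighted Gini by more than `1e-12`, so constant
and duplicate-cell nodes become (possibly impure) leaves.

## Class balancing

Random-forest importance is biased towards classes with many cells: a split
separating a 600-cell cluster earns more impurity decrease than one
separating a 40-cell cluster, so markers of rare populations are
under-ranked exactly when they are most interesting. Balancing addresses
this around a *central* reference cluster — the one sized closest to the
even share `c / n` (ties go to the smaller cluster, then the lower label):

* **Rare clusters** (below the central size) are raised exactly to it by
  SMOTE: a synthetic cell is `i + u (j - i)` with `u ~ Uniform(0, 1)`, `i`
  cycling through the cluster and `j` drawn from `i`'s `smote_k = 5`
  within-cluster nearest neighbours in gene space. Synthetic cells are
  convex combinations of two real same-cluster cells, so they never leave
  the cluster's componentwise envelope.
* **Major clusters** (above) keep their `U = 80%` of cells closest to the
  cluster centroid, shedding the periphery where mislabelled cells
  concentrate.
* Non-central clusters exactly at the central size are left untouched
  (role `"balanced"` in the plan).

Two consequences of the central-cluster rule are worth knowing. First, with
exactly two clusters the rule is always a tie (`|T_1 - c/2| = |T_2 - c/2|`),
the tie-break makes the *smaller* cluster central, and only undersampling
ever happens — oversampling requires at least three clusters. Second,
undersampling retains `floor(U * T)` cells of each major cluster, which can
remain above the central size; balancing narrows, but does not equalize,
the size distribution.

The oversampling amount is chosen so a rare cluster lands exactly on the
central size (`T_central - T_rare` synthetic cells). A literal reading of a
per-cell rate `R = T_central / T_rare` applied to every rare cell would
overshoot the central size, which cannot be intended; the implemented count
is the one that makes the sampling rate come out at `R`. Similarly, the
interpolation uses the signed difference `j - i`; an absolute difference
would push synthetic cells off the segment between the parents whenever a
component decreases, violating SMOTE's geometric definition.

Balancing operates in the log-normalized gene space, and the SMOTE
neighbour search does too — distances are taken between full expression
profiles within the cluster, not in a reduced embedding.

## Selection and redundancy pruning

Importance distributions are heavy-tailed: most genes hover near the mean
and discriminative genes are extreme outliers. The mu + 3 sigma rule (population
standard deviation) adapts to that shape without needing a preset gene
count; when no gene clears it — essentially only when all genes are
comparably informative — the single top gene is returned with a warning.

Pruning then walks the importance-ordered list. At each surviving anchor,
`L` is the number of candidates after it still in play and the threshold is
`h' = v + v'/(L + 1)` (defaults `v = 0.8`, `v' = 0.1`): with many candidates
left the threshold sits near `v`; for the last few, high-importance genes it
is stricter to beat (up to `v + v'/2`), so late-stage removals require
near-duplication. Removal uses the *signed* Pearson correlation as the rule
is written — strongly anti-correlated genes carry complementary information
and are kept. Correlations are computed on the log-normalized matrix over
all cells (the selection should describe the dataset, not the balanced
training set). A zero-variance gene has no defined correlation; it is
treated as correlating 0 with everything (warned about, never removed as
redundant).

## Numerical and tie-breaking choices

* k-NN ties at the k-th distance, equal-gain splits, equal-importance genes
  and equal central-cluster distances all break deterministically (lowest
  index / first candidate), so every stage is bit-reproducible given a seed.
* Split thresholds are midpoints of consecutive distinct values, clamped
  back to the lower value when rounding would land the midpoint on the
  upper one — otherwise a node could recurse on itself for adjacent
  floating-point values.
* PCA is computed from the eigendecomposition of the cell-by-cell Gram
  matrix (cheap when genes outnumber cells); components are capped at
  `min(n_pcs, cells - 1, genes)`.
* The spectral step row-normalizes the eigenvector embedding and
  discretizes with k-means (10 restarts, seeded); cluster 1 is relabelled
  to be the largest. With `n_clusters = "auto"`, `n` maximizes the eigengap
  of the normalized Laplacian over candidates 2..15.
* Cells with zero depth are removed (with a warning) before size factors;
  size factors scale to the median depth, so the median factor is 1.
* Shannon entropy is computed in nats; balance entropy `BE = 1 - H/log(n)`
  is invariant to that base choice and defined as 0 for a single class.

## The synthetic generator

`generate_synthetic()` draws negative-binomial counts
(`variance = mu + dispersion * mu^2`, default dispersion 0.3 — moderate
scRNA-seq overdispersion) with baseline mean 10. Marker genes are assigned
clusters round-robin and shifted by `2^log_fold_change` in their cluster;
duplicate pairs append exact copies of markers, giving perfectly correlated
groups for pruning tests; cluster sizes follow largest-remainder rounding
of the requested proportions, so stated proportions are hit exactly.

The generator emulates the features the method depends on — overdispersed
counts, cluster-specific mean shifts, size imbalance, redundancy — and
deliberately not others: no batch effects, no dropout beyond
negative-binomial zeros, no trajectory structure, and marker effects are
single-gene mean shifts rather than correlated programs. Passing tests on
this generator therefore demonstrate the mechanics of the method, not
performance on any real tissue.

The test suite exercises the pipeline at up to 1000 cells x 2000 genes with
a 5% rare cluster (ten seeds), and the balancing ablation at 800 cells x
500 genes on a 75/20/5 split (balance entropy 0.37). The ablation fixture
uses three clusters and clearly clusterable markers on purpose: with two
clusters oversampling can never trigger (see above), and when markers are
too weak for the label-prediction stage to isolate the rare cluster, the
ablation would measure label noise rather than the balancing effect.

## Limitations

* Selection quality is bounded by the predicted labels; if spectral
  clustering cannot see a population (e.g. a very small cluster with weak
  markers), balancing cannot rescue its markers.
* The number of clusters `n` is an input; the eigengap fallback works for
  well-separated data but is not a substitute for judgement on real data.
* Importance is Gini-based and shared among correlated genes; the pruning
  step removes redundancy afterwards but the importance values themselves
  remain diluted within correlated groups.
* All-cell (no-bootstrap) trees mean there is no out-of-bag machinery; all
  stability comes from subspace randomization.

## A minimal run

```{r example, eval = FALSE}
sim <- generate_synthetic(synthetic_spec(
  n_cells = 300, n_genes = 400, n_clusters = 3,
  cluster_props = c(0.5, 0.3, 0.2), n_informative = 15, seed = 7))
res <- run_pipeline(sim$matrix, n_clusters = 3, seed = 7)
res$selection$genes
evaluate_features(res$lognorm, res$selection$genes, sim$labels)
```
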