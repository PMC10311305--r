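# scGeneForest

Label-guided random-forest feature selection for single-cell RNA-seq
clustering.

Clustering cells works best on a compact set of genes that actually
discriminate cell types. scGeneForest selects that set by asking a
classifier: it predicts provisional cell labels with a spectral clustering
flow, rebalances skewed cluster sizes, scores every gene by how much a
forest of decision trees relies on it to reproduce the labels, and returns
the outlying, non-redundant genes. It is aimed at anyone building a
scRNA-seq clustering pipeline who wants a selection driven by cell-type
discrimination rather than raw variance.

## Method

Given a genes × cells expression matrix **X** (raw counts):

1. **Preprocess.** Remove genes detected in < 3 cells; divide each cell by
   its size factor (depth / median depth); transform `X' = log2(X + 1)`.
2. **Predict labels.** PCA (top 50 PCs) → Euclidean 15-nearest-neighbour
   cell graph → spectral partition into *n* clusters.
3. **Balance.** With reference size *h = c/n*, the cluster sized closest to
   *h* is *central*; smaller (rare) clusters are raised to the central size
   by SMOTE interpolation `i' = i + u (j − i)`, `u ~ U(0,1)`, between a cell
   and one of its 5 within-cluster nearest neighbours; larger (major)
   clusters keep the 80% of cells closest to their centroid.
4. **Score.** Decision trees grown on *all* cells (no bootstrap), each on a
   random `⌈√g⌉`-gene subspace, to purity. At a node with `w` cells and
   Gini impurity `I = 1 − Σ_C p_C²`, a split earns
   `N = w·I − w_l·I_l − w_r·I_r`; a gene's tree importance is its share of
   the tree's total `N`, and the forest importance `f_i` is the average
   over trees (500 by default).
5. **Select.** Keep genes with `f_i ≥ μ + 3σ`, order by importance, then
   scan: a later gene is removed when its Pearson correlation with a
   surviving earlier gene exceeds `h' = v + v'/(L+1)` (defaults `v = 0.8`,
   `v' = 0.1`, `L` = genes remaining after the anchor).

Evaluation helpers implement balance entropy `BE = 1 − H/log n` and k-NN
type consistency `F'_k = Σ_i Σ_{j∈kNN(i)} 1[type_i = type_j] / (c·k)`, and
delegate ARI / NMI / silhouette to mclust, igraph and cluster.

## Worked example

```r
library(scGeneForest)

sim <- generate_synthetic(synthetic_spec(
  n_cells = 300, n_genes = 400, n_clusters = 3,
  cluster_props = c(0.5, 0.3, 0.2), n_informative = 15, seed = 7))
res <- run_pipeline(sim$matrix, n_clusters = 3, seed = 7)
res
#> <pipeline_result> 3 clusters (sizes: 150, 87, 63), 14 genes selected (0 pruned as redundant)

as.character(res$selection$genes)
#>  [1] "marker_010" "marker_002" "marker_009" "marker_006" "marker_013"
#>  [6] "marker_005" "marker_004" "marker_014" "marker_001" "marker_015"
#> [11] "marker_007" "marker_008" "marker_012" "marker_011"

evaluate_features(res$lognorm, res$selection$genes, sim$labels,
                  labels = res$labeling$labels)
#>             statistic  value
#> 1     balance_entropy 0.0628
#> 2  knn_consistency_k1 0.9900
#> 3  knn_consistency_k3 0.9944
#> 4  knn_consistency_k5 0.9967
#> 5 knn_consistency_k10 0.9957
#> 6 knn_consistency_k15 0.9931
#> 7     mean_silhouette 0.3418
#> 8                 ari 0.9426
#> 9                 nmi 0.9011
```

The pipeline recovered 14 of the 15 planted marker genes and nothing else
(recall 0.93); in the selected-gene space ~99% of each cell's nearest
neighbours share its true type, and the predicted partition agrees with
the ground truth at ARI 0.94.

A thin command-line wrapper ships at `inst/cli/scgeneforest`
(`run`, `evaluate` and `simulate` subcommands), mirroring
`run_pipeline_files()`, `evaluate_features()` and `generate_synthetic()`.

## Documentation

The methods vignette (`vignettes/gene-selection-methods.Rmd`) documents the
model, every tunable parameter with its default and rationale, numerical
and tie-breaking choices, what the synthetic generator does and does not
emulate, and known limitations.
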