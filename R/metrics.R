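#' k-nearest-neighbour type consistency
#'
#' The fraction of each cell's `k` nearest Euclidean neighbours (self
#' excluded, ties at the k-th distance broken by cell index) that share its
#' type, averaged over all cells:
#' `F'_k = sum_i sum_{j in kNN(i)} 1[type_i = type_j] / (c * k)`.
#' 1 means every neighbourhood is type-pure; 0 means no neighbour ever
#' matches.
#'
#' @param coords cells x d numeric matrix (e.g. selected-gene expression or
#'   an embedding).
#' @param types per-cell type labels (any atomic vector).
#' @param k neighbour count, `1 <= k < cells`.
#' @return Consistency in `[0, 1]`.
#' @export
knn_consistency <- function(coords, types, k) {
  coords <- as.matrix(coords)
  cc <- nrow(coords)
  if (length(types) != cc) stop("types must have one entry per cell")
  if (k < 1L || k >= cc) stop("need 1 <= k < number of cells")
  d <- as.matrix(dist(coords))
  diag(d) <- Inf
  hits <- 0L
  for (i in seq_len(cc)) {
    nbr <- head(order(d[i, ]), k)
    hits <- hits + sum(types[nbr] == types[i])
  }
  hits / (cc * k)
}

#' Shannon entropy of a class-size distribution
#'
#' `H = -sum (T_i / c) * ln(T_i / c)` in nats; `ln(n)` for `n` balanced
#' classes, 0 for a single class.
#'
#' @param sizes positive class sizes.
#' @return Entropy in nats.
#' @export
shannon_entropy <- function(sizes) {
  if (any(sizes <= 0)) stop("class sizes must be positive")
  p <- sizes / sum(sizes)
  -sum(p * log(p))
}

#' Balance entropy of a class-size distribution
#'
#' `BE = 1 - H / ln(n)`: 0 for perfectly balanced classes, approaching 1
#' under extreme imbalance. Invariant to the logarithm base (the ratio
#' cancels). Defined as 0 for a single class.
#'
#' @param sizes positive class sizes.
#' @return Balance entropy in `[0, 1]`.
#' @export
balance_entropy <- function(sizes) {
  n <- length(sizes)
  if (n <= 1L) return(0)
  1 - shannon_entropy(sizes) / log(n)
}

#' Partition agreement: adjusted Rand index and normalized mutual information
#'
#' Standard measures, delegated to \pkg{mclust} (ARI) and \pkg{igraph}
#' (NMI).
#'
#' @param labels,truth two partitions of the same cells.
#' @return Named list with `ari` and `nmi`.
#' @export
clustering_agreement <- function(labels, truth) {
  if (length(labels) != length(truth))
    stop("partitions must cover the same cells")
  list(ari = mclust::adjustedRandIndex(labels, truth),
       nmi = igraph::compare(as.integer(factor(labels)),
                             as.integer(factor(truth)), method = "nmi"))
}

#' Evaluate a gene selection against known cell types
#'
#' Restricts the matrix to the selected genes and reports the balance
#' entropy of the type distribution, k-NN consistency for several `k`, mean
#' silhouette width, and (when a second partition is given) ARI/NMI.
#'
#' @param m lognorm-layer [expr_matrix()].
#' @param genes selected gene ids.
#' @param types per-cell type labels.
#' @param k neighbour counts for the consistency curve
#'   (default `c(1, 3, 5, 10, 15)`, trimmed to `< cells`).
#' @param labels optional predicted partition to compare with `types`.
#' @return A data frame with one row per statistic (`statistic`, `value`).
#' @export
evaluate_features <- function(m, genes, types, k = c(1, 3, 5, 10, 15),
                              labels = NULL) {
  stop_if_not_layer(m, "lognorm")
  coords <- t(m$values[genes, , drop = FALSE])
  k <- k[k < nrow(coords)]
  out <- data.frame(statistic = "balance_entropy",
                    value = balance_entropy(as.vector(table(types))))
  for (kk in k)
    out <- rbind(out, data.frame(statistic = sprintf("knn_consistency_k%d", kk),
                                 value = knn_consistency(coords, types, kk)))
  if (requireNamespace("cluster", quietly = TRUE) &&
      length(unique(types)) > 1L) {
    sil <- cluster::silhouette(as.integer(factor(types)), dist(coords))
    out <- rbind(out, data.frame(statistic = "mean_silhouette",
                                 value = mean(sil[, "sil_width"])))
  }
  if (!is.null(labels)) {
    agr <- clustering_agreement(labels, types)
    out <- rbind(out,
                 data.frame(statistic = c("ari", "nmi"),
                            value = c(agr$ari, agr$nmi)))
  }
  out
}
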