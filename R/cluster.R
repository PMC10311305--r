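#' PCA embedding of cells
#'
#' Projects cells of a log-normalized matrix onto the top principal
#' components. Genes are mean-centered; the number of components is capped
#' at `min(n_components, cells - 1, genes)`. Computed from the eigen
#' decomposition of the cell-by-cell Gram matrix, which is cheap when genes
#' outnumber cells (the usual scRNA-seq regime).
#'
#' @param m lognorm-layer [expr_matrix()].
#' @param n_components requested number of components (default 50).
#' @return An object of class `embedding`: list with `coords`
#'   (cells x p scores) and `explained_variance` (non-increasing, length p).
#' @export
pca_embed <- function(m, n_components = 50) {
  stop_if_not_layer(m, "lognorm")
  cc <- n_cells(m)
  if (cc < 2L) stop("PCA needs at least 2 cells")
  p <- min(n_components, cc - 1L, n_genes(m))
  x <- t(m$values)                      # cells x genes
  xc <- sweep(x, 2L, colMeans(x), "-")
  K <- tcrossprod(xc)                   # cells x cells Gram matrix
  eig <- eigen(K, symmetric = TRUE)
  lam <- pmax(eig$values, 0)
  d <- sqrt(lam[seq_len(p)])
  coords <- eig$vectors[, seq_len(p), drop = FALSE] %*% diag(d, p)
  rownames(coords) <- m$cell_ids
  structure(list(coords = coords,
                 explained_variance = lam[seq_len(p)] / (cc - 1)),
            class = "embedding")
}

#' Euclidean k-nearest-neighbour cell graph
#'
#' Connects every cell to its `k` nearest Euclidean neighbours (self
#' excluded, distance ties broken by cell index) and symmetrizes the
#' adjacency by union, with binary edge weights.
#'
#' @param e an `embedding` from [pca_embed()] or a numeric cells x d matrix.
#' @param k neighbour count (default 15); must be smaller than the number
#'   of cells.
#' @return Object of class `knn_graph`: list with sparse symmetric
#'   `adjacency` (zero diagonal) and `k`.
#' @export
build_knn_graph <- function(e, k = 15) {
  coords <- if (inherits(e, "embedding")) e$coords else as.matrix(e)
  cc <- nrow(coords)
  if (cc <= k)
    stop("need more cells (", cc, ") than neighbours k = ", k,
         "; choose a smaller k")
  d <- as.matrix(dist(coords))
  diag(d) <- Inf
  nbr <- apply(d, 1L, function(row) head(order(row), k))  # k x c, stable ties
  i <- rep(seq_len(cc), each = k)
  A <- Matrix::sparseMatrix(i = i, j = as.vector(nbr), x = 1,
                            dims = c(cc, cc))
  A <- ((A + Matrix::t(A)) > 0) * 1
  Matrix::diag(A) <- 0
  structure(list(adjacency = A, k = k), class = "knn_graph")
}

#' Cluster labelling container
#'
#' @param labels integer vector of cluster assignments in `1..n`.
#' @param n number of clusters (default `max(labels)`).
#' @return Object of class `cluster_labeling`: `labels`, `n`, `sizes`
#'   (cluster sizes, length `n`) and `h = cells / n`, the reference size
#'   used to pick the central cluster during balancing.
#' @export
cluster_labeling <- function(labels, n = max(labels)) {
  labels <- as.integer(labels)
  if (any(labels < 1L) || any(labels > n))
    stop("labels must lie in 1..n")
  structure(list(labels = labels, n = as.integer(n),
                 sizes = tabulate(labels, n),
                 h = length(labels) / n),
            class = "cluster_labeling")
}

#' @export
print.cluster_labeling <- function(x, ...) {
  cat(sprintf("<cluster_labeling> %d cells, %d clusters (sizes: %s), h = %.2f\n",
              length(x$labels), x$n, paste(x$sizes, collapse = ", "), x$h))
  invisible(x)
}

normalized_laplacian <- function(A) {
  A <- as.matrix(A)
  deg <- rowSums(A)
  inv_sqrt <- ifelse(deg > 0, 1 / sqrt(deg), 0)
  L <- -A * tcrossprod(inv_sqrt)
  diag(L) <- ifelse(deg > 0, 1, 0)
  L
}

#' Spectral partitioning of a cell graph
#'
#' Embeds cells with the eigenvectors of the `n` smallest eigenvalues of
#' the symmetric normalized Laplacian, row-normalizes, and discretizes with
#' k-means (10 restarts, seeded). Labels are relabelled so cluster 1 is the
#' largest (ties towards the lowest original label).
#'
#' @param gph a `knn_graph`.
#' @param n number of clusters.
#' @param seed integer RNG seed for the k-means step.
#' @return A [cluster_labeling()].
#' @export
spectral_partition <- function(gph, n, seed = 1) {
  A <- gph$adjacency
  cc <- nrow(A)
  if (n > cc) stop("cannot form ", n, " clusters from ", cc, " cells")
  if (n < 1L) stop("n must be at least 1")
  if (n == 1L) return(cluster_labeling(rep(1L, cc), 1L))
  L <- normalized_laplacian(A)
  eig <- eigen(L, symmetric = TRUE)
  if (sum(eig$values < 1e-10) > n)
    warning("graph has more connected components than requested clusters")
  U <- eig$vectors[, seq(cc, cc - n + 1L), drop = FALSE]  # n smallest
  rn <- sqrt(rowSums(U^2))
  U <- U / ifelse(rn > 0, rn, 1)
  km <- withr::with_seed(as.integer(seed),
                         stats::kmeans(U, centers = n, nstart = 10,
                                       iter.max = 100))
  relabel_largest_first(km$cluster, n)
}

relabel_largest_first <- function(labels, n) {
  sizes <- tabulate(labels, n)
  ord <- order(-sizes, seq_len(n))        # largest first, ties by old label
  map <- integer(n)
  map[ord] <- seq_len(n)
  cluster_labeling(map[labels], n)
}

eigengap_n_clusters <- function(L, n_max = 15) {
  ev <- sort(eigen(L, symmetric = TRUE, only.values = TRUE)$values)
  hi <- min(n_max, length(ev) - 1L)
  if (hi < 2L) return(1L)
  gaps <- ev[seq(3L, hi + 1L)] - ev[seq(2L, hi)]  # gap after candidate n = 2..hi
  which.max(gaps) + 1L
}

#' Predict cell labels by the spectral clustering flow
#'
#' Composition PCA -> k-NN graph -> spectral partition. With
#' `n_clusters = "auto"` the cluster number is chosen by the largest
#' eigengap of the normalized Laplacian among candidates 2..15.
#'
#' @param m lognorm-layer [expr_matrix()].
#' @param n_clusters integer, or `"auto"` for the eigengap heuristic.
#' @param seed integer RNG seed.
#' @param n_pcs number of principal components (default 50).
#' @param knn_k neighbour count for the cell graph (default 15).
#' @return A [cluster_labeling()].
#' @export
predict_labels <- function(m, n_clusters = "auto", seed = 1,
                           n_pcs = 50, knn_k = 15) {
  e <- pca_embed(m, n_components = n_pcs)
  gph <- build_knn_graph(e, k = knn_k)
  if (identical(n_clusters, "auto")) {
    L <- normalized_laplacian(gph$adjacency)
    n_clusters <- eigengap_n_clusters(L)
  }
  spectral_partition(gph, as.integer(n_clusters), seed = seed)
}
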