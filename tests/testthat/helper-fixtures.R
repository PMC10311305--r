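# Shared fixture builders. All randomness is locally seeded so individual
# test files stay order-independent.

# Quick lognorm-layer matrix from arbitrary non-negative values.
make_lognorm <- function(values, gene_ids = NULL, cell_ids = NULL) {
  values <- as.matrix(values)
  if (is.null(gene_ids)) gene_ids <- sprintf("g%03d", seq_len(nrow(values)))
  if (is.null(cell_ids)) cell_ids <- sprintf("c%03d", seq_len(ncol(values)))
  expr_matrix(values, gene_ids = gene_ids, cell_ids = cell_ids,
              layer = "lognorm")
}

# Well-separated Gaussian blobs in gene space (lognorm layer), for the
# clustering-flow tests: returns list(matrix, labels).
make_blobs <- function(sizes, n_genes = 20, sep = 8, sd = 0.5, seed = 1) {
  withr::with_seed(seed, {
    n <- sum(sizes)
    k <- length(sizes)
    centers <- matrix(stats::runif(k * n_genes, 0, 1), k, n_genes)
    for (j in seq_len(k)) centers[j, ] <- centers[j, ] + (j - 1) * sep
    labels <- rep(seq_len(k), sizes)
    vals <- t(centers[labels, ] + matrix(stats::rnorm(n * n_genes, sd = sd),
                                         n, n_genes))
    vals <- vals - min(vals)            # keep non-negative for the container
    list(matrix = make_lognorm(vals), labels = labels)
  })
}

# A cluster_labeling with prescribed sizes (labels in block order).
make_labeling <- function(sizes) {
  cluster_labeling(rep(seq_along(sizes), sizes), length(sizes))
}

# Independent brute-force k-NN sets (exhaustive pairwise distances, ties by
# index), used as the oracle for graph construction and Eq-5 style loops.
brute_knn <- function(coords, k) {
  n <- nrow(coords)
  lapply(seq_len(n), function(i) {
    d2 <- vapply(seq_len(n), function(j)
      sqrt(sum((coords[i, ] - coords[j, ])^2)), 0)
    d2[i] <- Inf
    order(d2, seq_len(n))[seq_len(k)]             # ties by index
  })
}
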