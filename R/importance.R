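#' Gini impurity of a class-count vector
#'
#' `1 - sum((count_C / w)^2)` over classes, with `w` the total count:
#' 0 for a pure node, approaching `1 - 1/n` for `n` evenly mixed classes.
#'
#' @param class_counts non-negative counts, at least one positive.
#' @return Impurity in `[0, 1)`.
#' @export
gini_impurity <- function(class_counts) {
  if (any(class_counts < 0)) stop("class counts must be non-negative")
  w <- sum(class_counts)
  if (w <= 0) stop("class counts sum to zero")
  1 - sum((class_counts / w)^2)
}

#' Importance of one binary split node
#'
#' The absolute weighted impurity decrease
#' `N = w * I - w_left * I_left - w_right * I_right`, with `w` the number
#' of cells reaching each node and `I` its Gini impurity. Non-negative for
#' any genuine split.
#'
#' @param node a list with `class_counts` and children `left`, `right`,
#'   each a list with its own `class_counts` (as produced by
#'   [tree_nodes_as_list()] or built by hand).
#' @return The impurity decrease (cell-count weighted, not normalized).
#' @export
node_importance <- function(node) {
  if (is.null(node$left) || is.null(node$right))
    stop("node_importance is defined for internal nodes only")
  w <- sum(node$class_counts)
  wl <- sum(node$left$class_counts)
  wr <- sum(node$right$class_counts)
  w * gini_impurity(node$class_counts) -
    wl * gini_impurity(node$left$class_counts) -
    wr * gini_impurity(node$right$class_counts)
}

#' Per-gene importance of one decision tree
#'
#' For every internal node the impurity decrease is computed and summed by
#' split gene, then normalized by the total decrease over all nodes, so a
#' tree's importances sum to 1 whenever it contains at least one split.
#' Genes outside the tree's subspace, or never split on, score 0.
#'
#' @param tree a `decision_tree` (see [fit_forest_importance()]): list with
#'   a `nodes` data frame (`gene`, `threshold`, `w`, `left`, `right`) and a
#'   `class_counts` matrix (nodes x classes).
#' @param g total number of genes in the dataset.
#' @return Numeric vector of length `g` summing to 1 (or all zero, with a
#'   warning, if no split reduced impurity).
#' @export
tree_importance <- function(tree, g) {
  nd <- tree$nodes
  cc <- tree$class_counts
  f <- numeric(g)
  internal <- which(!is.na(nd$left))
  if (length(internal) == 0L) {
    warning("tree has no split; importance is identically zero")
    return(f)
  }
  I <- 1 - rowSums((cc / nd$w)^2)
  N <- nd$w[internal] * I[internal] -
    nd$w[nd$left[internal]] * I[nd$left[internal]] -
    nd$w[nd$right[internal]] * I[nd$right[internal]]
  tot <- sum(N)
  if (tot <= 0) {
    warning("no impurity reduction anywhere in the tree; importance is zero")
    return(f)
  }
  s <- rowsum(N, nd$gene[internal])
  f[as.integer(rownames(s))] <- s[, 1L] / tot
  f
}

#' Flatten an exported node table into nested split nodes
#'
#' Convenience for inspecting single nodes with [node_importance()].
#'
#' @param tree a `decision_tree`.
#' @param id node row index (default 1, the root).
#' @return Nested list with `gene`, `threshold`, `w`, `class_counts` and
#'   recursively built `left`/`right` children (absent for leaves).
#' @export
tree_nodes_as_list <- function(tree, id = 1L) {
  nd <- tree$nodes
  out <- list(gene = nd$gene[id], threshold = nd$threshold[id],
              w = nd$w[id], class_counts = tree$class_counts[id, ])
  if (!is.na(nd$left[id])) {
    out$left <- tree_nodes_as_list(tree, nd$left[id])
    out$right <- tree_nodes_as_list(tree, nd$right[id])
  }
  out
}

subspace_size <- function(subspace, g) {
  if (identical(subspace, "sqrt")) return(as.integer(ceiling(sqrt(g))))
  if (identical(subspace, "all")) return(as.integer(g))
  s <- as.integer(subspace)
  if (is.na(s) || s < 1L) stop("subspace must be 'sqrt', 'all' or a positive integer")
  min(s, as.integer(g))
}

#' Forest-averaged Gini importance
#'
#' Grows `n_trees` decision trees, each trained on *all* cells of the
#' balanced dataset (no bootstrap, so every tree sees the same labels) but
#' restricted to an independently drawn random gene subspace. Trees are
#' grown by best-Gini binary splits to purity. The forest importance of a
#' gene is the mean of its per-tree normalized importances, a tree in whose
#' subspace the gene does not appear contributing 0.
#'
#' @param b a [balance()]d dataset (or any list with genes x cells `values`,
#'   `labels`, `gene_ids`).
#' @param n_trees number of trees (default 500). Because every tree sees
#'   only a `ceiling(sqrt(g))`-gene subspace, a gene is scored by roughly
#'   `n_trees * sqrt(g) / g` trees; the default keeps that evidence above
#'   ~10 trees per gene for datasets of a few thousand genes.
#' @param subspace `"sqrt"` (default, `ceiling(sqrt(g))` genes per tree),
#'   `"all"`, or an integer subspace size.
#' @param seed integer RNG seed; results are bit-reproducible.
#' @param keep_trees also return each tree's exported node table (for
#'   audits; memory-heavy on large data).
#' @return Object of class `importance_vector`: `f` (per-gene importance),
#'   `gene_ids`, `mu` (mean of `f`), `sigma` (population standard
#'   deviation), `n_trees`, and `trees` when requested.
#' @export
fit_forest_importance <- function(b, n_trees = 500, subspace = "sqrt",
                                  seed = 1, keep_trees = FALSE) {
  X <- t(b$values)                               # cells x genes
  y <- as.integer(factor(b$labels)) - 1L
  K <- max(y) + 1L
  if (K < 2L)
    stop("need at least 2 clusters to measure discriminative importance")
  g <- ncol(X)
  m_sub <- subspace_size(subspace, g)
  fsum <- numeric(g)
  trees <- if (keep_trees) vector("list", n_trees) else NULL
  withr::with_seed(as.integer(seed), {
    for (t in seq_len(n_trees)) {
      feats <- sort(sample.int(g, m_sub))
      raw <- build_tree_cpp(X[, feats, drop = FALSE], y, K)
      tree <- structure(list(
        nodes = data.frame(gene = feats[raw$gene],
                           threshold = raw$threshold,
                           w = raw$w, left = raw$left, right = raw$right),
        class_counts = raw$class_counts,
        gene_subspace = feats), class = "decision_tree")
      fsum <- fsum + tree_importance(tree, g)
      if (keep_trees) trees[[t]] <- tree
    }
  })
  f <- fsum / n_trees
  mu <- mean(f)
  structure(list(f = f, gene_ids = b$gene_ids, mu = mu,
                 sigma = sqrt(mean((f - mu)^2)),
                 n_trees = as.integer(n_trees), trees = trees),
            class = "importance_vector")
}

#' @export
print.importance_vector <- function(x, ...) {
  cat(sprintf("<importance_vector> %d genes, %d trees; mu = %.3g, sigma = %.3g\n",
              length(x$f), x$n_trees, x$mu, x$sigma))
  invisible(x)
}

#' Write a per-gene importance table
#'
#' @param imp an `importance_vector`.
#' @param path output TSV path.
#' @export
write_importance <- function(imp, path) {
  data.table::fwrite(data.table::data.table(gene_id = imp$gene_ids,
                                            importance = imp$f),
                     path, sep = "\t")
  invisible(path)
}
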