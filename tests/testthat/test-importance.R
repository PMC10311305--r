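# Independent oracle: recompute per-tree Gini importance by recursive
# traversal of the exported node table, using nothing from the package's
# importance code path.
oracle_tree_importance <- function(tree, g) {
  nd <- tree$nodes
  cc <- tree$class_counts
  gini <- function(counts) {
    p <- counts / sum(counts)
    1 - sum(p * p)
  }
  contrib <- numeric(g)
  total <- 0
  walk <- function(id) {
    if (is.na(nd$left[id])) return(invisible(NULL))
    n_imp <- nd$w[id] * gini(cc[id, ]) -
      nd$w[nd$left[id]] * gini(cc[nd$left[id], ]) -
      nd$w[nd$right[id]] * gini(cc[nd$right[id], ])
    contrib[nd$gene[id]] <<- contrib[nd$gene[id]] + n_imp
    total <<- total + n_imp
    walk(nd$left[id])
    walk(nd$right[id])
  }
  walk(1L)
  if (total > 0) contrib / total else contrib
}

random_balanced <- function(n_genes, n_cells, n_clusters, seed) {
  withr::with_seed(seed, {
    labels <- sample(rep(seq_len(n_clusters), length.out = n_cells))
    vals <- matrix(runif(n_genes * n_cells, 0, 4), n_genes, n_cells)
    vals[1, ] <- vals[1, ] + labels          # one mildly informative gene
    list(values = vals, labels = labels,
         gene_ids = sprintf("g%02d", seq_len(n_genes)))
  })
}

test_that("gini impurity follows 1 - sum(p^2)", {
  expect_equal(gini_impurity(c(10, 0)), 0)
  expect_equal(gini_impurity(c(5, 5)), 0.5)
  expect_equal(gini_impurity(c(3, 3, 3)), 2 / 3)
  expect_error(gini_impurity(c(0, 0)), "sum to zero")
  expect_error(gini_impurity(c(-1, 2)), "non-negative")
})

test_that("node importance is the weighted impurity decrease", {
  node <- list(class_counts = c(5, 5),
               left = list(class_counts = c(5, 0)),
               right = list(class_counts = c(0, 5)))
  expect_equal(node_importance(node), 5)

  useless <- list(class_counts = c(6, 6),
                  left = list(class_counts = c(3, 3)),
                  right = list(class_counts = c(3, 3)))
  expect_equal(node_importance(useless), 0)

  expect_error(node_importance(list(class_counts = c(1, 1))), "internal")
})

test_that("node importance is non-negative on real trees and matches direct recomputation", {
  for (seed in 1:5) {
    d <- random_balanced(4, 25, 2, seed)
    imp <- fit_forest_importance(d, n_trees = 2, subspace = "all",
                                 seed = seed, keep_trees = TRUE)
    for (tree in imp$trees) {
      nd <- tree$nodes
      for (id in which(!is.na(nd$left))) {
        node <- tree_nodes_as_list(tree, id)
        n_direct <- sum(node$class_counts) * gini_impurity(node$class_counts) -
          sum(node$left$class_counts) * gini_impurity(node$left$class_counts) -
          sum(node$right$class_counts) * gini_impurity(node$right$class_counts)
        expect_gte(n_direct, -1e-12)
        expect_equal(node_importance(node), n_direct)
      }
    }
  }
})

test_that("a single-split tree gives one-hot importance", {
  vals <- rbind(rep(1, 10),
                rep(2, 10),
                c(rep(0, 5), rep(9, 5)))       # only gene 3 separates
  d <- list(values = vals, labels = rep(1:2, each = 5),
            gene_ids = c("a", "b", "c"))
  imp <- fit_forest_importance(d, n_trees = 1, subspace = "all", seed = 1,
                               keep_trees = TRUE)
  f <- tree_importance(imp$trees[[1]], 3)
  expect_equal(f, c(0, 0, 1))
})

test_that("per-tree importance is normalized and matches the traversal oracle", {
  for (seed in 1:6) {
    d <- random_balanced(5, 30, 3, seed)
    imp <- fit_forest_importance(d, n_trees = 3, subspace = "all",
                                 seed = seed, keep_trees = TRUE)
    for (tree in imp$trees) {
      f_pkg <- tree_importance(tree, 5)
      expect_equal(sum(f_pkg), 1, tolerance = 1e-12)
      expect_lt(max(abs(f_pkg - oracle_tree_importance(tree, 5))), 1e-10)
    }
  }
})

test_that("forest importance is the mean of per-tree importances", {
  d <- random_balanced(6, 40, 2, 99)
  imp <- fit_forest_importance(d, n_trees = 5, subspace = 3, seed = 99,
                               keep_trees = TRUE)
  per_tree <- vapply(imp$trees, oracle_tree_importance, numeric(6), g = 6)
  expect_lt(max(abs(imp$f - rowMeans(per_tree))), 1e-10)
  expect_equal(imp$mu, mean(imp$f))
  expect_equal(imp$sigma, sqrt(mean((imp$f - mean(imp$f))^2)))
})

test_that("a perfectly separating gene takes all the importance", {
  withr::with_seed(55, {
    g <- 20
    vals <- matrix(runif(g * 30, 1.9, 2.1), g, 30)  # near-constant noise
    vals[7, ] <- c(rep(0, 15), rep(9, 15))
    d <- list(values = vals, labels = rep(1:2, each = 15),
              gene_ids = sprintf("g%02d", 1:g))
    imp <- fit_forest_importance(d, n_trees = 20, subspace = "all", seed = 1)
    expect_gt(imp$f[7], 0.95)
    expect_lt(max(imp$f[-7]), 0.05)
  })
})

test_that("duplicated informative genes share the importance of a single copy", {
  # Subspace sizes are matched so the signal enters a tree with the same
  # probability in both designs: 6 of 9 genes vs (for the duplicated pair)
  # 4 of 10 genes both give inclusion probability 2/3.
  withr::with_seed(56, {
    n <- 60
    labels <- rep(1:2, each = n / 2)
    noise <- matrix(runif(8 * n, 0, 4), 8, n)
    signal <- ifelse(labels == 1, 1, 5) + runif(n, 0, 3)
    single <- rbind(noise, signal)
    d1 <- list(values = single, labels = labels,
               gene_ids = sprintf("g%02d", 1:9))
    imp1 <- fit_forest_importance(d1, n_trees = 200, subspace = 6, seed = 4)

    dup <- rbind(noise, signal, signal)
    d2 <- list(values = dup, labels = labels,
               gene_ids = sprintf("g%02d", 1:10))
    imp2 <- fit_forest_importance(d2, n_trees = 200, subspace = 4, seed = 4)
    expect_gt(imp2$f[10], 0)                      # the second copy does score
    expect_lt(abs((imp2$f[9] + imp2$f[10]) - imp1$f[9]), 0.1)
  })
})

test_that("forest fitting is deterministic given the seed and rejects one cluster", {
  d <- random_balanced(5, 20, 2, 123)
  i1 <- fit_forest_importance(d, n_trees = 10, seed = 5)
  i2 <- fit_forest_importance(d, n_trees = 10, seed = 5)
  expect_identical(i1$f, i2$f)

  d$labels <- rep(1, 20)
  expect_error(fit_forest_importance(d, n_trees = 2, seed = 1),
               "at least 2 clusters")
})
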