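make_importance <- function(f, gene_ids = sprintf("g%04d", seq_along(f))) {
  mu <- mean(f)
  structure(list(f = f, gene_ids = gene_ids, mu = mu,
                 sigma = sqrt(mean((f - mu)^2)), n_trees = 1L),
            class = "importance_vector")
}

test_that("three-sigma cut keeps genes at or above mu + 3 sigma, importance-ordered", {
  f <- c(0.5, rep(0.01, 99))
  mu <- mean(f); sigma <- sqrt(mean((f - mu)^2))
  expect_true(mu + 3 * sigma < 0.5 && mu + 3 * sigma > 0.01)
  sel <- three_sigma_cut(make_importance(f))
  expect_equal(as.character(sel), "g0001")

  # degenerate equality: sigma = 0 and everything passes
  f_eq <- rep(0.2, 10)
  expect_length(three_sigma_cut(make_importance(f_eq)), 10)

  # exhaustive filter oracle on a heavy-tailed decay profile
  decay <- exp(-(1:1000) / 50)
  mu <- mean(decay); sigma <- sqrt(mean((decay - mu)^2))
  oracle <- sprintf("g%04d", which(decay >= mu + 3 * sigma))
  expect_gt(length(oracle), 5)
  sel_decay <- three_sigma_cut(make_importance(decay))
  expect_identical(as.character(sel_decay), oracle)
})

test_that("an empty three-sigma cut falls back to the top gene with a warning", {
  # a linear ramp has mu + 3 sigma above its maximum, so nothing clears it
  f <- seq(1, 0.001, length.out = 100)
  mu <- mean(f); sigma <- sqrt(mean((f - mu)^2))
  stopifnot(all(f < mu + 3 * sigma))
  expect_warning(sel <- three_sigma_cut(make_importance(f)), "top gene")
  expect_equal(as.character(sel), "g0001")
})

test_that("dynamic threshold follows v + v' / (L + 1)", {
  expect_equal(dynamic_threshold(1), 0.85)
  expect_equal(dynamic_threshold(4), 0.82)
  expect_equal(dynamic_threshold(1e9), 0.8, tolerance = 1e-8)
  Ls <- 0:20
  expect_true(all(diff(dynamic_threshold(Ls)) < 0))
  expect_error(dynamic_threshold(-1), "non-negative")
})

test_that("perfectly correlated duplicates lose their lower-importance copy", {
  withr::with_seed(61, {
    base <- runif(40, 0, 5)
    vals <- rbind(base, base, matrix(runif(3 * 40, 0, 5), 3))
    m <- make_lognorm(vals, gene_ids = c("top", "copy", "n1", "n2", "n3"))
    sel <- redundancy_prune(m, c("top", "copy", "n1", "n2", "n3"))
    expect_false("copy" %in% sel$genes)
    expect_true("top" %in% sel$genes)
    expect_equal(sel$removed$gene, "copy")
    expect_equal(sel$removed$removed_by, "top")
    expect_equal(sel$removed$correlation, 1)
  })
})

test_that("near-orthogonal genes survive pruning untouched", {
  withr::with_seed(62, {
    vals <- matrix(runif(6 * 200, 0, 5), 6, 200)
    m <- make_lognorm(vals)
    stopifnot(max(abs(cor(t(vals))[upper.tri(diag(6))])) < 0.3)
    sel <- redundancy_prune(m, m$gene_ids)
    expect_identical(sel$genes, m$gene_ids)
    expect_equal(nrow(sel$removed), 0)
  })
})

# Independent scan oracle: re-simulates the sequential anchor scan from an
# arbitrary correlation matrix, written against the rule itself.
oracle_scan <- function(ids, S, v = 0.8, v_prime = 0.1) {
  alive <- ids
  a <- 1
  while (a < length(alive)) {
    L <- length(alive) - a
    h <- v + v_prime / (L + 1)
    keep <- alive[seq_len(a)]
    for (j in alive[-seq_len(a)])
      if (!(S[alive[a], j] > h)) keep <- c(keep, j)
    alive <- keep
    a <- a + 1
  }
  alive
}

test_that("pruning agrees with a step-by-step scan oracle", {
  # hand-built six-gene structure with strong and borderline correlations
  withr::with_seed(63, {
    n <- 300
    z1 <- rnorm(n); z2 <- rnorm(n)
    g1 <- z1
    g2 <- 0.97 * z1 + sqrt(1 - 0.97^2) * rnorm(n)   # ~0.97 with g1
    g3 <- z2
    g4 <- 0.9 * z2 + sqrt(1 - 0.9^2) * rnorm(n)     # ~0.9 with g3
    g5 <- 0.5 * z1 + 0.5 * z2 + rnorm(n)
    g6 <- rnorm(n)
    vals <- rbind(g1, g2, g3, g4, g5, g6) + 6       # non-negative shift
    ids <- paste0("G", 1:6)
    m <- make_lognorm(vals, gene_ids = ids)
    sel <- redundancy_prune(m, ids)
    S <- cor(t(vals))
    dimnames(S) <- list(ids, ids)
    expect_identical(sel$genes, oracle_scan(ids, S))
    expect_true(all(sel$removed$correlation > sel$removed$threshold))
  })

  # randomized configurations
  for (seed in 1:8) {
    withr::with_seed(100 + seed, {
      n <- 150
      k <- 8
      base <- matrix(rnorm(3 * n), 3, n)
      mix <- matrix(runif(k * 3), k, 3)
      vals <- mix %*% base + 0.4 * matrix(rnorm(k * n), k, n) + 10
      ids <- paste0("G", seq_len(k))
      m <- make_lognorm(vals, gene_ids = ids)
      sel <- redundancy_prune(m, ids)
      S <- cor(t(vals))
      dimnames(S) <- list(ids, ids)
      expect_identical(sel$genes, oracle_scan(ids, S))
    })
  }
})

test_that("zero-variance genes correlate with nothing and are kept", {
  vals <- rbind(a = runif(30), flat = rep(2, 30), b = runif(30))
  m <- make_lognorm(vals, gene_ids = c("a", "flat", "b"))
  expect_warning(sel <- redundancy_prune(m, c("a", "flat", "b")),
                 "zero-variance")
  expect_true("flat" %in% sel$genes)
})

test_that("pruning never removes the highest-importance gene", {
  for (seed in 1:5) {
    withr::with_seed(200 + seed, {
      k <- 10; n <- 80
      base <- rnorm(n)
      vals <- matrix(rep(base, k), k, n, byrow = TRUE) +
        matrix(rnorm(k * n, sd = runif(1, 0.05, 2)), k, n) + 8
      ids <- paste0("G", seq_len(k))
      m <- make_lognorm(vals, gene_ids = ids)
      sel <- redundancy_prune(m, ids)
      expect_equal(sel$genes[1], "G1")
    })
  }
})

test_that("end-to-end selection recovers markers and strips duplicates", {
  sim <- generate_synthetic(synthetic_spec(
    n_cells = 250, n_genes = 300, n_clusters = 3,
    cluster_props = c(0.5, 0.3, 0.2), n_informative = 12,
    n_duplicate_pairs = 4, seed = 71))
  ln <- preprocess(sim$matrix)
  bal <- balance(ln, make_labeling(tabulate(sim$labels)), seed = 71)
  imp <- fit_forest_importance(bal, n_trees = 100, seed = 71)
  sel <- select_features(ln, imp)

  expect_identical(order(attr(sel$genes, "importance"),
                         decreasing = TRUE),
                   seq_along(sel$genes))          # importance-descending
  for (grp in sim$duplicate_groups)
    expect_lte(sum(grp %in% sel$genes), 1)
  recall <- mean(sim$informative_genes %in%
                   c(sel$genes, sel$removed$gene))
  expect_gte(recall, 0.5)
})
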