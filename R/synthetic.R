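#' Specification of a synthetic clustered scRNA-seq dataset
#'
#' Describes negative-binomial count data with known clusters: every gene
#' has baseline mean `base_mean` and dispersion `nb_dispersion`
#' (`variance = mu + nb_dispersion * mu^2`, the usual scRNA-seq
#' overdispersion parameterization); each informative (marker) gene is
#' assigned one cluster round-robin and its mean there is shifted to
#' `base_mean * 2^log_fold_change`; duplicate pairs append two exact copies
#' of an informative gene, giving groups of perfectly correlated genes for
#' redundancy tests.
#'
#' @param n_cells,n_genes,n_clusters dataset dimensions.
#' @param cluster_props cluster proportions summing to 1 (default equal);
#'   sizes are rounded by largest remainder so they sum to `n_cells`.
#' @param n_informative number of marker genes (default 30).
#' @param log_fold_change marker shift in log2 units (default 2, i.e. a
#'   4-fold mean increase in the marked cluster).
#' @param nb_dispersion negative-binomial dispersion (default 0.3,
#'   moderate overdispersion).
#' @param base_mean baseline mean count (default 10).
#' @param n_duplicate_pairs number of duplicate pairs appended (default 0).
#' @param seed integer RNG seed.
#' @return Object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_cells = 1000, n_genes = 2000, n_clusters = 4,
                           cluster_props = rep(1 / n_clusters, n_clusters),
                           n_informative = 30, log_fold_change = 2,
                           nb_dispersion = 0.3, base_mean = 10,
                           n_duplicate_pairs = 0, seed = 1) {
  if (abs(sum(cluster_props) - 1) > 1e-8)
    stop("cluster_props must sum to 1")
  if (length(cluster_props) != n_clusters)
    stop("cluster_props must have one entry per cluster")
  if (n_informative + 2 * n_duplicate_pairs > n_genes)
    stop("n_informative + 2 * n_duplicate_pairs exceeds n_genes")
  if (n_duplicate_pairs > n_informative && n_duplicate_pairs > 0)
    stop("cannot have more duplicate pairs than informative genes")
  if (nb_dispersion <= 0 || base_mean <= 0 || log_fold_change < 0)
    stop("nb_dispersion and base_mean must be positive, log_fold_change non-negative")
  structure(list(n_cells = as.integer(n_cells),
                 n_genes = as.integer(n_genes),
                 n_clusters = as.integer(n_clusters),
                 cluster_props = cluster_props,
                 n_informative = as.integer(n_informative),
                 log_fold_change = log_fold_change,
                 nb_dispersion = nb_dispersion,
                 base_mean = base_mean,
                 n_duplicate_pairs = as.integer(n_duplicate_pairs),
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

largest_remainder_sizes <- function(props, total) {
  raw <- props * total
  sizes <- floor(raw)
  short <- total - sum(sizes)
  if (short > 0) {
    extra <- order(-(raw - sizes), seq_along(props))[seq_len(short)]
    sizes[extra] <- sizes[extra] + 1
  }
  as.integer(sizes)
}

#' Generate a synthetic clustered count matrix
#'
#' Fully reproducible given the spec's seed. Gene layout: informative genes
#' first (`marker_*`), then `2 * n_duplicate_pairs` exact copies of the
#' first `n_duplicate_pairs` markers (`dup_*`), then pure-noise genes.
#'
#' @param spec a [synthetic_spec()].
#' @return List with `matrix` (raw-layer [expr_matrix()]), `labels` (true
#'   cluster per cell, `1..n_clusters`), `informative_genes` (marker ids,
#'   excluding copies), and `duplicate_groups` (list of id vectors, each a
#'   group of identical genes: the source marker and its two copies).
#' @export
generate_synthetic <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  sizes <- largest_remainder_sizes(spec$cluster_props, spec$n_cells)
  labels <- rep(seq_len(spec$n_clusters), sizes)
  size_nb <- 1 / spec$nb_dispersion
  fold <- 2^spec$log_fold_change
  n_dup <- 2L * spec$n_duplicate_pairs
  n_noise <- spec$n_genes - spec$n_informative - n_dup
  withr::with_seed(spec$seed, {
    vals <- matrix(rnbinom(n_noise * spec$n_cells, mu = spec$base_mean,
                           size = size_nb),
                   nrow = n_noise, ncol = spec$n_cells)
    markers <- matrix(0, spec$n_informative, spec$n_cells)
    marker_cluster <- (seq_len(spec$n_informative) - 1L) %%
      spec$n_clusters + 1L
    for (i in seq_len(spec$n_informative)) {
      mu <- ifelse(labels == marker_cluster[i],
                   spec$base_mean * fold, spec$base_mean)
      markers[i, ] <- rnbinom(spec$n_cells, mu = mu, size = size_nb)
    }
    NULL
  })
  marker_ids <- sprintf("marker_%03d", seq_len(spec$n_informative))
  dup_groups <- list()
  dup_rows <- NULL
  dup_ids <- character(0)
  if (spec$n_duplicate_pairs > 0L) {
    src <- seq_len(spec$n_duplicate_pairs)
    dup_rows <- markers[rep(src, each = 2L), , drop = FALSE]
    dup_ids <- sprintf("dup_%03d%s", rep(src, each = 2L),
                       rep(c("a", "b"), spec$n_duplicate_pairs))
    dup_groups <- lapply(src, function(i)
      c(marker_ids[i], sprintf("dup_%03d%s", i, c("a", "b"))))
  }
  noise_ids <- sprintf("noise_%04d", seq_len(n_noise))
  all_vals <- rbind(markers, dup_rows, vals)
  gene_ids <- c(marker_ids, dup_ids, noise_ids)
  m <- expr_matrix(all_vals, gene_ids = gene_ids,
                   cell_ids = sprintf("cell_%04d", seq_len(spec$n_cells)),
                   layer = "raw")
  list(matrix = m, labels = labels, informative_genes = marker_ids,
       duplicate_groups = dup_groups)
}
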