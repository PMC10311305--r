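#' Plan the class-balancing step
#'
#' The cluster whose size is closest to the reference size `h = cells / n`
#' becomes the central cluster (ties towards the smaller cluster, then the
#' lower id). Clusters smaller than the central size are rare and get a
#' SMOTE sampling rate `R = T_central / T_rare`; clusters larger are major
#' and will be undersampled; non-central clusters exactly at the central
#' size are left untouched (role `"balanced"`).
#'
#' @param lab a [cluster_labeling()].
#' @param U fraction of each major cluster retained (default 0.8).
#' @param smote_k SMOTE neighbour count (default 5).
#' @return Object of class `balance_plan`: `central` (cluster id), `role`
#'   (one of central/rare/major/balanced per cluster), `R` (sampling rate,
#'   NA unless rare), `U`, `smote_k`.
#' @export
plan_balance <- function(lab, U = 0.8, smote_k = 5) {
  if (U <= 0 || U > 1) stop("U must be in (0, 1]")
  sizes <- lab$sizes
  ord <- order(abs(sizes - lab$h), sizes, seq_along(sizes))
  central <- ord[1L]
  t_central <- sizes[central]
  role <- ifelse(sizes < t_central, "rare",
                 ifelse(sizes > t_central, "major", "balanced"))
  role[central] <- "central"
  R <- ifelse(role == "rare", t_central / sizes, NA_real_)
  structure(list(central = central, role = role, R = R,
                 U = U, smote_k = as.integer(smote_k)),
            class = "balance_plan")
}

#' @export
print.balance_plan <- function(x, ...) {
  cat(sprintf("<balance_plan> central cluster %d; roles: %s\n",
              x$central, paste(x$role, collapse = ", ")))
  invisible(x)
}

#' SMOTE oversampling of one rare cluster
#'
#' Synthesizes cells by interpolating between a cluster member `i` and one
#' of its `smote_k` nearest within-cluster neighbours `j` (Euclidean
#' distance in gene space): `i + u * (j - i)` with `u ~ Uniform(0, 1)`.
#' Seed cells are cycled so synthesis is spread over the whole cluster, and
#' exactly `round(R * T) - T` cells are produced, lifting the cluster to
#' the central size.
#'
#' @param x genes x cells matrix of one rare cluster (at least 1 cell).
#' @param R sampling rate `T_central / T_rare` (> 1).
#' @param smote_k neighbour count (clipped to cluster size - 1).
#' @param seed integer RNG seed.
#' @return genes x n_synthetic matrix of synthetic cells.
#' @export
smote_oversample <- function(x, R, smote_k = 5, seed = 1) {
  x <- as.matrix(x)
  t_rare <- ncol(x)
  if (t_rare < 1L) stop("empty cluster")
  if (R <= 1) stop("sampling rate R must exceed 1 for a rare cluster")
  n_syn <- as.integer(round(R * t_rare)) - t_rare
  if (n_syn < 1L) return(x[, 0, drop = FALSE])
  if (t_rare == 1L) {
    warning("rare cluster has a single cell; duplicating it (interpolation undefined)")
    return(x[, rep(1L, n_syn), drop = FALSE])
  }
  k <- min(smote_k, t_rare - 1L)
  d <- as.matrix(dist(t(x)))
  diag(d) <- Inf
  nbrs <- apply(d, 1L, function(row) head(order(row), k))
  nbrs <- matrix(nbrs, nrow = k)          # k x t_rare
  withr::with_seed(as.integer(seed), {
    out <- matrix(0, nrow(x), n_syn)
    for (s in seq_len(n_syn)) {
      i <- (s - 1L) %% t_rare + 1L
      j <- nbrs[sample.int(k, 1L), i]
      u <- stats::runif(1L)
      out[, s] <- x[, i] + u * (x[, j] - x[, i])
    }
    out
  })
}

#' Centroid-distance undersampling of one major cluster
#'
#' Ranks cells by Euclidean distance to the cluster centroid (mean vector),
#' ties broken by cell index, and retains the closest
#' `max(1, floor(U * T))` cells, discarding the periphery.
#'
#' @param x genes x cells matrix of one major cluster.
#' @param U retained fraction (default 0.8).
#' @return Increasing integer vector of retained column indices.
#' @export
center_undersample <- function(x, U = 0.8) {
  x <- as.matrix(x)
  tc <- ncol(x)
  if (tc < 1L) stop("empty cluster")
  centroid <- rowMeans(x)
  d <- sqrt(colSums((x - centroid)^2))
  n_keep <- max(1L, floor(U * tc))
  sort(head(order(d), n_keep))            # stable ties by index
}

#' Balance a labelled dataset
#'
#' Applies the balance plan to a log-normalized matrix: the central (and
#' any equally sized) cluster is kept whole, each rare cluster is raised to
#' the central size by [smote_oversample()], and each major cluster is
#' reduced by [center_undersample()]. Output columns are the retained
#' originals in input order followed by synthetic cells grouped by cluster.
#'
#' @param m lognorm-layer [expr_matrix()].
#' @param lab [cluster_labeling()] aligned with the columns of `m`.
#' @param plan a [plan_balance()] result (default derived from `lab`).
#' @param seed integer RNG seed.
#' @param mode `"both"` (default), `"over_only"`, `"under_only"` or
#'   `"none"`, to switch off either half of the strategy.
#' @return Object of class `balanced_dataset`: `values` (genes x cells'),
#'   `labels`, `provenance` (`"original"`/`"synthetic"`), `gene_ids`,
#'   `cell_ids`.
#' @export
balance <- function(m, lab, plan = plan_balance(lab), seed = 1,
                    mode = c("both", "over_only", "under_only", "none")) {
  mode <- match.arg(mode)
  stop_if_not_layer(m, "lognorm")
  if (length(lab$labels) != n_cells(m))
    stop("labels do not align with the columns of m")
  labels <- lab$labels
  keep <- rep(TRUE, length(labels))
  if (mode %in% c("both", "under_only")) {
    for (C in which(plan$role == "major")) {
      cols <- which(labels == C)
      ret <- center_undersample(m$values[, cols, drop = FALSE], U = plan$U)
      keep[cols] <- FALSE
      keep[cols[ret]] <- TRUE
    }
  }
  syn_vals <- list(); syn_lab <- integer(0)
  if (mode %in% c("both", "over_only")) {
    for (C in which(plan$role == "rare")) {
      cols <- which(labels == C)
      s <- smote_oversample(m$values[, cols, drop = FALSE], R = plan$R[C],
                            smote_k = plan$smote_k, seed = seed + C)
      if (ncol(s) > 0L) {
        colnames(s) <- sprintf("synthetic_c%d_%d", C, seq_len(ncol(s)))
        syn_vals[[length(syn_vals) + 1L]] <- s
        syn_lab <- c(syn_lab, rep(C, ncol(s)))
      }
    }
  }
  vals <- m$values[, keep, drop = FALSE]
  out_lab <- labels[keep]
  prov <- rep("original", sum(keep))
  if (length(syn_vals) > 0L) {
    vals <- cbind(vals, do.call(cbind, syn_vals))
    out_lab <- c(out_lab, syn_lab)
    prov <- c(prov, rep("synthetic", length(syn_lab)))
  }
  structure(list(values = vals, labels = out_lab, provenance = prov,
                 gene_ids = m$gene_ids, cell_ids = colnames(vals)),
            class = "balanced_dataset")
}

#' @export
print.balanced_dataset <- function(x, ...) {
  cat(sprintf("<balanced_dataset> %d genes x %d cells (%d synthetic), sizes: %s\n",
              nrow(x$values), ncol(x$values), sum(x$provenance == "synthetic"),
              paste(tabulate(x$labels), collapse = ", ")))
  invisible(x)
}
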