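#' Three-sigma importance cut
#'
#' Keeps genes whose forest importance is at least `mu + 3 * sigma` (mean
#' and population standard deviation of the importance distribution) and
#' orders them by importance, descending, ties broken by gene index. When
#' nothing clears the cut, the single top-importance gene is returned with
#' a warning.
#'
#' @param imp an `importance_vector` from [fit_forest_importance()].
#' @return Character vector of gene ids, importance-descending, with the
#'   importances attached as the `importance` attribute.
#' @export
three_sigma_cut <- function(imp) {
  thr <- imp$mu + 3 * imp$sigma
  sel <- which(imp$f >= thr)
  if (length(sel) == 0L) {
    warning("no gene reaches mu + 3*sigma; falling back to the top gene")
    sel <- which.max(imp$f)
  }
  sel <- sel[order(-imp$f[sel], sel)]
  structure(imp$gene_ids[sel], importance = imp$f[sel])
}

#' Dynamic redundancy threshold
#'
#' `h' = v + v' / (L + 1)`, where `L` is the number of candidate genes
#' after the current anchor that are still in play. Early anchors (large
#' `L`) prune close to the base threshold `v`; late, high-importance-dense
#' stages tolerate more correlation.
#'
#' @param L number of genes not yet analyzed (>= 0).
#' @param v base correlation threshold (default 0.8).
#' @param v_prime importance-protection increment (default 0.1).
#' @return The threshold `h'`.
#' @export
dynamic_threshold <- function(L, v = 0.8, v_prime = 0.1) {
  if (any(L < 0)) stop("L must be non-negative")
  v + v_prime / (L + 1)
}

#' Sequential correlation pruning of an ordered gene list
#'
#' Scans the importance-ordered list: each surviving gene in turn becomes
#' the anchor, the threshold `h'` is recomputed from the number of genes
#' remaining after it, and every later surviving gene whose Pearson
#' correlation with the anchor (across all cells of the log-normalized
#' matrix) exceeds `h'` is removed. Removed genes never become anchors;
#' survivors keep their importance order. The signed correlation is used,
#' so anti-correlated genes are never pruned. Zero-variance genes have all
#' correlations defined as 0 (with a warning) and are never removed as
#' redundant.
#'
#' @param m lognorm-layer [expr_matrix()] covering all candidate genes.
#' @param genes gene ids ordered by importance, descending.
#' @param v,v_prime see [dynamic_threshold()].
#' @return Object of class `gene_selection`: `genes` (survivors, ordered)
#'   and `removed`, a data frame with one row per removal
#'   (`gene`, `removed_by`, `correlation`, `threshold`).
#' @export
redundancy_prune <- function(m, genes, v = 0.8, v_prime = 0.1) {
  stop_if_not_layer(m, "lognorm")
  if (!all(genes %in% m$gene_ids)) stop("unknown gene id in selection")
  ex <- m$values[genes, , drop = FALSE]
  sds <- apply(ex, 1L, stats::sd)
  if (any(sds == 0))
    warning("zero-variance gene(s) in selection; their correlations are set to 0")
  S <- matrix(0, length(genes), length(genes),
              dimnames = list(genes, genes))
  ok <- sds > 0
  if (sum(ok) >= 2L) S[ok, ok] <- stats::cor(t(ex[ok, , drop = FALSE]))
  surviving <- genes
  removed <- list()
  pos <- 1L
  while (pos < length(surviving)) {
    anchor <- surviving[pos]
    L <- length(surviving) - pos
    h <- dynamic_threshold(L, v, v_prime)
    cand <- surviving[(pos + 1L):length(surviving)]
    s_ij <- S[anchor, cand]
    drop <- cand[s_ij > h]
    if (length(drop) > 0L) {
      removed[[length(removed) + 1L]] <-
        data.frame(gene = drop, removed_by = anchor,
                   correlation = unname(s_ij[s_ij > h]), threshold = h)
      surviving <- surviving[!surviving %in% drop]
    }
    pos <- pos + 1L
  }
  removed <- if (length(removed) > 0L) do.call(rbind, removed) else
    data.frame(gene = character(0), removed_by = character(0),
               correlation = numeric(0), threshold = numeric(0))
  structure(list(genes = surviving, removed = removed),
            class = "gene_selection")
}

#' @export
print.gene_selection <- function(x, ...) {
  cat(sprintf("<gene_selection> %d genes kept, %d removed as redundant\n",
              length(x$genes), nrow(x$removed)))
  invisible(x)
}

#' Final feature selection: three-sigma cut then redundancy pruning
#'
#' @param m lognorm-layer [expr_matrix()] (all cells, all filtered genes).
#' @param imp an `importance_vector` aligned with `m`.
#' @param v,v_prime pruning parameters, see [dynamic_threshold()].
#' @return A `gene_selection` whose `genes` carry their importances as the
#'   `importance` attribute and with the full removal audit trail.
#' @export
select_features <- function(m, imp, v = 0.8, v_prime = 0.1) {
  cut <- three_sigma_cut(imp)
  sel <- redundancy_prune(m, as.character(cut), v = v, v_prime = v_prime)
  impmap <- stats::setNames(imp$f, imp$gene_ids)
  attr(sel$genes, "importance") <- unname(impmap[sel$genes])
  sel
}

#' Write the selection audit table
#'
#' One row per candidate gene that passed the three-sigma cut, recording
#' whether it was kept or which anchor removed it and at what correlation
#' and threshold.
#'
#' @param sel a `gene_selection`.
#' @param imp the `importance_vector` the selection came from.
#' @param path output TSV path.
#' @export
write_selection_audit <- function(sel, imp, path) {
  impmap <- stats::setNames(imp$f, imp$gene_ids)
  kept <- data.frame(gene = as.character(sel$genes), status = "kept",
                     removed_by = NA_character_, correlation = NA_real_,
                     threshold = NA_real_)
  rem <- sel$removed
  if (nrow(rem) > 0L)
    rem <- data.frame(gene = rem$gene, status = "removed",
                      removed_by = rem$removed_by,
                      correlation = rem$correlation,
                      threshold = rem$threshold)
  else rem <- kept[0, ]
  out <- rbind(kept, rem)
  out$importance <- unname(impmap[out$gene])
  out <- out[order(-out$importance), c("gene", "importance", "status",
                                       "removed_by", "correlation",
                                       "threshold")]
  data.table::fwrite(out, path, sep = "\t")
  invisible(path)
}
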