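#' Remove genes expressed in too few cells
#'
#' Drops genes detected (value strictly greater than zero) in fewer than
#' `min_cells` cells. Applied to raw counts before normalization; lowly
#' expressed genes carry little information for discriminating cell types
#' and inflate the feature space.
#'
#' @param m raw-layer [expr_matrix()].
#' @param min_cells minimum number of cells a gene must be detected in
#'   (default 3).
#' @return An `expr_matrix` with the surviving genes, order preserved.
#' @export
filter_low_expression <- function(m, min_cells = 3) {
  stop_if_not_layer(m, "raw")
  keep <- rowSums(m$values > 0) >= min_cells
  if (!any(keep))
    stop("no gene is expressed in at least ", min_cells,
         " cells: empty feature space")
  expr_matrix(m$values[keep, , drop = FALSE],
              gene_ids = m$gene_ids[keep],
              cell_ids = m$cell_ids, layer = "raw")
}

#' Cell-specific size factors from sequencing depth
#'
#' The size factor of a cell is its total count (sequencing depth) divided by
#' the median depth over all cells, so the median factor is exactly 1 and
#' normalization rescales every cell to the median library size.
#'
#' @param m raw-layer [expr_matrix()]; every cell must have positive depth.
#' @return Numeric vector of positive factors, one per cell.
#' @export
compute_size_factors <- function(m) {
  stop_if_not_layer(m, "raw")
  depths <- colSums(m$values)
  if (any(depths == 0)) {
    bad <- m$cell_ids[which(depths == 0)[1L]]
    stop(sprintf("cell '%s' has zero total count; remove empty cells first",
                 bad))
  }
  depths / median(depths)
}

#' Depth-normalize and log2-transform
#'
#' Divides each cell by its size factor and applies `log2(x + 1)`,
#' producing the log-normalized layer used by all downstream steps.
#'
#' @param m raw-layer [expr_matrix()].
#' @param factors positive size factors, one per cell
#'   (default [compute_size_factors()]).
#' @return A lognorm-layer `expr_matrix` of the same shape.
#' @export
normalize_and_log <- function(m, factors = compute_size_factors(m)) {
  stop_if_not_layer(m, "raw")
  if (length(factors) != n_cells(m))
    stop("length(factors) must equal the number of cells")
  if (any(!is.finite(factors)) || any(factors <= 0))
    stop("size factors must be positive and finite")
  vals <- log2(sweep(m$values, 2L, factors, "/") + 1)
  expr_matrix(vals, gene_ids = m$gene_ids, cell_ids = m$cell_ids,
              layer = "lognorm")
}

#' Drop cells with zero total count
#'
#' @param m raw-layer [expr_matrix()].
#' @return `expr_matrix` without empty cells; warns when any are removed.
#' @export
drop_empty_cells <- function(m) {
  stop_if_not_layer(m, "raw")
  depths <- colSums(m$values)
  if (all(depths > 0)) return(m)
  drop <- which(depths == 0)
  warning(sprintf("removing %d cell(s) with zero total count (e.g. '%s')",
                  length(drop), m$cell_ids[drop[1L]]))
  expr_matrix(m$values[, -drop, drop = FALSE], gene_ids = m$gene_ids,
              cell_ids = m$cell_ids[-drop], layer = "raw")
}

#' Full preprocessing: empty-cell removal, gene filter, log-normalization
#'
#' @inheritParams filter_low_expression
#' @return lognorm-layer `expr_matrix`.
#' @export
preprocess <- function(m, min_cells = 3) {
  m <- drop_empty_cells(m)
  m <- filter_low_expression(m, min_cells = min_cells)
  normalize_and_log(m)
}
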