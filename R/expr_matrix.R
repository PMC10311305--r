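#' Expression matrix container
#'
#' A light container for a genes x cells expression matrix. Values must be
#' finite and non-negative; gene and cell identifiers must be unique. The
#' `layer` flag records whether the matrix holds raw counts or
#' log2-normalized values, and downstream operations check it so that, for
#' example, gene filtering is only ever applied to raw counts.
#'
#' @param values numeric matrix, genes in rows, cells in columns.
#' @param gene_ids character vector of unique gene identifiers (defaults to
#'   `rownames(values)`).
#' @param cell_ids character vector of unique cell identifiers (defaults to
#'   `colnames(values)`).
#' @param layer `"raw"` for counts, `"lognorm"` for log2-normalized values.
#'
#' @return An object of class `expr_matrix`: a list with elements `values`,
#'   `gene_ids`, `cell_ids` and `layer`.
#' @export
#' @examples
#' m <- expr_matrix(matrix(rpois(12, 5), 3, 4))
#' dim(m$values)
expr_matrix <- function(values, gene_ids = rownames(values),
                        cell_ids = colnames(values),
                        layer = c("raw", "lognorm")) {
  layer <- match.arg(layer)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(gene_ids)) gene_ids <- sprintf("gene_%d", seq_len(nrow(values)))
  if (is.null(cell_ids)) cell_ids <- sprintf("cell_%d", seq_len(ncol(values)))
  gene_ids <- as.character(gene_ids)
  cell_ids <- as.character(cell_ids)
  if (length(gene_ids) != nrow(values))
    stop("length(gene_ids) must equal nrow(values)")
  if (length(cell_ids) != ncol(values))
    stop("length(cell_ids) must equal ncol(values)")
  if (anyDuplicated(gene_ids)) stop("duplicated gene identifiers")
  if (anyDuplicated(cell_ids)) stop("duplicated cell identifiers")
  if (anyNA(values) || any(!is.finite(values)))
    stop("expression values must be finite and non-missing")
  if (any(values < 0)) {
    bad <- which(values < 0, arr.ind = TRUE)[1L, ]
    stop(sprintf("negative expression value at gene '%s', cell '%s'",
                 gene_ids[bad[1L]], cell_ids[bad[2L]]))
  }
  dimnames(values) <- list(gene_ids, cell_ids)
  structure(list(values = values, gene_ids = gene_ids,
                 cell_ids = cell_ids, layer = layer),
            class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("<expr_matrix> %d genes x %d cells, layer = %s\n",
              nrow(x$values), ncol(x$values), x$layer))
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

n_genes <- function(m) nrow(m$values)
n_cells <- function(m) ncol(m$values)

stop_if_not_layer <- function(m, layer) {
  if (!inherits(m, "expr_matrix")) stop("expected an expr_matrix")
  if (!identical(m$layer, layer))
    stop(sprintf("expected a %s-layer matrix, got %s", layer, m$layer))
  invisible(m)
}
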