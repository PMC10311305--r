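#' Read an expression matrix from delimited text
#'
#' Expects genes in rows and cells in columns: the first column holds gene
#' identifiers and the header row holds cell identifiers. Set
#' `transpose = TRUE` for cells-in-rows files.
#'
#' @param path CSV/TSV file (separator auto-detected; `.gz` accepted).
#' @param transpose logical; input is cells x genes and must be flipped.
#' @param layer `"raw"` (default) or `"lognorm"`.
#' @return An [expr_matrix()].
#' @export
read_expression_csv <- function(path, transpose = FALSE, layer = "raw") {
  if (!file.exists(path)) stop("input file not found: ", path)
  dt <- data.table::fread(path, header = TRUE, data.table = FALSE)
  if (ncol(dt) < 2L) stop("malformed input: ", path,
                          " has no expression columns")
  ids <- as.character(dt[[1L]])
  vals <- as.matrix(dt[, -1L, drop = FALSE])
  if (!is.numeric(vals)) {
    bad <- which(!vapply(dt[-1L], is.numeric, logical(1L)))[1L]
    stop(sprintf("malformed input: column '%s' of %s is not numeric",
                 names(dt)[-1L][bad], path))
  }
  rownames(vals) <- ids
  if (transpose) vals <- t(vals)
  expr_matrix(vals, layer = layer)
}

#' Write an expression matrix to delimited text
#'
#' Genes in rows, first column `gene_id`, header = cell identifiers.
#'
#' @param m [expr_matrix()].
#' @param path output file; separator picked from the extension
#'   (`.csv` comma, otherwise tab).
#' @export
write_expression_csv <- function(m, path) {
  sep <- if (grepl("\\.csv(\\.gz)?$", path)) "," else "\t"
  dt <- data.table::data.table(gene_id = m$gene_ids)
  dt <- cbind(dt, data.table::as.data.table(m$values))
  data.table::fwrite(dt, path, sep = sep)
  invisible(path)
}

mm_read <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path) else path
  as.matrix(Matrix::readMM(con))
}

read_lines_maybe_gz <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path) else file(path)
  on.exit(try(close(con), silent = TRUE))
  readLines(con)
}

#' Read a Matrix Market expression matrix with name sidecars
#'
#' @param mtx `.mtx` file (genes x cells).
#' @param genes,cells text files with one gene / cell identifier per line.
#' @param transpose logical; the `.mtx` is cells x genes.
#' @param layer `"raw"` or `"lognorm"`.
#' @return An [expr_matrix()].
#' @export
read_expression_mtx <- function(mtx, genes, cells, transpose = FALSE,
                                layer = "raw") {
  for (p in c(mtx, genes, cells))
    if (!file.exists(p)) stop("input file not found: ", p)
  vals <- mm_read(mtx)
  if (transpose) vals <- t(vals)
  gid <- read_lines_maybe_gz(genes)
  cid <- read_lines_maybe_gz(cells)
  if (length(gid) != nrow(vals))
    stop("gene sidecar length (", length(gid),
         ") does not match matrix rows (", nrow(vals), ")")
  if (length(cid) != ncol(vals))
    stop("cell sidecar length (", length(cid),
         ") does not match matrix columns (", ncol(vals), ")")
  expr_matrix(vals, gene_ids = gid, cell_ids = cid, layer = layer)
}

first_existing <- function(dir, candidates) {
  for (f in candidates) {
    p <- file.path(dir, f)
    if (file.exists(p)) return(p)
  }
  stop("none of ", paste(candidates, collapse = ", "),
       " found in ", dir)
}

#' Read a 10x-style expression directory
#'
#' Looks for `matrix.mtx`, `features.tsv` (or `genes.tsv`) and
#' `barcodes.tsv`, with gzipped variants accepted. The feature file may have
#' several tab-separated columns; the first is used as the gene identifier.
#'
#' @param dir directory path.
#' @param layer `"raw"` or `"lognorm"`.
#' @return An [expr_matrix()].
#' @export
read_expression_10x <- function(dir, layer = "raw") {
  if (!dir.exists(dir)) stop("input directory not found: ", dir)
  mtx <- first_existing(dir, c("matrix.mtx", "matrix.mtx.gz"))
  feat <- first_existing(dir, c("features.tsv", "features.tsv.gz",
                                "genes.tsv", "genes.tsv.gz"))
  bc <- first_existing(dir, c("barcodes.tsv", "barcodes.tsv.gz"))
  vals <- mm_read(mtx)
  gid <- vapply(strsplit(read_lines_maybe_gz(feat), "\t"), `[`, "", 1L)
  cid <- read_lines_maybe_gz(bc)
  if (length(gid) != nrow(vals) || length(cid) != ncol(vals))
    stop("sidecar lengths do not match the matrix dimensions in ", dir)
  expr_matrix(vals, gene_ids = gid, cell_ids = cid, layer = layer)
}

#' Write an expression matrix as a Matrix Market triple
#'
#' Writes `matrix.mtx`, `features.tsv` and `barcodes.tsv` into `dir`, the
#' same layout [read_expression_10x()] accepts.
#'
#' @param m [expr_matrix()].
#' @param dir output directory (created if missing).
#' @export
write_expression_mtx <- function(m, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(Matrix::Matrix(m$values, sparse = TRUE),
                  file.path(dir, "matrix.mtx"))
  writeLines(m$gene_ids, file.path(dir, "features.tsv"))
  writeLines(m$cell_ids, file.path(dir, "barcodes.tsv"))
  invisible(dir)
}
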