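#' Run the full feature-selection pipeline in memory
#'
#' Raw input is preprocessed (empty-cell removal, low-expression filter,
#' log-normalization); cell labels are predicted by the spectral clustering
#' flow; cluster sizes are balanced; a forest of decision trees scores
#' genes by Gini importance; and the final set is extracted by the
#' three-sigma cut with correlation pruning. A lognorm-layer input skips
#' preprocessing.
#'
#' @param m an [expr_matrix()] (raw or lognorm layer).
#' @param n_clusters integer or `"auto"` (eigengap heuristic).
#' @param seed integer seed driving every stochastic step.
#' @param min_cells gene filter threshold (default 3).
#' @param n_pcs,knn_k spectral-flow parameters (defaults 50, 15).
#' @param retain_U,smote_k,balance_mode balancing parameters
#'   (defaults 0.8, 5, `"both"`).
#' @param n_trees,subspace forest parameters (defaults 500, `"sqrt"`; see
#'   [fit_forest_importance()] for how the tree count interacts with the
#'   per-tree gene subspace).
#' @param v,v_prime pruning parameters (defaults 0.8, 0.1).
#' @return Object of class `pipeline_result`: `selection`
#'   (a `gene_selection`), `importance`, `labeling`, `plan`,
#'   `balanced_sizes`, `lognorm` (the preprocessed matrix) and `params`
#'   (all resolved parameters).
#' @export
run_pipeline <- function(m, n_clusters = "auto", seed = 1, min_cells = 3,
                         n_pcs = 50, knn_k = 15, retain_U = 0.8,
                         smote_k = 5, balance_mode = "both", n_trees = 500,
                         subspace = "sqrt", v = 0.8, v_prime = 0.1) {
  params <- list(n_clusters = n_clusters, seed = seed, min_cells = min_cells,
                 n_pcs = n_pcs, knn_k = knn_k, retain_U = retain_U,
                 smote_k = smote_k, balance_mode = balance_mode,
                 n_trees = n_trees, subspace = subspace, v = v,
                 v_prime = v_prime)
  ln <- if (identical(m$layer, "raw")) preprocess(m, min_cells = min_cells)
        else m
  lab <- predict_labels(ln, n_clusters = n_clusters, seed = seed,
                        n_pcs = n_pcs, knn_k = knn_k)
  plan <- plan_balance(lab, U = retain_U, smote_k = smote_k)
  bal <- balance(ln, lab, plan, seed = seed, mode = balance_mode)
  imp <- fit_forest_importance(bal, n_trees = n_trees, subspace = subspace,
                               seed = seed)
  sel <- select_features(ln, imp, v = v, v_prime = v_prime)
  structure(list(selection = sel, importance = imp, labeling = lab,
                 plan = plan, balanced_sizes = tabulate(bal$labels, lab$n),
                 lognorm = ln, params = params),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf(paste0("<pipeline_result> %d clusters (sizes: %s), ",
                     "%d genes selected (%d pruned as redundant)\n"),
              x$labeling$n, paste(x$labeling$sizes, collapse = ", "),
              length(x$selection$genes), nrow(x$selection$removed)))
  invisible(x)
}

read_any_expression <- function(input, format = c("csv", "mtx", "10x"),
                                transpose = FALSE) {
  format <- match.arg(format)
  switch(format,
         csv = read_expression_csv(input, transpose = transpose),
         mtx = {
           dir <- dirname(input)
           read_expression_mtx(input,
                               genes = first_existing(dir, c("features.tsv",
                                                             "features.tsv.gz",
                                                             "genes.tsv",
                                                             "genes.tsv.gz")),
                               cells = first_existing(dir, c("barcodes.tsv",
                                                             "barcodes.tsv.gz")),
                               transpose = transpose)
         },
         `10x` = read_expression_10x(input))
}

#' Run the pipeline from files and write all artifacts
#'
#' Reads an expression matrix, runs [run_pipeline()], and writes into
#' `out_dir`: `selected_genes.txt` (one id per line, importance order),
#' `importance.tsv`, `audit.tsv` (kept/removed trail), `labels.tsv`
#' (predicted labels per cell) and `run_log.json` (every resolved
#' parameter, for reruns). Outputs are byte-identical across reruns with
#' the same configuration and seed.
#'
#' @param input path to the expression input.
#' @param out_dir output directory, created if missing.
#' @param format `"csv"`, `"mtx"` or `"10x"`.
#' @param transpose input is cells x genes (csv/mtx only).
#' @param ... parameters forwarded to [run_pipeline()].
#' @return The `pipeline_result`, invisibly.
#' @export
run_pipeline_files <- function(input, out_dir, format = "csv",
                               transpose = FALSE, ...) {
  m <- read_any_expression(input, format = format, transpose = transpose)
  res <- run_pipeline(m, ...)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  writeLines(as.character(res$selection$genes),
             file.path(out_dir, "selected_genes.txt"))
  write_importance(res$importance, file.path(out_dir, "importance.tsv"))
  write_selection_audit(res$selection, res$importance,
                        file.path(out_dir, "audit.tsv"))
  data.table::fwrite(data.table::data.table(cell_id = res$lognorm$cell_ids,
                                            label = res$labeling$labels),
                     file.path(out_dir, "labels.tsv"), sep = "\t")
  log <- c(res$params,
           list(input = input, format = format, transpose = transpose,
                n_cells = length(res$lognorm$cell_ids),
                n_genes_after_filter = length(res$lognorm$gene_ids),
                n_selected = length(res$selection$genes),
                package_version = as.character(utils::packageVersion("scGeneForest"))))
  jsonlite::write_json(log, file.path(out_dir, "run_log.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(res)
}
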