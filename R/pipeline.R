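#' Run the full pipeline on a count matrix and write its result files
#'
#' Chains quality filtering ([qc_filter_cells()]), `log2(TPM/10 + 1)`
#' normalization ([normalize_log_tpm()]), recursive random-forest
#' clustering ([recursive_cluster()]) and one-vs-rest marker detection
#' ([find_markers()]) and writes three deterministic files to `out_dir`:
#' `clusters.tsv` (cell, leaf label, vote probability, abandoned flag),
#' `markers.tsv` (marker table over all leaves), and `report.json`
#' (QC log, leaf sizes, per-region leaf composition and the split tree
#' with stop reasons). Running twice with an identical input and seed
#' produces byte-identical files.
#'
#' @param counts A [count_matrix()] with populated metadata, or a fixture
#'   directory readable by [read_fixture()].
#' @param out_dir Output directory (created if absent).
#' @param params A [cluster_params()] (carries the seed).
#' @param min_genes,min_umis,min_map_ratio,max_raw_reads QC thresholds, see
#'   [qc_filter_cells()].
#' @return Invisibly, a list with the `tree`, `assignments`, `markers`, the
#'   normalized matrix and the paths written.
#' @export
run_pipeline <- function(counts, out_dir, params = cluster_params(),
                         min_genes = 1000, min_umis = 20000,
                         min_map_ratio = 0.2, max_raw_reads = NULL) {
  if (is.character(counts)) counts <- read_fixture(counts)$counts
  stopifnot(inherits(counts, "CountMatrix"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  qc <- qc_filter_cells(counts, min_genes = min_genes, min_umis = min_umis,
                        min_map_ratio = min_map_ratio,
                        max_raw_reads = max_raw_reads)
  expr <- normalize_log_tpm(qc)
  tree <- recursive_cluster(expr, params = params)
  assign <- cluster_assignments(tree)
  labs <- stats::setNames(assign$cluster, assign$cell_id)
  labs <- labs[!is.na(labs)]
  mexpr <- expr$expr[, names(labs), drop = FALSE]
  markers <- do.call(rbind, lapply(names(tree$leaves), function(lab) {
    if (length(tree$leaves) < 2) return(NULL)
    find_markers(mexpr, labs, lab)
  }))
  if (is.null(markers))
    markers <- data.frame(gene = character(0), cluster = character(0),
                          fold_change = numeric(0), auc = numeric(0),
                          power = numeric(0), stringsAsFactors = FALSE)
  clusters_path <- file.path(out_dir, "clusters.tsv")
  markers_path <- file.path(out_dir, "markers.tsv")
  report_path <- file.path(out_dir, "report.json")
  utils::write.table(assign, clusters_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(markers, markers_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  region <- qc$meta$region[match(assign$cell_id, qc$meta$cell_id)]
  comp <- table(region = region, cluster = assign$cluster)
  report <- list(
    n_cells_input = ncol(counts$counts),
    n_cells_qc = ncol(qc$counts),
    qc_removed = qc_log(qc),
    n_leaves = length(tree$leaves),
    leaf_sizes = as.list(lengths(tree$leaves)),
    n_abandoned = length(tree$abandoned),
    region_composition = as.data.frame(comp, stringsAsFactors = FALSE),
    tree = .tree_summary(tree$root))
  jsonlite::write_json(report, report_path, auto_unbox = TRUE, digits = 10,
                       pretty = TRUE)
  invisible(list(tree = tree, assignments = assign, markers = markers,
                 expr = expr,
                 paths = c(clusters_path, markers_path, report_path)))
}

# Internal: JSON-friendly skeleton of the split tree.
.tree_summary <- function(node) {
  if (node$type == "leaf")
    return(list(type = "leaf", n_cells = length(node$cells),
                stop_reason = node$stop_reason))
  list(type = "split", n_cells = length(node$cells),
       n_deg = node$n_deg, n_feature_genes = length(node$feature_genes),
       n_abandoned = length(node$abandoned),
       left = .tree_summary(node$left), right = .tree_summary(node$right))
}
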