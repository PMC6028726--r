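#' ROC classification power of a gene between two groups
#'
#' The AUC is the probability that a random value from `x` exceeds one from
#' `y`, counting ties as one half -- the rank-sum statistic rescaled to
#' [0, 1]. The classification power folds the AUC onto a 0-to-1 scale where
#' 0 means the gene separates the groups no better than chance and 1 means
#' perfectly: `power = 2 * |auc - 0.5|`.
#'
#' @param x,y Numeric expression values for the two groups (each non-empty).
#' @return A list with elements `auc` and `power`.
#' @export
auc_classification_power <- function(x, y) {
  if (length(x) < 1 || length(y) < 1) stop("empty group")
  r <- rank(c(x, y))
  nx <- length(x)
  auc <- (sum(r[seq_len(nx)]) - nx * (nx + 1) / 2) / (nx * length(y))
  list(auc = auc, power = 2 * abs(auc - 0.5))
}

# Internal: per-gene AUC of cluster cells vs rest over the rows of a dense
# matrix. Columns in `in_idx` form group x.
.auc_rows <- function(mat, in_idx) {
  nx <- length(in_idx)
  ny <- ncol(mat) - nx
  apply(mat, 1, function(v) {
    r <- rank(v)
    (sum(r[in_idx]) - nx * (nx + 1) / 2) / (nx * ny)
  })
}

#' Marker genes of a cluster by fold-change and classification power
#'
#' One-vs-rest differential expression: for each gene the fold change is
#' the ratio of mean linear expression (`2^expr - 1`, pseudocount
#' `eps = 0.01`) in the cluster versus the rest, and the classification
#' power comes from the ROC AUC (see [auc_classification_power()]). A gene
#' is a marker when `fold_change >= fc_hi` or `<= fc_lo` (so both
#' directions count) and `power >= power_min`.
#'
#' @param expr An [expr_matrix()] or plain `log2(TPM/10 + 1)` matrix.
#' @param labels Cluster labels, either named by cell id or aligned with
#'   the columns of `expr`.
#' @param cluster The cluster whose markers are sought; it and its
#'   complement must each hold at least 2 cells.
#' @param fc_lo,fc_hi Fold-change gates (linear scale).
#' @param power_min Minimum classification power.
#' @param eps Pseudocount added to both group means.
#' @return A `data.frame` with columns `gene`, `cluster`, `fold_change`,
#'   `auc`, `power`, sorted by power (descending), then `|log2
#'   fold_change|` (descending), then gene id.
#' @export
find_markers <- function(expr, labels, cluster, fc_lo = 0.5, fc_hi = 2,
                         power_min = 0.4, eps = 0.01) {
  m <- .expr_of(expr)
  labels <- .align_labels(labels, colnames(m))
  in_cells <- which(labels == cluster)
  if (length(in_cells) == 0) stop("cluster not present in labels")
  if (length(in_cells) < 2) stop("singleton cluster")
  if (ncol(m) - length(in_cells) < 2)
    stop("need at least 2 cells outside the cluster")
  lin <- m
  lin@x <- 2^lin@x - 1
  mean_in <- Matrix::rowMeans(lin[, in_cells, drop = FALSE])
  mean_out <- Matrix::rowMeans(lin[, -in_cells, drop = FALSE])
  fc <- (mean_in + eps) / (mean_out + eps)
  dm <- as.matrix(m)
  auc <- .auc_rows(dm, in_cells)
  power <- 2 * abs(auc - 0.5)
  pass <- (fc >= fc_hi | fc <= fc_lo) & power >= power_min
  out <- data.frame(gene = rownames(m)[pass],
                    cluster = rep(cluster, sum(pass)),
                    fold_change = unname(fc[pass]), auc = unname(auc[pass]),
                    power = unname(power[pass]), stringsAsFactors = FALSE,
                    row.names = NULL)
  out[order(-out$power, -abs(log2(out$fold_change)), out$gene), ,
      drop = FALSE]
}

#' Number of differentially expressed genes between two cell groups
#'
#' Counts genes passing the marker gates in either direction between two
#' explicit groups; this is the quantity the recursive clustering uses to
#' accept or reject a split.
#'
#' @param expr Expression matrix (see [find_markers()]).
#' @param cells_a,cells_b Disjoint character vectors of cell ids.
#' @inheritParams find_markers
#' @return Integer count of DEGs.
#' @export
count_degs <- function(expr, cells_a, cells_b, fc_lo = 0.5, fc_hi = 2,
                       power_min = 0.4, eps = 0.01) {
  stopifnot(length(intersect(cells_a, cells_b)) == 0)
  m <- .expr_of(expr)
  m <- m[, c(cells_a, cells_b), drop = FALSE]
  labels <- rep(c("a", "b"), c(length(cells_a), length(cells_b)))
  nrow(find_markers(m, labels, "a", fc_lo = fc_lo, fc_hi = fc_hi,
                    power_min = power_min, eps = eps))
}

# Internal: recycle/reorder labels to the given cell ids.
.align_labels <- function(labels, cells) {
  labels <- stats::setNames(as.character(labels), names(labels))
  if (!is.null(names(labels))) {
    if (!all(cells %in% names(labels)))
      stop("labels are missing some cells")
    labels <- labels[cells]
  } else if (length(labels) != length(cells)) {
    stop("labels must be named by cell or match the number of cells")
  }
  unname(labels)
}
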