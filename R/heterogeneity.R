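#' Rank-sum comparison of two cell-cell correlation distributions
#'
#' Compares the off-diagonal pairwise correlations among the cells of group
#' A (each unordered pair once, self-pairs excluded) against the
#' correlations between cells of group A and cells of group B (pairs of the
#' same cell excluded, so overlapping groups contribute no self
#' correlations). Uses a two-sided rank-sum test: exact enumeration when
#' both samples have at most `exact_max` values and no ties, the normal
#' approximation with tie correction otherwise.
#'
#' @param cc Cell-cell Pearson correlation matrix with cell-id dimnames.
#' @param idx_a,idx_b Cell ids (or indices) of the two groups; A needs at
#'   least 2 cells, B at least 1.
#' @param exact_max Largest per-group sample size for the exact test.
#' @return A list with `n_within`, `n_cross`, `median_within`,
#'   `median_cross`, and `p_value`.
#' @export
correlation_pair_test <- function(cc, idx_a, idx_b, exact_max = 20) {
  if (is.character(idx_a)) idx_a <- match(idx_a, colnames(cc))
  if (is.character(idx_b)) idx_b <- match(idx_b, colnames(cc))
  stopifnot(!anyNA(idx_a), !anyNA(idx_b), length(idx_a) >= 2,
            length(idx_b) >= 1)
  within <- cc[idx_a, idx_a][upper.tri(diag(length(idx_a)))]
  cross <- cc[idx_a, idx_b, drop = FALSE]
  same <- outer(idx_a, idx_b, "==")
  cross <- cross[!same]
  exact <- length(within) <= exact_max && length(cross) <= exact_max &&
    !anyDuplicated(c(within, cross))
  p <- suppressWarnings(stats::wilcox.test(within, cross,
                                           exact = exact)$p.value)
  list(n_within = length(within), n_cross = length(cross),
       median_within = stats::median(within),
       median_cross = stats::median(cross), p_value = p)
}

#' Regional heterogeneity of cell-cell correlations per sub-cluster
#'
#' For every sub-cluster with more than `min_cells` cells, highly variable
#' genes are selected on that sub-cluster ([select_hvg_dispersion()]) and
#' the Pearson correlation between its cells is computed over them. For
#' each ordered pair of regions (A, B) the within-A correlation
#' distribution is compared to the A-vs-B cross distribution with a
#' two-sided rank-sum test ([correlation_pair_test()]). A lower within
#' median than in another region indicates a more heterogeneous population
#' there.
#'
#' @param expr An [expr_matrix()] or plain matrix.
#' @param clusters Sub-cluster labels, named by cell or aligned to columns.
#' @param regions Region labels, named by cell or aligned to columns.
#' @param min_cells Only sub-clusters with strictly more cells are tested.
#' @param mean_min,disp_min Thresholds for the per-sub-cluster HVG
#'   selection.
#' @param min_region_cells Regions with fewer cells of the sub-cluster are
#'   skipped (with a log entry in attribute `"skipped"`).
#' @return A `data.frame` with one row per (sub-cluster, region A,
#'   region B): sizes, within/cross medians, and the rank-sum `p_value`.
#' @export
regional_heterogeneity <- function(expr, clusters, regions, min_cells = 200,
                                   mean_min = 1, disp_min = 1,
                                   min_region_cells = 2) {
  m <- .expr_of(expr)
  clusters <- .align_labels(clusters, colnames(m))
  regions <- .align_labels(regions, colnames(m))
  rows <- list()
  skipped <- character(0)
  for (cl in sort(unique(clusters))) {
    cl_cells <- sort(colnames(m)[clusters == cl])
    if (length(cl_cells) <= min_cells) next
    sub <- m[, cl_cells, drop = FALSE]
    hvgs <- select_hvg_dispersion(sub, mean_min = mean_min,
                                  disp_min = disp_min)
    if (length(hvgs) < 2) {
      skipped <- c(skipped, sprintf("%s: fewer than 2 variable genes", cl))
      next
    }
    cc <- suppressWarnings(stats::cor(as.matrix(sub[hvgs, , drop = FALSE])))
    cc[!is.finite(cc)] <- 0
    reg <- regions[match(cl_cells, colnames(m))]
    reg_levels <- sort(unique(reg))
    for (ra in reg_levels) {
      a <- cl_cells[reg == ra]
      if (length(a) < max(2, min_region_cells)) {
        skipped <- c(skipped, sprintf("%s/%s: fewer than %d cells", cl, ra,
                                      max(2, min_region_cells)))
        next
      }
      for (rb in setdiff(reg_levels, ra)) {
        b <- cl_cells[reg == rb]
        if (length(b) < min_region_cells) next
        ct <- correlation_pair_test(cc, a, b)
        rows[[length(rows) + 1L]] <- data.frame(
          cluster = cl, region_a = ra, region_b = rb,
          n_a = length(a), n_b = length(b),
          n_within = ct$n_within, n_cross = ct$n_cross,
          median_within = ct$median_within,
          median_cross = ct$median_cross, p_value = ct$p_value,
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows)
         else data.frame(cluster = character(0), region_a = character(0),
                         region_b = character(0), n_a = integer(0),
                         n_b = integer(0), n_within = integer(0),
                         n_cross = integer(0), median_within = numeric(0),
                         median_cross = numeric(0), p_value = numeric(0),
                         stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  out
}
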