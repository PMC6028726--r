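#' Cell cycle scores from phase gene sets
#'
#' The score for each phase is the unweighted mean expression of the
#' phase's gene set in each cell (e.g. a G1/S set and a G2/M set). Set
#' genes absent from the matrix are dropped with a warning; a set with no
#' gene present is an error.
#'
#' @param expr An [expr_matrix()] or plain matrix.
#' @param g1s,g2m Character vectors of gene ids (e.g. from [read_gmt()]).
#' @return A `data.frame` with `cell_id`, `g1s_score`, `g2m_score`, and the
#'   `phase` call from [classify_phase()].
#' @export
cellcycle_scores <- function(expr, g1s, g2m) {
  m <- .expr_of(expr)
  s1 <- .set_score(m, g1s, "G1/S")
  s2 <- .set_score(m, g2m, "G2/M")
  data.frame(cell_id = colnames(m), g1s_score = unname(s1),
             g2m_score = unname(s2),
             phase = classify_phase(s1, s2),
             stringsAsFactors = FALSE, row.names = NULL)
}

# Internal: per-cell mean expression over the present genes of a set.
.set_score <- function(m, set, label) {
  set <- unique(set)
  present <- intersect(set, rownames(m))
  if (length(present) == 0)
    stop("no ", label, " set gene present in the matrix")
  if (length(present) < length(set))
    warning(sprintf("%s: %d of %d set genes absent from the matrix, dropped",
                    label, length(set) - length(present), length(set)))
  Matrix::colMeans(m[present, , drop = FALSE])
}

#' Classify cell cycle phase from G1/S and G2/M scores
#'
#' A cell is quiescent when both scores are below 2; otherwise it is
#' proliferative and assigned G2/M when its G2/M score exceeds its G1/S
#' score, and G1/S when the G1/S score exceeds the G2/M score. The rule
#' pair leaves the exact tie (both scores equal and at least 2) uncovered;
#' such cells are assigned G1/S (documented tie-break, configurable).
#'
#' @param g1s,g2m Numeric score vectors (recycled to a common length).
#' @param tie Phase assigned when a proliferative cell has exactly equal
#'   scores.
#' @return Character vector over `{"quiescent", "G1/S", "G2/M"}`.
#' @export
classify_phase <- function(g1s, g2m, tie = "G1/S") {
  stopifnot(tie %in% c("G1/S", "G2/M"))
  n <- max(length(g1s), length(g2m))
  g1s <- rep_len(g1s, n); g2m <- rep_len(g2m, n)
  ifelse(g1s < 2 & g2m < 2, "quiescent",
         ifelse(g2m > g1s, "G2/M",
                ifelse(g1s > g2m, "G1/S", tie)))
}

#' Per-region tallies and ratio of two marker-positive interneuron types
#'
#' A cell is positive for a marker when its `log2(TPM/10 + 1)` expression
#' is strictly greater than `pos_threshold`. Within each region the ratio
#' is `nA / (nA + nB)`; cells positive for both markers count in both
#' tallies, cells positive for neither count in neither. Regions with
#' `nA + nB = 0` are reported with an `NA` ratio.
#'
#' @param expr An [expr_matrix()] or plain matrix.
#' @param cells Cell ids of the interneuron population to tally.
#' @param regions Region labels, named by cell id or aligned to `cells`.
#' @param gene_a,gene_b Marker genes (defaults: the MGE-derived marker LHX6
#'   and the CGE-derived marker CALB2).
#' @param pos_threshold Positivity threshold (strict `>`).
#' @param min_sum Region-size threshold forwarded to
#'   [classify_region_dominance()].
#' @return A `data.frame` with one row per region: `region`, `n_a`, `n_b`,
#'   `ratio`, `dominance`.
#' @export
interneuron_region_ratio <- function(expr, cells, regions,
                                     gene_a = "LHX6", gene_b = "CALB2",
                                     pos_threshold = 1, min_sum = 15) {
  m <- .expr_of(expr)
  stopifnot(all(cells %in% colnames(m)),
            all(c(gene_a, gene_b) %in% rownames(m)))
  regions <- .align_labels(regions, cells)
  pos_a <- as.vector(m[gene_a, cells] > pos_threshold)
  pos_b <- as.vector(m[gene_b, cells] > pos_threshold)
  out <- do.call(rbind, lapply(sort(unique(regions)), function(r) {
    sel <- regions == r
    na <- sum(pos_a[sel]); nb <- sum(pos_b[sel])
    data.frame(region = r, n_a = na, n_b = nb,
               ratio = if (na + nb > 0) na / (na + nb) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  out$dominance <- classify_region_dominance(out$n_a, out$n_b, out$ratio,
                                             min_sum = min_sum)
  rownames(out) <- NULL
  out
}

#' Dominance label of a region from interneuron tallies
#'
#' A region is `insufficient` when the two tallies sum to fewer than
#' `min_sum` cells; otherwise it is labelled for type A when the ratio is
#' strictly above 0.6, for type B when strictly below 0.4, and `balanced`
#' in between (the boundaries 0.4 and 0.6 fall to `balanced`).
#'
#' @param n_a,n_b Per-region positive-cell tallies.
#' @param ratio Per-region `n_a / (n_a + n_b)`.
#' @param min_sum Minimum `n_a + n_b` for a call.
#' @param labels Dominance labels for type A and type B.
#' @return Character vector over `{labels[1], labels[2], "balanced",
#'   "insufficient"}`.
#' @export
classify_region_dominance <- function(n_a, n_b, ratio, min_sum = 15,
                                      labels = c("LHX6", "CALB2")) {
  ifelse(n_a + n_b < min_sum, "insufficient",
         ifelse(ratio > 0.6, labels[1],
                ifelse(ratio < 0.4, labels[2], "balanced")))
}

#' Per-region maturity as the fraction of cells truly expressing a marker
#'
#' For each region, the fraction of the given cells (e.g. excitatory
#' neurons) whose expression of the upper-layer marker exceeds the
#' threshold (`log2(TPM/10 + 1) > 1` counts as true expression). Regions
#' with fewer than `min_n` cells are excluded from the call.
#'
#' @param expr An [expr_matrix()] or plain matrix.
#' @param cells Cell ids of the population (e.g. excitatory neurons).
#' @param regions Region labels, named by cell or aligned to `cells`.
#' @param gene Marker gene (default CUX2).
#' @param pos_threshold Positivity threshold (strict `>`).
#' @param min_n Minimum cells per region.
#' @return A `data.frame` with `region`, `n`, `ratio` (`NA` when excluded)
#'   and `excluded`.
#' @export
cux2_maturity_ratio <- function(expr, cells, regions, gene = "CUX2",
                                pos_threshold = 1, min_n = 50) {
  m <- .expr_of(expr)
  stopifnot(all(cells %in% colnames(m)), gene %in% rownames(m))
  regions <- .align_labels(regions, cells)
  pos <- as.vector(m[gene, cells] > pos_threshold)
  out <- do.call(rbind, lapply(sort(unique(regions)), function(r) {
    sel <- regions == r
    n <- sum(sel)
    data.frame(region = r, n = n,
               ratio = if (n >= min_n) mean(pos[sel]) else NA_real_,
               excluded = n < min_n, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Per-region synapse maturity score from a gene set
#'
#' The per-neuron score is the mean expression over the synapse gene set
#' (e.g. synaptic-transmission and vesicle GO terms, supplied as a GMT
#' set -- membership is configuration, not computed); the region score is
#' the mean of its neurons' scores. Regions with fewer than `min_n` cells
#' are excluded.
#'
#' @param expr An [expr_matrix()] or plain matrix.
#' @param cells Neuron cell ids.
#' @param regions Region labels, named by cell or aligned to `cells`.
#' @param gene_set Character vector of synapse genes.
#' @param min_n Minimum neurons per region.
#' @return A `data.frame` with `region`, `n`, `score` (`NA` when excluded)
#'   and `excluded`.
#' @export
synapse_maturity_score <- function(expr, cells, regions, gene_set,
                                   min_n = 50) {
  m <- .expr_of(expr)
  stopifnot(all(cells %in% colnames(m)))
  regions <- .align_labels(regions, cells)
  per_cell <- .set_score(m[, cells, drop = FALSE], gene_set, "synapse")
  out <- do.call(rbind, lapply(sort(unique(regions)), function(r) {
    sel <- regions == r
    n <- sum(sel)
    data.frame(region = r, n = n,
               score = if (n >= min_n) mean(per_cell[sel]) else NA_real_,
               excluded = n < min_n, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Per-cell gene-set enrichment by ranking-recovery AUC
#'
#' For each cell, all genes are ranked by expression (descending; ties
#' broken by a seeded random order) and the recovery curve counts how many
#' set genes appear within the top `ceiling(top_frac * G)` ranks as the cut
#' moves down. The score is the area under that curve divided by the
#' maximal achievable area (all set genes at the very top), giving a value
#' in [0, 1] that is monotone in the expression of set genes.
#'
#' @param expr An [expr_matrix()] or plain matrix.
#' @param gene_set Character vector of set genes; absent genes are dropped
#'   with a warning.
#' @param cells Cells to score (default all).
#' @param top_frac Fraction of the ranking examined.
#' @param seed Seed for the tie-breaking order.
#' @return Named numeric vector of per-cell scores in [0, 1].
#' @export
geneset_enrichment_auc <- function(expr, gene_set, cells = NULL,
                                   top_frac = 0.05, seed = 0) {
  m <- .expr_of(expr)
  if (is.null(cells)) cells <- colnames(m)
  stopifnot(all(cells %in% colnames(m)), top_frac > 0, top_frac <= 1)
  gene_set <- unique(gene_set)
  present <- intersect(gene_set, rownames(m))
  if (length(present) == 0) stop("no set gene present in the matrix")
  if (length(present) < length(gene_set))
    warning(sprintf("%d of %d set genes absent from the matrix, dropped",
                    length(gene_set) - length(present), length(gene_set)))
  G <- nrow(m)
  top <- ceiling(top_frac * G)
  k <- length(present)
  if (k > top)
    warning("gene set larger than the examined top ranks; ",
            "normalizing by the achievable maximum")
  kmax <- min(k, top)
  area_max <- sum(pmin(seq_len(top), kmax))
  set_idx <- match(present, rownames(m))
  set.seed(seed)
  scores <- vapply(cells, function(cl) {
    v <- as.vector(m[, cl])
    tb <- sample.int(G)
    ord <- order(-v, tb)
    pos <- which(ord %in% set_idx)
    hits <- tabulate(pos[pos <= top], nbins = top)
    sum(cumsum(hits)) / area_max
  }, numeric(1))
  stats::setNames(scores, cells)
}
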