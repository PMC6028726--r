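#' Deduplicate tagged reads into a distinct-UMI count matrix
#'
#' Each transcript molecule is identified by the tuple (cell barcode, gene,
#' UMI); duplicated reads with an identical tuple are discarded and the
#' count for a gene in a cell is the number of distinct UMIs observed for
#' it. Deduplication uses exact string identity only -- no edit-distance
#' collapsing.
#'
#' @param reads A `data.frame` with character columns `barcode`, `umi`,
#'   `gene` (one row per read), e.g. from [simulate_tagged_reads()] or
#'   [read_tagged_reads()].
#' @return A [count_matrix()] with genes and cells ordered
#'   lexicographically. Metadata columns are left `NA`; attach them with
#'   [set_cell_metadata()] before QC. An empty stream yields a 0 x 0 matrix.
#' @export
demultiplex_count <- function(reads) {
  need <- c("barcode", "umi", "gene")
  if (!all(need %in% names(reads)))
    stop("reads must have columns barcode, umi, gene")
  if (nrow(reads) == 0)
    return(count_matrix(matrix(0L, 0, 0,
                               dimnames = list(character(0), character(0)))))
  if (any(!nzchar(reads$barcode)) || any(!nzchar(reads$umi)) ||
      any(!nzchar(reads$gene)))
    stop("reads must have non-empty barcode, umi and gene fields")
  key <- paste(reads$barcode, reads$gene, reads$umi, sep = "\r")
  mol <- reads[!duplicated(key), c("barcode", "gene")]
  genes <- sort(unique(mol$gene))
  cells <- sort(unique(mol$barcode))
  m <- Matrix::sparseMatrix(i = match(mol$gene, genes),
                            j = match(mol$barcode, cells),
                            x = 1L, dims = c(length(genes), length(cells)),
                            dimnames = list(genes, cells))
  count_matrix(m)
}

#' Attach per-cell metadata to a count matrix
#'
#' @param counts A [count_matrix()].
#' @param meta `data.frame` with a `cell_id` column (or row names) covering
#'   every cell, plus any of `region`, `embryo`, `raw_reads`,
#'   `mapping_ratio`.
#' @return The `CountMatrix` with metadata filled in.
#' @export
set_cell_metadata <- function(counts, meta) {
  stopifnot(inherits(counts, "CountMatrix"))
  count_matrix(counts$counts, meta)
}

#' Quality-filter cells of a count matrix
#'
#' Retains cells with at least `min_genes` detected genes (count > 0), at
#' least `min_umis` total distinct UMIs, and a mapping ratio of at least
#' `min_map_ratio`; the removal rule is "fewer than", so a cell exactly at a
#' threshold is retained. Optionally, cells with more than `max_raw_reads`
#' raw reads are removed as a guard against wells that were not truly single
#' cells; this guard is off by default because no principled fixed cut-off
#' exists (see [raw_reads_cutoff()] for a percentile helper).
#'
#' @param counts A [count_matrix()] with populated `mapping_ratio` (and
#'   `raw_reads` when `max_raw_reads` is used).
#' @param min_genes,min_umis,min_map_ratio Inclusive retention thresholds.
#' @param max_raw_reads Optional upper bound on raw reads (inclusive), or
#'   `NULL` to disable.
#' @return The filtered `CountMatrix`. The removed cells and their
#'   comma-separated reasons (`genes`, `umis`, `mapping_ratio`,
#'   `raw_reads`) are available via [qc_log()].
#' @export
qc_filter_cells <- function(counts, min_genes = 1000, min_umis = 20000,
                            min_map_ratio = 0.2, max_raw_reads = NULL) {
  stopifnot(inherits(counts, "CountMatrix"))
  m <- counts$counts
  meta <- counts$meta
  if (!"mapping_ratio" %in% names(meta) || anyNA(meta$mapping_ratio))
    stop("metadata column mapping_ratio is required for QC")
  if (!is.null(max_raw_reads) &&
      (!"raw_reads" %in% names(meta) || anyNA(meta$raw_reads)))
    stop("metadata column raw_reads is required when max_raw_reads is set")
  n_genes <- Matrix::colSums(m > 0)
  n_umis <- Matrix::colSums(m)
  fail <- cbind(genes = n_genes < min_genes,
                umis = n_umis < min_umis,
                mapping_ratio = meta$mapping_ratio < min_map_ratio,
                raw_reads = if (is.null(max_raw_reads)) FALSE
                            else meta$raw_reads > max_raw_reads)
  keep <- rowSums(fail) == 0
  failed <- fail[!keep, , drop = FALSE]
  lg <- data.frame(
    cell_id = colnames(m)[!keep],
    reason = vapply(seq_len(nrow(failed)), function(i)
      paste(colnames(fail)[failed[i, ]], collapse = ","), character(1)),
    stringsAsFactors = FALSE, row.names = NULL)
  out <- count_matrix(m[, keep, drop = FALSE],
                      meta[keep, , drop = FALSE])
  attr(out, "qc_log") <- lg
  out
}

#' Suggested raw-read upper bound from the observed distribution
#'
#' @param counts A [count_matrix()] with `raw_reads` metadata.
#' @param probs Quantile used as the cut-off.
#' @return The raw-read count at that quantile.
#' @export
raw_reads_cutoff <- function(counts, probs = 0.995) {
  stopifnot(inherits(counts, "CountMatrix"))
  if (anyNA(counts$meta$raw_reads)) stop("raw_reads metadata is required")
  as.numeric(stats::quantile(counts$meta$raw_reads, probs))
}

#' Normalize UMI counts to log2(TPM/10 + 1)
#'
#' TPM is the count scaled to a per-cell total of one million (no
#' gene-length term, since distinct UMIs already count molecules). Because
#' typical cells carry far fewer than one million UMIs, plain log2(TPM + 1)
#' would count each molecule several times and overstate expression; the
#' extra division by 10 tempers that, giving
#' `expr = log2(count / total * 1e5 + 1)`.
#'
#' @param counts A QC-passing [count_matrix()]; a cell with zero total
#'   counts is an error.
#' @return An [expr_matrix()] carrying the same metadata. For every cell,
#'   `sum((2^expr - 1) * 10) == 1e6` up to floating-point error.
#' @export
normalize_log_tpm <- function(counts) {
  stopifnot(inherits(counts, "CountMatrix"))
  tot <- Matrix::colSums(counts$counts)
  if (ncol(counts$counts) > 0 && any(tot == 0)) stop("empty cell")
  m <- counts$counts %*% Matrix::Diagonal(x = ifelse(tot > 0, 1e5 / tot, 0))
  m <- methods::as(methods::as(m, "generalMatrix"), "CsparseMatrix")
  m@x <- log2(m@x + 1)
  dimnames(m) <- dimnames(counts$counts)
  expr_matrix(m, counts$meta)
}

#' De-log an expression matrix back to the linear TPM/10 scale
#'
#' @param expr An [expr_matrix()] or plain `log2(TPM/10 + 1)` matrix.
#' @return A sparse matrix of `TPM/10` values (`2^expr - 1`).
#' @export
delog_expr <- function(expr) {
  m <- .expr_of(expr)
  m@x <- 2^m@x - 1
  m
}
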