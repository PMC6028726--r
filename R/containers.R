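#' Gene-by-cell UMI count matrix with per-cell metadata
#'
#' Bundles a sparse, nonnegative integer gene-by-cell matrix of distinct-UMI
#' counts with the per-cell metadata the quality filters consume: a region
#' label, an embryo/sample identifier, the raw read count and the mapping
#' ratio. Rows are genes, columns are cells, both carried as dimnames.
#'
#' @param counts A genes-by-cells matrix (base or `Matrix` sparse) of
#'   nonnegative integers with row and column names.
#' @param meta Optional `data.frame` with one row per cell. Recognised
#'   columns: `region`, `embryo`, `raw_reads`, `mapping_ratio`. Missing
#'   columns are filled with `NA`; a `cell_id` column (or the row names) is
#'   matched against `colnames(counts)`.
#' @return An object of class `CountMatrix`: a list with elements `counts`
#'   (a `dgCMatrix`) and `meta` (a `data.frame` keyed by `cell_id`).
#' @examples
#' m <- matrix(c(1, 0, 2, 3, 0, 4), nrow = 3,
#'             dimnames = list(paste0("g", 1:3), paste0("c", 1:2)))
#' cm <- count_matrix(m)
#' dim(cm$counts)
#' @export
count_matrix <- function(counts, meta = NULL) {
  counts <- Matrix::Matrix(counts, sparse = TRUE)
  if (methods::is(counts, "nMatrix")) # pattern matrix, e.g. empty MTX
    counts <- methods::as(counts, "dMatrix")
  counts <- methods::as(methods::as(counts, "generalMatrix"),
                        "CsparseMatrix")
  if (is.null(rownames(counts)) && nrow(counts) > 0)
    stop("counts must have gene row names")
  if (is.null(colnames(counts)) && ncol(counts) > 0)
    stop("counts must have cell column names")
  if (any(counts@x < 0) || any(counts@x != round(counts@x)))
    stop("counts must be nonnegative integers")
  cells <- colnames(counts)
  if (is.null(cells)) cells <- character(0)
  n <- length(cells)
  full <- data.frame(cell_id = cells, region = rep(NA_character_, n),
                     embryo = rep(NA_character_, n),
                     raw_reads = rep(NA_real_, n),
                     mapping_ratio = rep(NA_real_, n),
                     stringsAsFactors = FALSE)
  if (!is.null(meta)) {
    meta <- as.data.frame(meta)
    ids <- if ("cell_id" %in% names(meta)) as.character(meta$cell_id)
           else rownames(meta)
    idx <- match(cells, ids)
    if (anyNA(idx) && length(cells) > 0)
      stop("meta is missing rows for some cells")
    for (col in c("region", "embryo", "raw_reads", "mapping_ratio"))
      if (col %in% names(meta)) full[[col]] <- meta[[col]][idx]
  }
  rownames(full) <- full$cell_id
  structure(list(counts = counts, meta = full), class = "CountMatrix")
}

#' @export
print.CountMatrix <- function(x, ...) {
  cat(sprintf("CountMatrix: %d genes x %d cells\n",
              nrow(x$counts), ncol(x$counts)))
  lg <- qc_log(x)
  if (!is.null(lg)) cat(sprintf("  QC removed %d cells\n", nrow(lg)))
  invisible(x)
}

#' @export
dim.CountMatrix <- function(x) dim(x$counts)

#' Normalized expression matrix
#'
#' Holds `log2(TPM/10 + 1)` expression with the same axes and per-cell
#' metadata as the [count_matrix()] it came from. Here TPM is the UMI count
#' scaled to a per-cell total of one million; there is no gene-length term
#' because UMI counts are molecule counts.
#'
#' @param expr Genes-by-cells numeric matrix of `log2(TPM/10 + 1)` values.
#' @param meta Per-cell metadata `data.frame` (see [count_matrix()]).
#' @return An object of class `ExprMatrix`.
#' @export
expr_matrix <- function(expr, meta = NULL) {
  expr <- methods::as(methods::as(Matrix::Matrix(expr, sparse = TRUE),
                                  "generalMatrix"), "CsparseMatrix")
  if (length(expr@x) && min(expr@x) < 0) stop("expression must be >= 0")
  cm <- count_matrix(Matrix::sparseMatrix(
    i = integer(0), j = integer(0), x = numeric(0),
    dims = dim(expr), dimnames = dimnames(expr)), meta)
  structure(list(expr = expr, meta = cm$meta), class = "ExprMatrix")
}

#' @export
print.ExprMatrix <- function(x, ...) {
  cat(sprintf("ExprMatrix (log2(TPM/10+1)): %d genes x %d cells\n",
              nrow(x$expr), ncol(x$expr)))
  invisible(x)
}

#' @export
dim.ExprMatrix <- function(x) dim(x$expr)

#' QC removal log of a filtered count matrix
#'
#' @param x A `CountMatrix` returned by [qc_filter_cells()].
#' @return A `data.frame` with columns `cell_id` and `reason`
#'   (comma-separated failed criteria), or `NULL` if `x` was never filtered.
#' @export
qc_log <- function(x) attr(x, "qc_log", exact = TRUE)

# Internal: accept an ExprMatrix or a plain matrix; return the dgCMatrix.
.expr_of <- function(x) {
  if (inherits(x, "ExprMatrix")) return(x$expr)
  methods::as(methods::as(Matrix::Matrix(x, sparse = TRUE),
                          "generalMatrix"), "CsparseMatrix")
}

# Internal: row means and variances of a sparse matrix without densifying.
.row_stats <- function(m) {
  n <- ncol(m)
  mu <- Matrix::rowMeans(m)
  if (n < 2) return(list(mean = mu, var = rep(NA_real_, nrow(m))))
  ex2 <- Matrix::rowSums(m^2)
  v <- (ex2 - n * mu^2) / (n - 1)
  # clamp floating-point residue so constant genes report exactly zero
  v[v < 1e-10 * (ex2 / n + 1e-300)] <- 0
  list(mean = mu, var = v)
}
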