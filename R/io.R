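#' Write a count matrix (and optional ground truth) as a plain-text fixture
#'
#' Writes the standard sparse exchange layout: `matrix.mtx` (Matrix Market
#' triplets), `genes.tsv` and `barcodes.tsv` (one name per line),
#' `metadata.tsv` (columns `cell_id`, `region`, `embryo`, `raw_reads`,
#' `mapping_ratio`) and, when truth is supplied, `truth.json`.
#'
#' @param counts A [count_matrix()].
#' @param dir Output directory (created if absent).
#' @param truth Optional truth list from [simulate_counts()].
#' @return Invisibly, the vector of files written.
#' @seealso [read_fixture()]
#' @export
write_fixture <- function(counts, dir, truth = NULL) {
  stopifnot(inherits(counts, "CountMatrix"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("matrix.mtx", "genes.tsv", "barcodes.tsv",
                            "metadata.tsv"))
  Matrix::writeMM(counts$counts, paths[1])
  chr0 <- function(x) if (is.null(x)) character(0) else x
  writeLines(chr0(rownames(counts$counts)), paths[2])
  writeLines(chr0(colnames(counts$counts)), paths[3])
  utils::write.table(counts$meta, paths[4], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(truth)) {
    tp <- file.path(dir, "truth.json")
    jsonlite::write_json(truth, tp, auto_unbox = FALSE, digits = NA)
    paths <- c(paths, tp)
  }
  invisible(paths)
}

#' Read a count-matrix fixture written by [write_fixture()]
#'
#' @param dir Directory holding `matrix.mtx`, `genes.tsv`, `barcodes.tsv`
#'   and optionally `metadata.tsv` and `truth.json`.
#' @return A list with `counts` (a [count_matrix()]) and `truth` (a list, or
#'   `NULL` when no `truth.json` is present).
#' @export
read_fixture <- function(dir) {
  m <- Matrix::readMM(file.path(dir, "matrix.mtx"))
  genes <- if (nrow(m) > 0) readLines(file.path(dir, "genes.tsv"))
           else character(0)
  cells <- if (ncol(m) > 0) readLines(file.path(dir, "barcodes.tsv"))
           else character(0)
  dimnames(m) <- list(genes, cells)
  meta <- NULL
  mp <- file.path(dir, "metadata.tsv")
  if (file.exists(mp) && ncol(m) > 0)
    meta <- utils::read.table(mp, sep = "\t", header = TRUE,
                              stringsAsFactors = FALSE,
                              colClasses = c(cell_id = "character"))
  truth <- NULL
  tp <- file.path(dir, "truth.json")
  if (file.exists(tp)) {
    truth <- jsonlite::read_json(tp, simplifyVector = TRUE)
    if (!is.null(truth$true_label))
      truth$true_label <- unlist(truth$true_label)
  }
  list(counts = count_matrix(m, meta), truth = truth)
}

#' Read UMI-tagged reads from a TSV file
#'
#' Expects three columns, `barcode`, `umi`, `gene`, with a header line.
#'
#' @param path File path.
#' @return A `data.frame` of reads suitable for [demultiplex_count()].
#' @export
read_tagged_reads <- function(path) {
  rd <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, colClasses = "character")
  need <- c("barcode", "umi", "gene")
  if (!all(need %in% names(rd)))
    stop("tagged-read file must have columns barcode, umi, gene")
  rd[need]
}

#' Write UMI-tagged reads to a TSV file
#'
#' @param reads A `data.frame` with columns `barcode`, `umi`, `gene`.
#' @param path Output file path.
#' @export
write_tagged_reads <- function(reads, path) {
  utils::write.table(reads[c("barcode", "umi", "gene")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene sets from a GMT file
#'
#' GMT is the tab-delimited gene-set format: one set per line, first field
#' the set name, second a free-text description, remaining fields the member
#' genes. Duplicate members within a set are dropped.
#'
#' @param path GMT file path.
#' @return A named list of character vectors of gene identifiers.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  sets <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3) stop("malformed GMT line: ", substr(l, 1, 40))
    unique(f[-(1:2)][nzchar(f[-(1:2)])])
  })
  names(sets) <- vapply(lines, function(l)
    strsplit(l, "\t", fixed = TRUE)[[1]][1], character(1))
  sets
}

#' Write gene sets to a GMT file
#'
#' @param sets Named list of character vectors.
#' @param path Output file path.
#' @param description Description field written for every set.
#' @export
write_gmt <- function(sets, path, description = "na") {
  stopifnot(!is.null(names(sets)), all(nzchar(names(sets))))
  lines <- vapply(names(sets), function(nm)
    paste(c(nm, description, sets[[nm]]), collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}
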