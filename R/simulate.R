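#' Configuration for the synthetic scRNA-seq generator
#'
#' Describes the statistical structure the generator plants: `n_clusters`
#' cell populations of `cells_per_cluster` cells each, negative-binomial
#' gene counts with per-cell library-size factors, per-cluster marker genes
#' whose mean is multiplied by `marker_fold`, optional extra-dispersed
#' variable genes, region labels imposed through per-region cluster mixing
#' proportions, UMI duplicate reads, and a fraction of low-quality cells
#' constructed to fail the quality filters (library size below 20,000
#' distinct UMIs and/or mapping ratio below 0.2).
#'
#' @param n_clusters Number of planted cell clusters (K).
#' @param cells_per_cluster Cells drawn per cluster.
#' @param n_genes Number of genes.
#' @param n_markers_per_cluster Marker genes planted per cluster (disjoint
#'   across clusters).
#' @param marker_fold Mean multiplier (> 1 plants structure; 1 = none) for a
#'   cluster's markers in its own cells, linear scale.
#' @param nb_dispersion Negative-binomial dispersion phi, with
#'   `variance = mu + mu^2 * phi`. Small values (~0.01) are Poisson-like.
#' @param mean_library_size Expected total distinct UMIs per good cell.
#' @param lib_sdlog Log-normal sdlog of the per-cell library-size factors.
#' @param regions Named list of per-region cluster mixing proportions, each a
#'   numeric vector of length `n_clusters` summing to 1. A cell of cluster k
#'   is assigned region r with probability proportional to `regions[[r]][k]`.
#'   Default: a single region `"R1"`.
#' @param frac_low_quality Fraction of cells planted as low quality.
#' @param umi_dup_rate Probability that a molecule is re-read; each read is
#'   duplicated again with the same probability (geometric copies).
#' @param umi_length UMI length in bases over {A,C,G,T}.
#' @param n_hvg Number of planted highly variable (extra-dispersed) genes,
#'   disjoint from markers.
#' @param hvg_var_fold Count-variance inflation factor for planted variable
#'   genes, relative to the baseline negative-binomial variance at the
#'   gene's mean.
#' @param seed Integer seed; identical configurations are bit-reproducible.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_clusters = 3, cells_per_cluster = 100,
                       n_genes = 2000, n_markers_per_cluster = 20,
                       marker_fold = 8, nb_dispersion = 0.5,
                       mean_library_size = 1e5, lib_sdlog = 0.25,
                       regions = NULL, frac_low_quality = 0,
                       umi_dup_rate = 0, umi_length = 8,
                       n_hvg = 0, hvg_var_fold = 10, seed = 1) {
  stopifnot(n_clusters >= 1, cells_per_cluster >= 1, n_genes >= 1,
            n_markers_per_cluster >= 0, marker_fold >= 1, nb_dispersion > 0,
            mean_library_size >= 1, lib_sdlog >= 0,
            frac_low_quality >= 0, frac_low_quality <= 1,
            umi_dup_rate >= 0, umi_dup_rate < 1, umi_length >= 1,
            n_hvg >= 0, hvg_var_fold >= 1)
  if (n_markers_per_cluster * n_clusters + n_hvg > n_genes)
    stop("marker overcommit")
  if (is.null(regions)) regions <- list(R1 = rep(1 / n_clusters, n_clusters))
  if (is.null(names(regions)) || any(!nzchar(names(regions))))
    stop("regions must be a named list")
  for (r in names(regions)) {
    p <- regions[[r]]
    if (length(p) != n_clusters || any(p < 0) ||
        abs(sum(p) - 1) > 1e-8)
      stop("region mixing proportions must be length n_clusters and sum to 1")
  }
  structure(list(n_clusters = n_clusters,
                 cells_per_cluster = cells_per_cluster, n_genes = n_genes,
                 n_markers_per_cluster = n_markers_per_cluster,
                 marker_fold = marker_fold, nb_dispersion = nb_dispersion,
                 mean_library_size = mean_library_size, lib_sdlog = lib_sdlog,
                 regions = regions, frac_low_quality = frac_low_quality,
                 umi_dup_rate = umi_dup_rate, umi_length = umi_length,
                 n_hvg = n_hvg, hvg_var_fold = hvg_var_fold,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate a ground-truthed UMI count matrix
#'
#' Draws gene counts from a negative binomial with per-cell library-size
#' factors (log-normal around `mean_library_size`) and gamma-distributed
#' relative gene abundances. Marker genes of a cell's own cluster have their
#' mean multiplied by `marker_fold` before the cell's expected total is
#' rescaled to its library size, so library sizes stay comparable across
#' clusters. Planted variable genes get a per-gene dispersion chosen so
#' their count variance at the gene's mean is `hvg_var_fold` times the
#' baseline. Low-quality cells are planted by shrinking the library size
#' below 20,000 UMIs and/or drawing a mapping ratio below 0.2, so both
#' printed QC criteria are exercised.
#'
#' @param config A [sim_config()].
#' @return A list with elements:
#'   \describe{
#'     \item{counts}{A [count_matrix()] with populated metadata (`region`,
#'       `embryo = "sim"`, `raw_reads`, `mapping_ratio`).}
#'     \item{truth}{A list with `true_label` (named by cell),
#'       `planted_markers` (cluster -> gene list), `planted_hvgs`,
#'       and `low_quality_cells`.}
#'   }
#' @export
simulate_counts <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  K <- config$n_clusters
  n <- K * config$cells_per_cluster
  G <- config$n_genes
  genes <- sprintf("gene_%0*d", nchar(G), seq_len(G))
  cells <- sprintf("cell_%0*d", nchar(n), seq_len(n))
  clusters <- sprintf("C%d", seq_len(K))
  label <- rep(clusters, each = config$cells_per_cluster)
  names(label) <- cells

  # relative gene abundances; markers drawn among better-expressed genes so
  # a planted marker is detectable at realistic depth
  w <- stats::rgamma(G, shape = 2, rate = 1)
  w <- w / sum(w)
  nm <- config$n_markers_per_cluster
  eligible <- which(w >= stats::median(w))
  need <- nm * K + config$n_hvg
  if (length(eligible) < need) eligible <- seq_len(G)
  special <- sample(eligible, need)
  planted_markers <- list()
  if (nm > 0) {
    mk <- special[seq_len(nm * K)]
    planted_markers <- split(genes[mk], rep(clusters, each = nm))
    marker_idx <- split(mk, rep(seq_len(K), each = nm))
  } else {
    marker_idx <- rep(list(integer(0)), K)
  }
  hvg_idx <- if (config$n_hvg > 0) special[nm * K + seq_len(config$n_hvg)]
             else integer(0)

  # library sizes; planted low-quality cells fail one or both QC criteria
  lib <- stats::rlnorm(n, log(config$mean_library_size) -
                            config$lib_sdlog^2 / 2, config$lib_sdlog)
  map_ratio <- stats::runif(n, 0.4, 0.9)
  n_low <- round(config$frac_low_quality * n)
  low_cells <- character(0)
  if (n_low > 0) {
    low <- sample(n, n_low)
    mode <- sample(c("lib", "ratio", "both"), n_low, replace = TRUE)
    lib[low[mode != "ratio"]] <-
      stats::runif(sum(mode != "ratio"), 2000, 12000)
    map_ratio[low[mode != "lib"]] <-
      stats::runif(sum(mode != "lib"), 0.05, 0.18)
    low_cells <- sort(cells[low])
  }

  # per-gene dispersion; planted variable genes inflated to hvg_var_fold x
  # the baseline count variance at the gene's library-averaged mean
  phi <- rep(config$nb_dispersion, G)
  if (length(hvg_idx)) {
    mbar <- w[hvg_idx] * mean(lib)
    base_var <- mbar + mbar^2 * config$nb_dispersion
    phi[hvg_idx] <- pmax((config$hvg_var_fold * base_var - mbar) / mbar^2,
                         config$nb_dispersion)
  }

  counts <- matrix(0L, G, n, dimnames = list(genes, cells))
  for (k in seq_len(K)) {
    idx <- which(label == clusters[k])
    mw <- w
    mw[marker_idx[[k]]] <- mw[marker_idx[[k]]] * config$marker_fold
    mw <- mw / sum(mw)
    mu <- outer(mw, lib[idx])
    counts[, idx] <- stats::rnbinom(G * length(idx), mu = mu,
                                    size = 1 / rep(phi, length(idx)))
  }

  tot <- colSums(counts)
  region <- vapply(seq_len(n), function(i) {
    k <- match(label[i], clusters)
    p <- vapply(config$regions, function(x) x[k], numeric(1))
    if (sum(p) == 0) names(config$regions)[1]
    else sample(names(config$regions), 1, prob = p)
  }, character(1))
  meta <- data.frame(cell_id = cells, region = region, embryo = "sim",
                     raw_reads = round(tot * (1 + config$umi_dup_rate) /
                                         map_ratio),
                     mapping_ratio = map_ratio, stringsAsFactors = FALSE)
  list(counts = count_matrix(counts, meta),
       truth = list(true_label = label,
                    planted_markers = planted_markers,
                    planted_hvgs = genes[sort(hvg_idx)],
                    low_quality_cells = low_cells))
}

#' Expand a count matrix into a stream of UMI-tagged reads
#'
#' For every (gene, cell) entry with count c, emits c molecules, each with a
#' random UMI of `umi_length` bases; UMI collisions are allowed to occur
#' naturally. Each read is then re-emitted as a duplicate with probability
#' `umi_dup_rate`, repeatedly (geometric number of copies), so deduplication
#' is exercised realistically.
#'
#' @param counts A [count_matrix()] (typically from [simulate_counts()]).
#' @param config The [sim_config()] supplying `umi_dup_rate`, `umi_length`
#'   and `seed`. The read stream is seeded by `seed + 1` so it is
#'   reproducible independently of the count draw.
#' @return A `data.frame` with columns `barcode`, `umi`, `gene`, one row per
#'   read.
#' @export
simulate_tagged_reads <- function(counts, config) {
  stopifnot(inherits(counts, "CountMatrix"), inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  m <- methods::as(counts$counts, "TsparseMatrix")
  if (length(m@x) == 0)
    return(data.frame(barcode = character(0), umi = character(0),
                      gene = character(0), stringsAsFactors = FALSE))
  cnt <- as.integer(m@x)
  gene <- rep(rownames(m)[m@i + 1L], cnt)
  barcode <- rep(colnames(m)[m@j + 1L], cnt)
  n_mol <- length(gene)
  umi <- do.call(paste0, as.data.frame(
    matrix(sample(c("A", "C", "G", "T"), n_mol * config$umi_length,
                  replace = TRUE), nrow = n_mol),
    stringsAsFactors = FALSE))
  copies <- 1L + stats::rgeom(n_mol, prob = 1 - config$umi_dup_rate)
  idx <- rep(seq_len(n_mol), copies)
  data.frame(barcode = barcode[idx], umi = umi[idx], gene = gene[idx],
             stringsAsFactors = FALSE)
}
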