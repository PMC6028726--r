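# Shared planted dataset: 3 clusters x 60 cells, strong markers, two regions
# with different cluster composition. Built once per test run.
fix_sim <- local({
  cfg <- sim_config(n_clusters = 3, cells_per_cluster = 60, n_genes = 800,
                    marker_fold = 8, seed = 101,
                    regions = list(A = c(0.6, 0.2, 0.2),
                                   B = c(0.2, 0.4, 0.4)))
  sim <- simulate_counts(cfg)
  sim$config <- cfg
  sim$expr <- normalize_log_tpm(sim$counts)
  sim$labels <- stats::setNames(sim$truth$true_label,
                                names(sim$truth$true_label))
  sim
})

# Independent oracle: distinct-(barcode, gene, umi) tuples tabulated by hand.
brute_force_counts <- function(reads) {
  tup <- unique(reads[c("barcode", "gene", "umi")])
  tab <- table(factor(tup$gene), factor(tup$barcode))
  m <- matrix(as.numeric(tab), nrow(tab), ncol(tab),
              dimnames = list(rownames(tab), colnames(tab)))
  m[order(rownames(m)), order(colnames(m)), drop = FALSE]
}

# Independent oracle: AUC by enumeration of all pairs.
brute_force_auc <- function(x, y) {
  s <- 0
  for (xi in x) s <- s + sum(xi > y) + 0.5 * sum(xi == y)
  s / (length(x) * length(y))
}

# Small deterministic read stream for dedup tests.
make_reads <- function(n, n_bc = 5, n_gene = 8, n_umi = 20, seed = 1) {
  set.seed(seed)
  data.frame(barcode = sample(sprintf("bc%02d", seq_len(n_bc)), n, TRUE),
             umi = sample(sprintf("u%03d", seq_len(n_umi)), n, TRUE),
             gene = sample(sprintf("g%02d", seq_len(n_gene)), n, TRUE),
             stringsAsFactors = FALSE)
}

# Expression matrix with exact per-gene values replicated over cells.
expr_from_values <- function(values, n_cells, gene_names = NULL) {
  m <- matrix(rep(values, n_cells), length(values), n_cells)
  rownames(m) <- if (is.null(gene_names))
    sprintf("g%03d", seq_along(values)) else gene_names
  colnames(m) <- sprintf("c%03d", seq_len(n_cells))
  m
}
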