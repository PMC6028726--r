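fast_params <- function(seed = 1, ...) {
  cluster_params(reps = 4, ntree = 50, seed = seed, ...)
}

test_that("bisection splits planted populations along the truth", {
  cells <- names(fix_sim$labels)[fix_sim$labels %in% c("C1", "C2")]
  bi <- bisect_cells(fix_sim$expr, cells)
  lab_left <- unique(fix_sim$labels[bi$left])
  lab_right <- unique(fix_sim$labels[bi$right])
  expect_length(lab_left, 1)
  expect_length(lab_right, 1)
  expect_setequal(c(lab_left, lab_right), c("C1", "C2"))
  # two cells split into singletons
  two <- bisect_cells(fix_sim$expr, cells[1:2])
  expect_length(two$left, 1)
  expect_length(two$right, 1)
  expect_error(bisect_cells(fix_sim$expr, cells[1]), "no-split")
})

test_that("duplicated cells are co-assigned at zero distance", {
  set.seed(3)
  base <- matrix(rnorm(50 * 15, 5), 50, 15,
                 dimnames = list(sprintf("g%02d", 1:50),
                                 sprintf("a%02d", 1:15)))
  dup <- base
  colnames(dup) <- sub("a", "b", colnames(dup))
  m <- cbind(base, dup)
  bi <- bisect_cells(m, hvgs = rownames(m))
  for (i in 1:15) {
    pair <- c(sprintf("a%02d", i), sprintf("b%02d", i))
    expect_true(all(pair %in% bi$left) || all(pair %in% bi$right))
  }
})

test_that("refinement votes are near-unanimous for separated groups", {
  # disjoint marker support: group A expresses the first gene block only,
  # group B the second; votes must be essentially unanimous
  set.seed(44)
  m <- matrix(abs(rnorm(60 * 60, sd = 0.1)), 60, 60,
              dimnames = list(sprintf("g%02d", 1:60),
                              sprintf("c%02d", 1:60)))
  m[1:30, 1:30] <- m[1:30, 1:30] + 5
  m[31:60, 31:60] <- m[31:60, 31:60] + 5
  left <- colnames(m)[1:30]
  right <- colnames(m)[31:60]
  sr <- rf_refine(m, left, right, fast_params(seed = 5),
                  features = rownames(m))
  expect_identical(sr$status, "ok")
  expect_gte(min(sr$vote_prob), 0.9)
  expect_length(sr$abandoned, 0)
  expect_setequal(sr$left, left)
  expect_setequal(sr$right, right)
  # the planted fixture separates nearly as cleanly on average
  cells <- names(fix_sim$labels)[fix_sim$labels %in% c("C1", "C2")]
  sr2 <- rf_refine(fix_sim$expr,
                   cells[fix_sim$labels[cells] == "C1"],
                   cells[fix_sim$labels[cells] == "C2"],
                   fast_params(seed = 5))
  expect_identical(sr2$status, "ok")
  expect_gte(mean(sr2$vote_prob), 0.9)
})

test_that("refinement repairs or abandons mislabelled cells", {
  cells <- names(fix_sim$labels)[fix_sim$labels %in% c("C1", "C2")]
  left <- sort(cells[fix_sim$labels[cells] == "C1"])
  right <- sort(cells[fix_sim$labels[cells] == "C2"])
  set.seed(77)
  flip_l <- sample(left, 3)
  flip_r <- sample(right, 3)
  sr <- rf_refine(fix_sim$expr, c(setdiff(left, flip_l), flip_r),
                  c(setdiff(right, flip_r), flip_l), fast_params(seed = 6))
  expect_identical(sr$status, "ok")
  flipped <- c(flip_l, flip_r)
  fixed <- c(intersect(flip_l, sr$left), intersect(flip_r, sr$right),
             intersect(flipped, sr$abandoned))
  expect_gte(length(unique(fixed)) / length(flipped), 0.9)
})

test_that("refinement of an arbitrary split of one population is uncertain", {
  cfg <- sim_config(n_clusters = 1, cells_per_cluster = 80, n_genes = 500,
                    marker_fold = 1, mean_library_size = 4e4, seed = 17)
  expr <- normalize_log_tpm(simulate_counts(cfg)$counts)
  cells <- sort(colnames(expr$expr))
  sr <- rf_refine(expr, cells[1:40], cells[41:80], fast_params(seed = 7))
  uncertain <- sr$status != "ok" ||
    mean(sr$vote_prob) < 0.8 ||
    length(sr$abandoned) > 8
  expect_true(uncertain)
})

test_that("homogeneous data stays a single leaf", {
  cfg <- sim_config(n_clusters = 1, cells_per_cluster = 90, n_genes = 500,
                    marker_fold = 1, mean_library_size = 4e4, seed = 23)
  expr <- normalize_log_tpm(simulate_counts(cfg)$counts)
  tree <- recursive_cluster(expr, params = fast_params(seed = 2))
  expect_length(tree$leaves, 1)
  expect_match(tree$root$stop_reason, "min-size|too-few-DEGs|unstable|degenerate")
})

test_that("planted sub-clusters are recovered and partition the cells", {
  tree <- recursive_cluster(fix_sim$expr, params = fast_params(seed = 3))
  expect_length(tree$leaves, 3)
  a <- cluster_assignments(tree)
  ok <- !is.na(a$cluster)
  ari <- mclust::adjustedRandIndex(a$cluster[ok],
                                   fix_sim$labels[a$cell_id[ok]])
  expect_gte(ari, 0.9)
  # leaves plus abandoned cells partition the input exactly
  expect_identical(sort(c(unlist(tree$leaves, use.names = FALSE),
                          tree$abandoned)), tree$cells)
  expect_identical(anyDuplicated(unlist(tree$leaves)), 0L)
  # assignments table is consistent with the tree
  expect_identical(sum(a$abandoned), length(tree$abandoned))
  expect_true(all(a$vote_prob[ok & !a$abandoned] >= 0.55 |
                    is.na(a$vote_prob[ok])))
})

test_that("clustering is deterministic and invariant to cell order", {
  p <- fast_params(seed = 9)
  t1 <- recursive_cluster(fix_sim$expr, params = p)
  t2 <- recursive_cluster(fix_sim$expr, params = p)
  expect_identical(t1$leaves, t2$leaves)
  expect_identical(t1$abandoned, t2$abandoned)
  set.seed(4)
  perm <- sample(ncol(fix_sim$expr$expr))
  t3 <- recursive_cluster(fix_sim$expr$expr[, perm], params = p)
  expect_identical(lapply(t1$leaves, sort), lapply(t3$leaves, sort))
})

test_that("recovery does not improve as marker separation weakens", {
  med_ari <- sapply(c(8, 2), function(fold) {
    median(sapply(1:3, function(s) {
      cfg <- sim_config(n_clusters = 2, cells_per_cluster = 50,
                        n_genes = 500, marker_fold = fold,
                        mean_library_size = 3e4, seed = 80 + s)
      sim <- simulate_counts(cfg)
      expr <- normalize_log_tpm(sim$counts)
      tree <- recursive_cluster(expr, params = fast_params(seed = s))
      a <- cluster_assignments(tree)
      ok <- !is.na(a$cluster)
      if (length(tree$leaves) < 2) return(0)
      mclust::adjustedRandIndex(a$cluster[ok],
                                sim$truth$true_label[a$cell_id[ok]])
    }))
  })
  expect_gte(med_ari[1], med_ari[2] - 0.1)
})
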