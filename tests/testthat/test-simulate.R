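test_that("generator is bit-reproducible for an identical configuration", {
  cfg <- sim_config(n_clusters = 2, cells_per_cluster = 30, n_genes = 200,
                    mean_library_size = 5000, umi_dup_rate = 0.3, seed = 7)
  a <- simulate_counts(cfg)
  b <- simulate_counts(cfg)
  expect_identical(as.matrix(a$counts$counts), as.matrix(b$counts$counts))
  expect_identical(a$counts$meta, b$counts$meta)
  expect_identical(a$truth, b$truth)
  expect_identical(simulate_tagged_reads(a$counts, cfg),
                   simulate_tagged_reads(b$counts, cfg))
})

test_that("overcommitted marker budget is rejected", {
  expect_error(sim_config(n_clusters = 5, n_genes = 50,
                          n_markers_per_cluster = 20), "marker overcommit")
})

test_that("planted markers separate their cluster in the generated counts", {
  cnt <- as.matrix(fix_sim$counts$counts)
  lab <- fix_sim$truth$true_label[colnames(cnt)]
  for (cl in names(fix_sim$truth$planted_markers)) {
    for (g in fix_sim$truth$planted_markers[[cl]]) {
      m_in <- mean(cnt[g, lab == cl])
      m_out <- mean(cnt[g, lab != cl])
      expect_gte(m_in, 4 * m_out)
    }
  }
})

test_that("single-cluster unit-fold configuration plants no structure", {
  cfg <- sim_config(n_clusters = 1, cells_per_cluster = 40, n_genes = 150,
                    marker_fold = 1, mean_library_size = 5000, seed = 3)
  sim <- simulate_counts(cfg)
  expect_true(all(sim$truth$true_label == "C1"))
  expect_length(sim$truth$low_quality_cells, 0)
  # "marker" genes get no mean boost at fold 1: their pooled mean matches a
  # random gene panel of the same size within sampling noise
  cnt <- as.matrix(sim$counts$counts)
  mk <- sim$truth$planted_markers$C1
  expect_lt(mean(cnt[mk, ]) / mean(cnt), 3)
})

test_that("library sizes track the configured mean within 10 percent", {
  cfg <- sim_config(n_clusters = 1, cells_per_cluster = 250, n_genes = 400,
                    mean_library_size = 30000, seed = 11)
  sim <- simulate_counts(cfg)
  tot <- Matrix::colSums(sim$counts$counts)
  expect_lt(abs(mean(tot) - 30000) / 30000, 0.1)
})

test_that("planted low-quality cells sit below the QC thresholds", {
  cfg <- sim_config(n_clusters = 3, cells_per_cluster = 100, n_genes = 600,
                    frac_low_quality = 0.1, mean_library_size = 60000,
                    seed = 13)
  sim <- simulate_counts(cfg)
  low <- sim$truth$low_quality_cells
  expect_length(low, 30)
  tot <- Matrix::colSums(sim$counts$counts)
  ratio <- sim$counts$meta$mapping_ratio
  names(ratio) <- sim$counts$meta$cell_id
  expect_true(all(tot[low] < 20000 | ratio[low] < 0.2))
  good <- setdiff(names(tot), low)
  expect_true(all(tot[good] >= 20000 & ratio[good] >= 0.2))
})

test_that("tagged-read stream matches the molecule table", {
  # all-zero matrix -> empty stream
  cfg0 <- sim_config(n_clusters = 1, cells_per_cluster = 2, n_genes = 5,
                     n_markers_per_cluster = 0, seed = 1)
  zero <- count_matrix(matrix(0L, 5, 2, dimnames = list(
    paste0("g", 1:5), paste0("c", 1:2))))
  expect_identical(nrow(simulate_tagged_reads(zero, cfg0)), 0L)
  # single cell, single gene, count 5, no duplication -> 5 distinct reads
  one <- count_matrix(matrix(5L, 1, 1, dimnames = list("g1", "c1")))
  cfg1 <- sim_config(n_clusters = 1, cells_per_cluster = 1, n_genes = 1,
                     n_markers_per_cluster = 0, umi_dup_rate = 0, seed = 5)
  rd <- simulate_tagged_reads(one, cfg1)
  expect_identical(nrow(rd), 5L)
  expect_identical(length(unique(rd$umi)), 5L)
  # duplicated stream: distinct UMIs per (cell, gene) equal the molecule
  # count, collisions aside (8-base UMIs make them rare)
  cfg <- sim_config(n_clusters = 1, cells_per_cluster = 20, n_genes = 60,
                    mean_library_size = 400, umi_dup_rate = 0.5, seed = 9)
  sim <- simulate_counts(cfg)
  reads <- simulate_tagged_reads(sim$counts, cfg)
  expect_gt(nrow(reads), sum(sim$counts$counts))
  dedup <- as.matrix(demultiplex_count(reads)$counts)
  truth <- as.matrix(sim$counts$counts)[rownames(dedup), colnames(dedup)]
  expect_true(all(dedup <= truth))
  expect_gte(mean(dedup == truth), 0.999)
})

test_that("fixtures round-trip losslessly through the readers", {
  dir <- withr::local_tempdir()
  write_fixture(fix_sim$counts, dir, truth = fix_sim$truth)
  back <- read_fixture(dir)
  expect_identical(as.matrix(back$counts$counts),
                   as.matrix(fix_sim$counts$counts))
  expect_identical(back$counts$meta$region, fix_sim$counts$meta$region)
  expect_equal(back$counts$meta$mapping_ratio,
               fix_sim$counts$meta$mapping_ratio, tolerance = 1e-12)
  expect_identical(sort(unlist(back$truth$planted_markers)),
                   sort(unlist(fix_sim$truth$planted_markers)))
  # degenerate 0-cell matrix still round-trips
  dir0 <- withr::local_tempdir()
  empty <- count_matrix(matrix(0L, 3, 0, dimnames = list(
    paste0("g", 1:3), character(0))))
  write_fixture(empty, dir0)
  expect_identical(dim(read_fixture(dir0)$counts$counts), c(3L, 0L))
})

test_that("toy matrix writes the hand-counted number of sparse entries", {
  dir <- withr::local_tempdir()
  toy <- count_matrix(matrix(c(1L, 0L, 2L, 3L, 0L, 4L), nrow = 3,
                             dimnames = list(paste0("g", 1:3),
                                             paste0("c", 1:2))))
  write_fixture(toy, dir)
  lines <- readLines(file.path(dir, "matrix.mtx"))
  body <- lines[!startsWith(lines, "%")]
  expect_identical(length(body) - 1L, 4L) # dims line + 4 nonzeros
})
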