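test_that("cycle scores are set means and missing genes are handled", {
  m <- rbind(a = c(3, 0), b = c(1, 0), c = c(5, 2))
  colnames(m) <- c("c1", "c2")
  sc <- cellcycle_scores(m, g1s = c("a", "b"), g2m = c("c"))
  expect_equal(sc$g1s_score, c(2, 0))
  expect_equal(sc$g2m_score, c(5, 2))
  # absent set genes are dropped with a warning, mean over the rest
  expect_warning(sc2 <- cellcycle_scores(m, g1s = c("a", "b", "zz"),
                                         g2m = "c"), "absent")
  expect_equal(sc2$g1s_score, c(2, 0))
  expect_error(cellcycle_scores(m, g1s = c("nope"), g2m = "c"),
               "no G1/S set gene")
})

test_that("phase rules separate quiescent and proliferative cells", {
  expect_identical(classify_phase(1.5, 1.9), "quiescent")
  expect_identical(classify_phase(2.5, 3.0), "G2/M")
  expect_identical(classify_phase(3.0, 2.5), "G1/S")
  expect_identical(classify_phase(2.0, 2.0), "G1/S") # documented tie-break
  expect_identical(classify_phase(2.0, 2.0, tie = "G2/M"), "G2/M")
  expect_identical(classify_phase(0, 2.0), "G2/M") # one score at threshold
})

test_that("interneuron tallies use strict positivity and shared counting", {
  m <- rbind(LHX6 = c(1.0, 2, 2, 0, 2, 0, 0),
             CALB2 = c(0.5, 0, 2, 2, 2, 0, 0))
  colnames(m) <- paste0("c", 1:7)
  reg <- setNames(rep("R1", 7), colnames(m))
  tab <- interneuron_region_ratio(m, colnames(m), reg, min_sum = 2)
  # c1 is exactly at 1.0 for LHX6: not positive; c3/c5 count in both tallies
  expect_equal(tab$n_a, 3)
  expect_equal(tab$n_b, 3)
  expect_equal(tab$ratio, 0.5)
  # 10 vs 5 gives the textbook 2/3 ratio
  m2 <- rbind(LHX6 = c(rep(2, 10), rep(0, 5)),
              CALB2 = c(rep(0, 10), rep(2, 5)))
  colnames(m2) <- paste0("c", 1:15)
  tab2 <- interneuron_region_ratio(m2, colnames(m2),
                                   rep("R1", 15))
  expect_equal(tab2$ratio, 2 / 3, tolerance = 1e-12)
  # no positives of either type: undefined ratio, insufficient region
  m3 <- rbind(LHX6 = rep(0, 4), CALB2 = rep(0, 4))
  colnames(m3) <- paste0("c", 1:4)
  tab3 <- interneuron_region_ratio(m3, colnames(m3), rep("R1", 4))
  expect_true(is.na(tab3$ratio))
  expect_identical(tab3$dominance, "insufficient")
})

test_that("dominance thresholds are strict with boundaries balanced", {
  expect_identical(classify_region_dominance(10, 4, 10 / 14), "insufficient")
  expect_identical(classify_region_dominance(61, 39, 0.61), "LHX6")
  expect_identical(classify_region_dominance(60, 40, 0.60), "balanced")
  expect_identical(classify_region_dominance(40, 60, 0.40), "balanced")
  expect_identical(classify_region_dominance(39, 61, 0.39), "CALB2")
})

test_that("maturity ratio excludes small regions and counts true expression", {
  n <- 60 + 49
  m <- rbind(CUX2 = c(rep(3, 15), rep(0, 45), rep(3, 49)))
  colnames(m) <- paste0("c", seq_len(n))
  reg <- c(rep("big", 60), rep("small", 49))
  tab <- cux2_maturity_ratio(m, colnames(m), reg)
  big <- tab[tab$region == "big", ]
  small <- tab[tab$region == "small", ]
  expect_equal(big$ratio, 0.25)
  expect_false(big$excluded)
  expect_true(small$excluded)
  expect_true(is.na(small$ratio))
  # all-zero marker gives ratio 0, not NA
  m0 <- m; m0["CUX2", 1:60] <- 0
  expect_equal(cux2_maturity_ratio(m0, colnames(m0), reg)$ratio[1], 0)
})

test_that("synapse score averages per-cell means per region", {
  m <- rbind(s1 = c(1, 3, 0), s2 = c(1, 3, 0), other = c(9, 9, 9))
  colnames(m) <- paste0("c", 1:3)
  reg <- c("R1", "R1", "R2")
  tab <- synapse_maturity_score(m, colnames(m), reg,
                                gene_set = c("s1", "s2"), min_n = 2)
  expect_equal(tab$score[tab$region == "R1"], 2) # mean of per-cell means 1, 3
  expect_true(tab$excluded[tab$region == "R2"])
  expect_error(synapse_maturity_score(m, colnames(m), reg,
                                      gene_set = "none", min_n = 1),
               "no synapse set gene")
})

test_that("enrichment score matches the hand-enumerated recovery curve", {
  # ranking: g1 (10) > x (9) > g2 (8) > the rest; top 5 of 10 ranks
  vals <- c(g1 = 10, x = 9, g2 = 8, d = 7, e = 6, f = 5, g = 4, h = 3,
            i = 2, j = 1)
  m <- matrix(vals, ncol = 1, dimnames = list(names(vals), "c1"))
  sc <- geneset_enrichment_auc(m, c("g1", "g2"), top_frac = 0.5)
  # curve 1,1,2,2,2 -> area 8; best achievable 1,2,2,2,2 -> 9
  expect_equal(unname(sc), 8 / 9, tolerance = 1e-12)
  # set at the very top scores exactly 1
  sc1 <- geneset_enrichment_auc(m, c("g1", "x"), top_frac = 0.5)
  expect_equal(unname(sc1), 1)
  # zero-expressed set among many positives scores near zero
  sc0 <- geneset_enrichment_auc(m, c("i", "j"), top_frac = 0.3)
  expect_lte(unname(sc0), 0.2)
  # a set larger than the examined window warns but stays in [0, 1]
  expect_warning(scw <- geneset_enrichment_auc(m, names(vals)[1:8],
                                               top_frac = 0.2), "larger")
  expect_lte(max(scw), 1)
})

test_that("raising a set gene never lowers the enrichment score", {
  set.seed(12)
  m <- matrix(rexp(60), 20, 3,
              dimnames = list(sprintf("g%02d", 1:20), paste0("c", 1:3)))
  set <- c("g03", "g11", "g17")
  base <- geneset_enrichment_auc(m, set, top_frac = 0.3, seed = 2)
  for (g in set) {
    m2 <- m
    m2[g, ] <- m2[g, ] + 1.5
    bumped <- geneset_enrichment_auc(m2, set, top_frac = 0.3, seed = 2)
    expect_true(all(bumped >= base - 1e-12))
  }
})

test_that("GMT files round-trip and shipped sets parse", {
  sets <- list(alpha = c("g1", "g2", "g3"), beta = c("g9"))
  path <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(sets, path)
  expect_identical(read_gmt(path), sets)
  shipped <- read_gmt(system.file("extdata/genesets/cellcycle_example.gmt",
                                  package = "screfine"))
  expect_setequal(names(shipped), c("G1S_example", "G2M_example"))
  expect_gte(length(shipped$G1S_example), 10)
})
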