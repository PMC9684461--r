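test_that("Kis values are the sum of the two fold-changes", {
  wt <- KineticsTable(c("g1", "g2"), "WT", TR = c(2, 3), RA = c(4, 3))
  mut <- KineticsTable(c("g1", "g2"), "mut", TR = c(1, 3), RA = c(4, 3))
  k <- computeKisValues(wt, mut)
  # g1: HL 2 -> 4 (ratio 2), TR 2 -> 1 (inverse ratio 2) => Kis value 4
  expect_equal(k$kis_value[k$gene_id == "g1"], 4)
  # untouched gene scores 2
  expect_equal(k$kis_value[k$gene_id == "g2"], 2)
  expect_equal(k$kis_value, k$hl_ratio + k$tr_ratio_inv)
})

test_that("WT scored against itself gives Kis value 2 everywhere", {
  wt <- noiselessKinetics(makeTinyTruth(), conditionSpec("WT"))
  k <- computeKisValues(wt, wt)
  expect_equal(k$kis_value, rep(2, nrow(k)))
})

test_that("genes missing or undefined in either table are dropped with a count", {
  wt <- KineticsTable(c("g1", "g2", "g3"), "WT", TR = c(2, 2, 2),
                      RA = c(4, 4, 4))
  mut <- KineticsTable(c("g1", "g2", "g4"), "mut",
                       TR = c(1, 2, 2), RA = c(8, 4, 4),
                       HL = c(8, NA, 2))
  expect_message(k <- computeKisValues(wt, mut), "3 gene")
  expect_identical(k$gene_id, "g1")
  expect_identical(S4Vectors::metadata(k)$n_dropped, 3L)
})

test_that("headline noiseless Kis values have median 2r = 5", {
  tr <- generateTruth(20000, preset = "headline", seed = 81)
  wt <- noiselessKinetics(tr, conditionSpec("WT"))
  mut <- noiselessKinetics(tr, conditionSpec("dNLS12"))
  k <- computeKisValues(wt, mut)
  r <- 1 / (1 - kisFraction(tr))
  # perfect buffering makes both terms equal r; oracle = median of 2r
  expect_equal(median(k$kis_value), median(2 * r))
  expect_lt(abs(median(k$kis_value) - 5) / 5, 0.03)
})

test_that("Kis classification is boundary-inclusive on both criteria", {
  tab <- new("KisTable", S4Vectors::DataFrame(
    gene_id = c("boundary", "oneSided", "clear", "none"),
    hl_ratio = c(2.0, 3.0, 4.0, 1.2),
    tr_ratio_inv = c(2.0, 1.9, 3.0, 1.1),
    kis_value = c(4.0, 4.9, 7.0, 2.3),
    is_kis = NA, bin = NA_integer_))
  cls <- classifyKis(tab, threshold = 2)
  expect_setequal(cls$kis, c("boundary", "clear"))
  expect_true("oneSided" %in% cls$hl_affected)
  expect_false("oneSided" %in% cls$kis)
  expect_identical(unname(cls$counts), c(3L, 2L, 2L))
  expect_error(classifyKis(tab, threshold = 1))
})

test_that("classification is invariant to a common unit rescaling", {
  tr <- generateTruth(500, seed = 82)
  wt <- noiselessKinetics(tr, conditionSpec("WT"))
  mut <- noiselessKinetics(tr, conditionSpec("dNLS12"))
  scale <- function(k, c) KineticsTable(k$gene_id, k$strain,
                                        TR = k$TR * c, RA = k$RA * c)
  k1 <- classifyKis(computeKisValues(wt, mut))
  k2 <- classifyKis(computeKisValues(scale(wt, 37.5), scale(mut, 37.5)))
  expect_identical(k1$kis, k2$kis)
  expect_equal(k1$table$kis_value, k2$table$kis_value)
})

test_that("perfect buffering makes the HL- and TR-affected sets coincide", {
  tr <- generateTruth(2000, preset = "headline", seed = 83)
  wt <- noiselessKinetics(tr, conditionSpec("WT"))
  mut <- noiselessKinetics(tr, conditionSpec("dNLS12"))
  cls <- classifyKis(computeKisValues(wt, mut))
  expect_setequal(cls$hl_affected, cls$tr_affected)
  # both sets are exactly the genes with r >= 2
  r <- 1 / (1 - kisFraction(tr))
  expect_setequal(cls$kis, tr$gene_id[r >= 2])
})

test_that("overlap significance matches closed forms and exhaustive enumeration", {
  # identical sets in a universe of 10: p = 1 / C(10, 5)
  expect_equal(overlapSignificance(letters[1:5], letters[1:5], 10),
               1 / choose(10, 5))
  # overlap 0 is always observed-or-larger: p = 1
  expect_equal(overlapSignificance(letters[1:3], letters[4:6], 12), 1)
  # exhaustive oracle over all C(N, b) draws, N <= 12
  cases <- list(c(a = 4, b = 5, N = 10, k = 3), c(a = 3, b = 3, N = 8, k = 1),
                c(a = 6, b = 4, N = 12, k = 2), c(a = 5, b = 5, N = 9, k = 4))
  for (cs in cases) {
    expect_equal(
      overlapSignificance(cs["a"], cs["b"], cs["N"], overlap = cs["k"]),
      enumOverlapP(cs["a"], cs["b"], cs["N"], cs["k"]),
      ignore_attr = TRUE)
  }
  expect_error(overlapSignificance(letters[1:5], letters[1:3], 4))
})

test_that("bin assignment ranks descending with equal sizes and stable ties", {
  b <- assignBins(1:12, nBins = 6)
  expect_identical(b[12:11], c(1L, 1L))   # highest values in bin 1
  expect_identical(as.integer(table(b)), rep(2L, 6))
  expect_identical(assignBins(c(5, 1, 9), nBins = 1), rep(1L, 3))
  # 100 genes in 6 bins: sizes 17,17,17,17,16,16
  sizes <- unname(table(assignBins(runif(100), nBins = 6)))
  expect_identical(as.integer(sizes), c(17L, 17L, 17L, 17L, 16L, 16L))
  # ties broken lexicographically by gene id
  bt <- assignBins(c(1, 1, 1, 1), nBins = 2, geneIds = c("d", "c", "b", "a"))
  expect_identical(bt, c(2L, 2L, 1L, 1L))
  expect_error(assignBins(1:5, nBins = 0))
  expect_error(assignBins(1:5, nBins = 6))
})

test_that("concatenating bins in order reproduces the descending sort", {
  set.seed(91)
  v <- runif(97)
  ids <- sprintf("g%03d", seq_along(v))
  bins <- assignBins(v, nBins = 5, geneIds = ids)
  byBin <- unlist(lapply(1:5, function(b) {
    i <- which(bins == b)
    i[order(-v[i], ids[i])]
  }))
  expect_identical(byBin, order(-v, ids))
})

test_that("permuting gene order changes no score, class or bin", {
  tr <- generateTruth(300, seed = 92)
  wt <- noiselessKinetics(tr, conditionSpec("WT"))
  mut <- noiselessKinetics(tr, conditionSpec("dNLS12"))
  run <- function(w, m) {
    k <- assignBins(classifyKis(computeKisValues(w, m))$table, nBins = 6)
    as.data.frame(k)[order(k$gene_id), ]
  }
  perm <- sample(nrow(wt))
  expect_equal(run(wt, mut), run(wt[perm, ], mut[perm, ]),
               ignore_attr = TRUE)
})

test_that("bin medians of log2 values summarize each bin", {
  s <- binSummary(log2(c(1, 2, 4)), bins = c(1, 1, 1))
  expect_equal(s$median, 1)
  expect_equal(s$n_genes, 3L)
  s2 <- binSummary(c(0, 1, 10, 11), bins = c(1, 1, 2, 2))
  expect_equal(s2$median, c(0.5, 10.5))
  expect_true(all(s2$q25 <= s2$median & s2$median <= s2$q75))
})

test_that("headline bin medians decrease from bin 1; deletion bins are flat", {
  tr <- generateTruth(5000, preset = "headline", seed = 93)
  wt <- noiselessKinetics(tr, conditionSpec("WT"))
  mut <- noiselessKinetics(tr, conditionSpec("dNLS12"))
  kis <- assignBins(computeKisValues(wt, mut), nBins = 6)
  med <- binSummary(log2(kis$hl_ratio), kis$bin)$median
  expect_true(all(diff(med) < 0))
  # same bins, deletion condition: stabilization across all bins, no gradient
  del <- noiselessKinetics(tr, conditionSpec("dXRN1"))
  hlDel <- del$HL[match(kis$gene_id, del$gene_id)] /
    wt$HL[match(kis$gene_id, wt$gene_id)]
  medDel <- binSummary(log2(hlDel), kis$bin)$median
  expect_lt(max(medDel) - min(medDel), 0.5)
  expect_true(all(medDel > 0))
})

test_that("buffering test reports medians and a rank-sum p-value", {
  x <- c(1, 2, 3, 4, 5)
  b <- bufferingTest(x, x)
  expect_equal(b$median_wt, b$median_mut)
  expect_gt(b$p_value, 0.99)
  tr <- generateTruth(5000, preset = "headline", seed = 94)
  wt <- noiselessKinetics(tr, conditionSpec("WT"))
  # beta = 1: element-wise identical abundance
  mut <- noiselessKinetics(tr, conditionSpec("dNLS12"))
  expect_equal(mut$RA, wt$RA)
  # beta = 0: stabilization without synthesis compensation raises RA
  unbuf <- noiselessKinetics(tr,
    conditionSpec("dNLS12", bufferingStrength = 0))
  res <- bufferingTest(wt$RA, unbuf$RA)
  expect_gt(res$median_mut, res$median_wt)
  expect_lt(res$p_value, 0.01)
})

test_that("log-ratio correlation matches the textbook covariance formula", {
  x <- c(0.5, 1, 2, 4, 8)
  expect_equal(correlateLogRatios(x, x), 1)
  expect_equal(correlateLogRatios(x, 1 / x), -1)
  set.seed(95)
  a <- exp(rnorm(50)); b <- a * exp(rnorm(50, sd = 0.5))
  la <- log2(a); lb <- log2(b)
  oracle <- sum((la - mean(la)) * (lb - mean(lb))) /
    sqrt(sum((la - mean(la))^2) * sum((lb - mean(lb))^2))
  expect_equal(correlateLogRatios(a, b), oracle)
  expect_error(correlateLogRatios(c(1, 2), c(1, 2)))
})

test_that("noisy headline data couples the synthesis and decay defects", {
  tr <- generateTruth(3000, preset = "headline", seed = 96)
  kwt <- groKinetics(simulateGro(applyCondition(tr, conditionSpec("WT")),
                                 measurementConfig(sigmaNoise = 0.3, seed = 97)))
  kmut <- groKinetics(simulateGro(applyCondition(tr, conditionSpec("dNLS12")),
                                  measurementConfig(sigmaNoise = 0.3, seed = 98)))
  k <- computeKisValues(kwt, kmut)
  expect_gt(correlateLogRatios(k$hl_ratio, k$tr_ratio_inv), 0.5)
})
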