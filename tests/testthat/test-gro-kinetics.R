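test_that("cell-volume normalization is element-wise division", {
  expect_equal(normalizeToCellVolume(c(10, 20), 2), c(5, 10))
  expect_equal(normalizeToCellVolume(c(3, 7), 1), c(3, 7))
  expect_error(normalizeToCellVolume(1:3, 0))
  expect_error(normalizeToCellVolume(1:3, -2))
})

test_that("volume normalization round-trips simulated signals exactly", {
  tr <- makeTinyTruth()
  prof <- applyCondition(tr, conditionSpec("WT"))
  g <- simulateGro(prof, measurementConfig(sigmaNoise = 0, cellVolume = 1.3,
                                           seed = 1))
  k <- groKinetics(g)  # divides the recorded volume back out
  expect_equal(k$TR, prof$tr)
  expect_equal(k$RA, prof$tr / prof$kd)
})

test_that("replicate aggregation is the per-gene geometric mean", {
  ntr <- matrix(c(1, 4, 9, 9), 2, 2, dimnames = list(c("g1", "g2"), NULL))
  ra <- matrix(c(2, 8, 2, 2), 2, 2, dimnames = list(c("g1", "g2"), NULL))
  g <- GroExperiment(ntr, ra, strain = "WT")
  agg <- aggregateReplicates(g)
  expect_equal(agg$TR, c(sqrt(1 * 9), sqrt(4 * 9)))
  expect_equal(agg$RA, c(2, 4))
  # single replicate is the identity
  g1 <- GroExperiment(ntr[, 1, drop = FALSE], ra[, 1, drop = FALSE], "WT")
  expect_equal(aggregateReplicates(g1)$TR, unname(ntr[, 1]))
  # zero signal flags the gene
  ntr[2, 1] <- 0
  gz <- GroExperiment(ntr, ra, "WT")
  expect_identical(aggregateReplicates(gz)$usable, c(TRUE, FALSE))
  expect_message(kz <- groKinetics(gz), "excluded")
  expect_true(is.na(kz$HL[2]))
})

test_that("half-life is RA/TR with undefined values signalled, not thrown", {
  expect_equal(computeHalfLife(RA = 10, TR = 5), 2)
  expect_equal(computeHalfLife(RA = 0, TR = 5), 0)
  expect_true(is.na(computeHalfLife(RA = 3, TR = 0)))
  expect_true(is.na(computeHalfLife(RA = 3, TR = -1)))
})

test_that("noiseless inference makes HL * kd constant across genes", {
  tr <- generateTruth(200, seed = 21)
  prof <- applyCondition(tr, conditionSpec("WT"))
  k <- groKinetics(simulateGro(prof, measurementConfig(sigmaNoise = 0,
                                                       seed = 1)))
  expect_lt(max(abs(k$HL * kdWT(tr) - 1)), 1e-9)
})

test_that("total Pol II transcription is the plain sum", {
  expect_equal(totalPolIITr(c(1, 2, 3)), 6)
  expect_equal(totalPolIITr(numeric(0)), 0)
  set.seed(31)
  x <- runif(200)
  acc <- 0
  for (v in x) acc <- acc + v   # loop oracle
  expect_equal(totalPolIITr(x), acc)
})

test_that("decay fitting reproduces analytic half-lives on exact exponentials", {
  t <- c(0, 5, 10, 20)
  mk <- function(kd) rbind(
    data.frame(gene_id = "g", minutes = t, level = 5 * exp(-kd * t)),
    data.frame(gene_id = "SCR1", minutes = t, level = 2))
  for (kd in c(0.03, 0.1, 0.5)) {
    fit <- fitDecayCurve(mk(kd))
    expect_lt(abs(fit$half_life - log(2) / kd) / (log(2) / kd), 1e-9)
    expect_identical(fit$status, "ok")
  }
})

test_that("decay fitting handles stable, rejected and short courses", {
  t <- c(0, 5, 10, 20)
  flat <- rbind(data.frame(gene_id = "g", minutes = t, level = 3),
                data.frame(gene_id = "SCR1", minutes = t, level = 1))
  f <- fitDecayCurve(flat)
  expect_identical(f$status, "stable")
  expect_identical(f$half_life, Inf)
  up <- rbind(data.frame(gene_id = "g", minutes = t,
                         level = exp(0.05 * t)),
              data.frame(gene_id = "SCR1", minutes = t, level = 1))
  f2 <- fitDecayCurve(up)
  expect_identical(f2$status, "rejected")
  expect_true(is.na(f2$half_life))
  short <- rbind(data.frame(gene_id = "g", minutes = c(0, 5),
                            level = c(1, 0.5)),
                 data.frame(gene_id = "SCR1", minutes = c(0, 5), level = 1))
  expect_identical(fitDecayCurve(short)$status, "insufficient")
})

test_that("decay fitting matches the covariance-formula regression oracle", {
  tr <- makeTinyTruth()
  tc <- simulateShutoff(tr, conditionSpec("WT"),
                        genes = c("gA", "gB", "gC"),
                        timepoints = c(0, 2, 5, 10, 20, 40),
                        sigmaNoise = 0.15, seed = 41)
  fit <- fitDecayCurve(tc)
  d <- as.data.frame(tc)
  ref <- d[d$gene_id == "SCR1", ]
  for (i in seq_len(nrow(fit))) {
    g <- d[d$gene_id == fit$gene_id[i], ]
    y <- log(g$level / ref$level[match(g$minutes, ref$minutes)])
    slope <- slopeOracle(g$minutes, y)
    expect_lt(abs(fit$slope[i] - slope), 1e-9)
    expect_lt(abs(fit$half_life[i] - log(2) / abs(slope)) /
                fit$half_life[i], 1e-9)
  }
})

test_that("reference normalization cancels loading artefacts", {
  t <- c(0, 5, 10)
  kd <- 0.1
  loading <- c(1, 0.5, 2)  # per-lane distortion hits gene and SCR1 alike
  d <- rbind(
    data.frame(gene_id = "g", minutes = t, level = exp(-kd * t) * loading),
    data.frame(gene_id = "SCR1", minutes = t, level = 7 * loading))
  fit <- fitDecayCurve(d)
  expect_lt(abs(fit$half_life - log(2) / kd) / (log(2) / kd), 1e-9)
})

test_that("spike-in normalization rescales counts by the spike ratio", {
  expect_equal(spikeNormalize(c(10, 20), spikeCounts = 4, referenceSpike = 2),
               c(5, 10))
  expect_equal(spikeNormalize(c(10, 20), spikeCounts = 3, referenceSpike = 3),
               c(10, 20))
  expect_error(spikeNormalize(1:3, spikeCounts = 0))
  m <- matrix(c(10, 20, 10, 20), 2, 2)
  norm <- spikeNormalize(m, spikeCounts = c(1, 2), referenceSpike = 1)
  expect_equal(norm[, 2], m[, 2] / 2)
})

test_that("spike normalization recovers true abundance ratios from refeed counts", {
  tr <- generateTruth(400, seed = 51)
  sim <- simulateRefeedCounts(tr, conditionSpec("WT"),
                              timepoints = c(0, 135), spikeFraction = 0.1,
                              meanDepth = 5e6, seed = 52)
  spike <- grepl("^spombe_", rownames(sim$counts))
  norm <- spikeNormalize(sim$counts[!spike, ],
                         spikeCounts = colSums(sim$counts[spike, ]))
  # normalized ratio between timepoints should track the true RA ratio
  expressed <- rowSums(sim$counts[!spike, ]) > 200
  obs <- norm[expressed, 2] / norm[expressed, 1]
  expected <- sim$truth_ra[expressed, 2] / sim$truth_ra[expressed, 1]
  expect_lt(median(abs(obs / expected - 1)), 0.05)
})

test_that("volume normalization commutes with replicate aggregation", {
  prof <- applyCondition(generateTruth(50, seed = 61), conditionSpec("WT"))
  g <- simulateGro(prof, measurementConfig(sigmaNoise = 0.2, seed = 62))
  aggThenNorm <- normalizeToCellVolume(aggregateReplicates(g)$TR, 1.7)
  gn <- GroExperiment(
    normalizeToCellVolume(SummarizedExperiment::assay(g, "ntr"), 1.7),
    normalizeToCellVolume(SummarizedExperiment::assay(g, "ra"), 1.7),
    strain = "WT")
  normThenAgg <- aggregateReplicates(gn)$TR
  expect_equal(aggThenNorm, normThenAgg)
})

test_that("HL ratios recover decay-rate truth through the noisy pipeline", {
  tr <- generateTruth(5000, preset = "headline", seed = 71)
  kwt <- groKinetics(simulateGro(
    applyCondition(tr, conditionSpec("WT")),
    measurementConfig(sigmaNoise = 0.2, seed = 72)))
  kmut <- groKinetics(simulateGro(
    applyCondition(tr, conditionSpec("dNLS12")),
    measurementConfig(sigmaNoise = 0.2, seed = 73)))
  ratio <- kmut$HL / kwt$HL
  truthRatio <- kdWT(tr) / applyCondition(tr, conditionSpec("dNLS12"))$kd
  expect_lt(abs(median(ratio) - median(truthRatio)) / median(truthRatio),
            0.05)
  # noiseless limit is exact per gene
  kwt0 <- groKinetics(simulateGro(
    applyCondition(tr[1:100, ], conditionSpec("WT")),
    measurementConfig(sigmaNoise = 0, seed = 1)))
  kmut0 <- groKinetics(simulateGro(
    applyCondition(tr[1:100, ], conditionSpec("dNLS12")),
    measurementConfig(sigmaNoise = 0, seed = 1)))
  expect_equal(kmut0$HL / kwt0$HL, truthRatio[1:100])
})
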