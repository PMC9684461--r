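#' @importFrom stats rnorm rlnorm rpois rmultinom runif median
#' @importFrom withr with_seed
NULL

.withSeed <- function(seed, code) {
  if (is.null(seed)) code else withr::with_seed(as.integer(seed), code)
}

#' Condition specification for the two-pathway decay model
#'
#' Describes one strain as a perturbation of the wild-type kinetics.
#' `importEfficiency` (eta, in `[0, 1]`) is the fraction of Kis-pathway
#' decay activity retained — 1 for the wild type, 0 when nuclear import of
#' the exonuclease is fully blocked. `bufferingStrength` (beta, in
#' `[0, 1]`) couples synthesis to the decay defect: with beta = 1 the
#' synthesis rate is co-reduced so that steady-state mRNA abundance is
#' exactly unchanged (perfect buffering); with beta = 0 synthesis is
#' untouched and abundance rises. The deletion strain `dXRN1` ignores eta
#' and decays with the exosome-backup rate `kd_exo`.
#'
#' @param name one of `"WT"`, `"dNLS1"`, `"dNLS2"`, `"dNLS12"`,
#'   `"dKAP120"`, `"dXRN1"`.
#' @param importEfficiency eta in `[0, 1]`; default per strain: 1 for WT,
#'   0.25 for single-NLS mutants, 0 for `dNLS12`/`dKAP120`, ignored for
#'   `dXRN1`.
#' @param bufferingStrength beta in `[0, 1]`, default 1.
#' @return A named list of class `ConditionSpec`.
#' @examples
#' conditionSpec("dNLS12")
#' @export
conditionSpec <- function(name = c("WT", "dNLS1", "dNLS2", "dNLS12",
                                   "dKAP120", "dXRN1"),
                          importEfficiency = NULL,
                          bufferingStrength = 1) {
  name <- match.arg(name)
  if (is.null(importEfficiency)) {
    importEfficiency <- switch(name,
      WT = 1, dNLS1 = 0.25, dNLS2 = 0.25,
      dNLS12 = 0, dKAP120 = 0, dXRN1 = 0)
  }
  stopifnot(importEfficiency >= 0, importEfficiency <= 1,
            bufferingStrength >= 0, bufferingStrength <= 1)
  structure(list(name = name,
                 import_efficiency = importEfficiency,
                 buffering_strength = bufferingStrength),
            class = "ConditionSpec")
}

#' Measurement configuration for simulated assays
#'
#' @param nReplicates number of biological replicates (>= 1); genomic
#'   run-on assays are conventionally done in three.
#' @param sigmaNoise log-space standard deviation of the multiplicative
#'   measurement noise (>= 0).
#' @param cellVolume positive per-strain cell-volume scale factor applied
#'   to raw signals (undone by the analysis pipeline).
#' @param seed integer seed, or `NULL` to use the current RNG state.
#' @return A named list of class `MeasurementConfig`.
#' @export
measurementConfig <- function(nReplicates = 3, sigmaNoise = 0.2,
                              cellVolume = 1, seed = NULL) {
  stopifnot(nReplicates >= 1, sigmaNoise >= 0, cellVolume > 0)
  structure(list(n_replicates = as.integer(nReplicates),
                 sigma_noise = sigmaNoise,
                 cell_volume = cellVolume,
                 seed = seed),
            class = "MeasurementConfig")
}

#' Generate ground-truth gene kinetics
#'
#' Draws a per-gene truth table under the two-pathway decay model. Total
#' wild-type decay rate `kd_wt` is split into a classical cytoplasmic
#' component `kd_cls` and an import-sensitive component `kd_kis`, via a
#' per-gene true half-life fold-change `r` (the stabilization a gene would
#' show if the Kis pathway were fully lost): `kd_kis = kd_wt * (1 - 1/r)`.
#'
#' Presets:
#' * `"headline"` — `r` ~ LogNormal(median 2.5, sdlog 0.4) truncated at
#'   `r >= 1`, giving a continuous spectrum of Kis fractions with the
#'   population median stabilization at 2.5-fold.
#' * `"uniform"` — Kis fraction `f` ~ Uniform(0, 0.95).
#' * `"null"` — `kd_kis = 0` for every gene (no import-sensitive decay).
#'
#' `tr_wt` is drawn log-uniform over `trRange` and `kd_wt` log-uniform over
#' `kdRange`. The exosome-backup rate is `kd_exo = kd_wt / s` with
#' stabilization factor `s` ~ LogNormal(median 3, sdlog 0.3) truncated at
#' `s >= 1`, independent of the Kis fraction. Optionally a destabilized
#' tail (`r < 1` is not allowed, so these genes instead get `kd_kis = 0`
#' and a mutant-destabilized marker via `kd_exo`) can be emulated by
#' `destabilizedFraction`, which assigns that fraction of genes `r` drawn
#' from Uniform(0.5, 1) — their `kd_kis` is clamped to 0 and the drawn `r`
#' is recorded only through `kd_cls = kd_wt`.
#'
#' @param nGenes number of genes (>= 1).
#' @param preset `"headline"`, `"uniform"` or `"null"`.
#' @param seed integer seed (same seed, identical table) or `NULL`.
#' @param trRange,kdRange length-2 positive ranges for the log-uniform
#'   draws of `tr_wt` (a.u./min) and `kd_wt` (1/min).
#' @param rSdlog log-sd of the headline fold-change distribution.
#' @param rMedian median of the headline fold-change distribution.
#' @param exoMedian,exoSdlog LogNormal parameters of the xrn1-null
#'   stabilization factor.
#' @return A [GeneTruth] table.
#' @examples
#' tr <- generateTruth(10, preset = "headline", seed = 1)
#' kisFraction(tr)
#' @export
generateTruth <- function(nGenes, preset = c("headline", "uniform", "null"),
                          seed = NULL,
                          trRange = c(0.5, 50), kdRange = c(0.02, 0.7),
                          rMedian = 2.5, rSdlog = 0.4,
                          exoMedian = 3, exoSdlog = 0.3) {
  preset <- match.arg(preset)
  if (nGenes < 1) stop("nGenes must be >= 1")
  stopifnot(all(trRange > 0), all(kdRange > 0))
  .withSeed(seed, {
    n <- as.integer(nGenes)
    gene_id <- sprintf("gene_%05d", seq_len(n))
    tr_wt <- exp(runif(n, log(trRange[1]), log(trRange[2])))
    kd_wt <- exp(runif(n, log(kdRange[1]), log(kdRange[2])))
    f <- switch(preset,
      headline = {
        r <- .rlnormTrunc(n, meanlog = log(rMedian), sdlog = rSdlog, lower = 1)
        1 - 1 / r
      },
      uniform = runif(n, 0, 0.95),
      null = rep(0, n))
    s <- .rlnormTrunc(n, meanlog = log(exoMedian), sdlog = exoSdlog, lower = 1)
    GeneTruth(gene_id = gene_id, tr_wt = tr_wt,
              kd_cls = kd_wt * (1 - f), kd_kis = kd_wt * f,
              kd_exo = kd_wt / s)
  })
}

# lognormal truncated below at `lower`, by resampling (truncation mass is
# small for the defaults, so the loop terminates quickly)
.rlnormTrunc <- function(n, meanlog, sdlog, lower) {
  x <- rlnorm(n, meanlog, sdlog)
  while (any(bad <- x < lower))
    x[bad] <- rlnorm(sum(bad), meanlog, sdlog)
  x
}

#' Total wild-type decay rate and Kis fraction accessors
#'
#' `kdWT(x)` returns `kd_cls + kd_kis`; `kisFraction(x)` returns
#' `f = kd_kis / kd_wt`, the share of wild-type decay carried by the
#' import-sensitive pathway.
#'
#' @param x a [GeneTruth] table.
#' @return A numeric vector aligned with `x`.
#' @export
kdWT <- function(x) {
  stopifnot(is(x, "GeneTruth"))
  x$kd_cls + x$kd_kis
}

#' @rdname kdWT
#' @export
kisFraction <- function(x) {
  stopifnot(is(x, "GeneTruth"))
  x$kd_kis / (x$kd_cls + x$kd_kis)
}

#' Apply a strain condition to ground-truth kinetics
#'
#' Computes the per-gene condition kinetics. For import mutants the decay
#' rate retains the classical pathway plus the residual Kis activity,
#' `kd_cond = kd_cls + eta * kd_kis`; for the deletion strain `dXRN1` the
#' exosome backup takes over, `kd_cond = kd_exo`. Synthesis is co-adjusted
#' by the buffering law `tr_cond = tr_wt * (kd_cond / kd_wt)^beta`, so that
#' with beta = 1 the steady-state abundance `tr/kd` is exactly the
#' wild-type one.
#'
#' @param truth a nonempty [GeneTruth] table.
#' @param cond a [conditionSpec()].
#' @return A [S4Vectors::DataFrame] with columns `gene_id`, `strain`,
#'   `tr`, `kd`.
#' @examples
#' tr <- generateTruth(5, seed = 1)
#' applyCondition(tr, conditionSpec("dNLS12"))
#' @export
applyCondition <- function(truth, cond) {
  stopifnot(is(truth, "GeneTruth"), inherits(cond, "ConditionSpec"))
  if (nrow(truth) == 0) stop("truth table is empty")
  kd_wt <- kdWT(truth)
  kd <- if (cond$name == "dXRN1") truth$kd_exo
        else truth$kd_cls + cond$import_efficiency * truth$kd_kis
  tr <- truth$tr_wt * (kd / kd_wt)^cond$buffering_strength
  DataFrame(gene_id = truth$gene_id, strain = cond$name, tr = tr, kd = kd)
}

#' Simulate a genomic run-on sample
#'
#' Generates gene-by-replicate nascent-transcription and mRNA-abundance
#' signals for one strain. Each signal is the true value times i.i.d.
#' multiplicative lognormal noise, times the strain's cell-volume factor:
#' `ntr = tr * exp(eps) * V` and `ra = (tr/kd) * exp(eps') * V` with
#' `eps, eps' ~ Normal(0, sigmaNoise)` independently per gene and
#' replicate.
#'
#' @param profile DataFrame from [applyCondition()] (columns `gene_id`,
#'   `strain`, `tr`, `kd`), all rates positive.
#' @param config a [measurementConfig()].
#' @return A [GroExperiment].
#' @examples
#' tr <- generateTruth(5, seed = 1)
#' g <- simulateGro(applyCondition(tr, conditionSpec("WT")),
#'                  measurementConfig(seed = 1))
#' @export
simulateGro <- function(profile, config = measurementConfig()) {
  stopifnot(all(c("gene_id", "tr", "kd") %in% colnames(profile)),
            inherits(config, "MeasurementConfig"))
  if (any(profile$tr <= 0) || any(profile$kd <= 0))
    stop("rates must be positive")
  n <- nrow(profile)
  k <- config$n_replicates
  .withSeed(config$seed, {
    eps  <- matrix(rnorm(n * k, 0, config$sigma_noise), n, k)
    eps2 <- matrix(rnorm(n * k, 0, config$sigma_noise), n, k)
    ntr <- profile$tr * exp(eps) * config$cell_volume
    ra  <- (profile$tr / profile$kd) * exp(eps2) * config$cell_volume
    dimnames(ntr) <- dimnames(ra) <-
      list(profile$gene_id, paste0("rep", seq_len(k)))
    GroExperiment(ntr, ra,
                  strain = if ("strain" %in% colnames(profile))
                             profile$strain[1] else NA_character_,
                  cellVolume = config$cell_volume,
                  sigmaNoise = config$sigma_noise)
  })
}

#' Simulate a transcription-shutoff decay time course
#'
#' Gene levels decay exponentially from their condition steady state after
#' transcription arrest: `level(g, t) = RA(g) * exp(-kd(g) * t) *
#' exp(noise)`. A stable reference transcript row (SCR1, `kd = 0`) is
#' always included for loading normalization.
#'
#' @param truth a [GeneTruth] table.
#' @param cond a [conditionSpec()].
#' @param genes character vector of gene ids (subset of `truth`).
#' @param timepoints minutes post shutoff; must include 0, none negative.
#' @param sigmaNoise log-space noise s.d. (0 for a noiseless course).
#' @param seed integer seed or `NULL`.
#' @param referenceLevel constant level of the reference transcript.
#' @return A [DecayTimeCourse].
#' @export
simulateShutoff <- function(truth, cond, genes, timepoints,
                            sigmaNoise = 0, seed = NULL,
                            referenceLevel = 100) {
  stopifnot(is(truth, "GeneTruth"), inherits(cond, "ConditionSpec"))
  if (any(timepoints < 0)) stop("timepoints must be >= 0")
  if (!0 %in% timepoints) stop("timepoints must include 0")
  if (!all(genes %in% truth$gene_id))
    stop("genes must be a subset of the truth table")
  prof <- applyCondition(truth[match(genes, truth$gene_id), ], cond)
  tp <- sort(unique(timepoints))
  .withSeed(seed, {
    grid <- expand.grid(gene = seq_len(nrow(prof)), t = tp)
    lvl0 <- prof$tr[grid$gene] / prof$kd[grid$gene]
    lvl <- lvl0 * exp(-prof$kd[grid$gene] * grid$t) *
      exp(rnorm(nrow(grid), 0, sigmaNoise))
    ref <- referenceLevel * exp(rnorm(length(tp), 0, sigmaNoise))
    DecayTimeCourse(
      gene_id = c(prof$gene_id[grid$gene], rep("SCR1", length(tp))),
      minutes = c(grid$t, tp),
      level = c(lvl, ref))
  })
}

#' Simulate starvation-exit count tables with spike-in rows
#'
#' Emulates spike-in-normalized RNA-seq of cells exiting starvation. Each
#' gene relaxes from a gene-specific starved level toward its condition
#' steady state, `M(g, t) = M* + (M0 - M*) * exp(-kd t)` with
#' `M0 = u_g * M*`, `u_g ~ Uniform(0.05, 0.5)` drawn once per gene. For
#' each condition-by-timepoint sample, reads are multinomial over genes
#' plus spike-in rows (prefixed `"spombe_"`) and carry a sample-specific
#' lognormal library-size factor. Spike-in cells are a fixed fraction of
#' the culture, so the spike-in read mass is constant per sample —
#' calibrated so its expected share equals `spikeFraction` when the
#' transcriptome is at its wild-type steady-state total; in starved
#' samples (less mRNA per cell) the spike share is correspondingly
#' higher. Dividing counts by the spike total therefore recovers absolute
#' abundance trajectories up to one global constant. True abundances are
#' returned alongside for recovery tests.
#'
#' @param truth a [GeneTruth] table.
#' @param conds list of [conditionSpec()]s.
#' @param timepoints sampling times in minutes (e.g. refeeding at 0, 45,
#'   135 min).
#' @param spikeFraction expected spike-in read share, in (0, 1).
#' @param meanDepth mean library size per sample.
#' @param nSpike number of spike-in rows.
#' @param librarySdlog log-sd of the per-sample library-size factor.
#' @param seed integer seed or `NULL`.
#' @return A list with `counts` (gene-by-sample integer matrix incl.
#'   spike rows), `samples` (DataFrame: sample, strain, minutes,
#'   library_factor) and `truth_ra` (true abundance matrix, genes only).
#' @export
simulateRefeedCounts <- function(truth, conds, timepoints = c(0, 45, 135),
                                 spikeFraction = 0.1, meanDepth = 1e6,
                                 nSpike = 50, librarySdlog = 0.2,
                                 seed = NULL) {
  stopifnot(is(truth, "GeneTruth"))
  if (spikeFraction <= 0 || spikeFraction >= 1)
    stop("spikeFraction must be in (0, 1)")
  if (inherits(conds, "ConditionSpec")) conds <- list(conds)
  .withSeed(seed, {
    u <- runif(nrow(truth), 0.05, 0.5)
    spike_ab <- exp(runif(nSpike, log(0.5), log(50)))
    # fixed spike mass per cell: spikeFraction of reads when the
    # transcriptome totals its WT steady-state mass
    ssTotal <- sum(truth$tr_wt / kdWT(truth))
    spike_ab <- spike_ab / sum(spike_ab) *
      ssTotal * spikeFraction / (1 - spikeFraction)
    spike_ids <- sprintf("spombe_%03d", seq_len(nSpike))
    samples <- do.call(rbind, lapply(conds, function(cd)
      data.frame(strain = cd$name, minutes = timepoints)))
    samples$sample <- sprintf("%s_t%g", samples$strain, samples$minutes)
    samples$library_factor <- exp(rnorm(nrow(samples), 0, librarySdlog))
    truth_ra <- matrix(NA_real_, nrow(truth), nrow(samples),
                       dimnames = list(truth$gene_id, samples$sample))
    counts <- matrix(0L, nrow(truth) + nSpike, nrow(samples),
                     dimnames = list(c(truth$gene_id, spike_ids),
                                     samples$sample))
    for (i in seq_len(nrow(samples))) {
      cd <- conds[[match(samples$strain[i], vapply(conds, `[[`, "", "name"))]]
      prof <- applyCondition(truth, cd)
      mstar <- prof$tr / prof$kd
      m <- mstar + (u * mstar - mstar) * exp(-prof$kd * samples$minutes[i])
      truth_ra[, i] <- m
      p <- c(m, spike_ab) / (sum(m) + sum(spike_ab))
      depth <- round(meanDepth * samples$library_factor[i])
      counts[, i] <- rmultinom(1, size = depth, prob = p)[, 1]
    }
    list(counts = counts, samples = DataFrame(samples), truth_ra = truth_ra)
  })
}

#' Simulate RIP-seq read records and polyadenylation-site annotations
#'
#' Emulates oligo(dT)-primed RIP-seq of an mRNA-binding protein. Expected
#' per-gene read counts are proportional to the strain's steady-state
#' abundance; in `mode = "in_vivo"` under an import mutant they are
#' additionally multiplied by `exp(bindGain * f * (1 - eta))`, a monotone
#' increasing function of the Kis fraction `f` (import-blocked protein
#' accumulates non-productively on high-Kis mRNAs), while `"in_vitro"`
#' binding is abundance-proportional only. Trailing-adenine lengths are
#' drawn so that `longTailFraction` of reads exceed 15 As (full-length
#' mRNAs); mapped distances to the gene's primary polyadenylation site are
#' Normal(0, `distanceSd`), rounded.
#'
#' @param truth a [GeneTruth] table.
#' @param mode `"in_vivo"` or `"in_vitro"`.
#' @param cond a [conditionSpec()].
#' @param meanReadsPerGene expected reads for an average-abundance gene.
#' @param bindGain log-scale gain of the in vivo Kis-dependent binding.
#' @param longTailFraction fraction of reads with > 15 trailing As.
#' @param distanceSd s.d. (bp) of the mapped distance to the polyA site.
#' @param seed integer seed or `NULL`.
#' @return A list with `reads` (DataFrame: read_id, gene_id, distance_bp,
#'   trailing_A) and `sites` (a [GenomicRanges::GRanges] of single-base
#'   primary polyA sites, one per gene, with `gene_id` metadata).
#' @export
simulateRipReads <- function(truth, mode = c("in_vivo", "in_vitro"),
                             cond = conditionSpec("WT"),
                             meanReadsPerGene = 50, bindGain = 1.5,
                             longTailFraction = 0.8, distanceSd = 100,
                             seed = NULL) {
  mode <- match.arg(mode)
  stopifnot(is(truth, "GeneTruth"), inherits(cond, "ConditionSpec"))
  prof <- applyCondition(truth, cond)
  ra <- prof$tr / prof$kd
  lambda <- ra / mean(ra) * meanReadsPerGene
  if (mode == "in_vivo" && cond$name != "dXRN1")
    lambda <- lambda * exp(bindGain * kisFraction(truth) *
                             (1 - cond$import_efficiency))
  sites <- makePolyASites(truth$gene_id)
  .withSeed(seed, {
    nread <- rpois(length(lambda), lambda)
    gene <- rep(truth$gene_id, nread)
    total <- sum(nread)
    long <- runif(total) < longTailFraction
    trailing <- integer(total)
    trailing[long] <- 16L + rpois(sum(long), 20)
    trailing[!long] <- sample(0:15, sum(!long), replace = TRUE)
    reads <- DataFrame(
      read_id = sprintf("read_%07d", seq_len(total)),
      gene_id = gene,
      distance_bp = as.integer(round(rnorm(total, 0, distanceSd))),
      trailing_A = trailing)
    list(reads = reads, sites = sites)
  })
}

#' Build a synthetic primary polyadenylation-site annotation
#'
#' One single-base site per gene, laid out on a synthetic chromosome with
#' regular spacing (genomic coordinates are arbitrary: the quantification
#' consumes read-to-site distances, not positions).
#'
#' @param geneIds character vector of gene ids.
#' @param spacing bp between consecutive sites.
#' @return A [GenomicRanges::GRanges], 0-based export-ready via
#'   [writePolyASites()].
#' @export
makePolyASites <- function(geneIds, spacing = 2000L) {
  gr <- GenomicRanges::GRanges(
    seqnames = "chr_sim",
    ranges = IRanges::IRanges(start = spacing * seq_along(geneIds),
                              width = 1L),
    strand = "+")
  gr$gene_id <- as.character(geneIds)
  names(gr) <- gr$gene_id
  gr
}
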