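#' @importFrom stats lm coef
NULL

#' Normalize signals to the average cell volume
#'
#' Raw run-on and hybridization signals scale with cell size; dividing by
#' the strain's average cell volume (median of the population) puts
#' strains on a per-volume footing.
#'
#' @param values numeric vector or matrix of signals (a.u.).
#' @param volume positive scalar volume factor.
#' @return `values / volume`.
#' @examples
#' normalizeToCellVolume(c(10, 20), 2)
#' @export
normalizeToCellVolume <- function(values, volume) {
  if (!is.numeric(volume) || length(volume) != 1 || volume <= 0)
    stop("volume must be a positive scalar")
  values / volume
}

#' Aggregate replicate signals into per-gene TR and RA
#'
#' Replicates are combined by the geometric mean per gene and signal
#' (ratio-friendly under multiplicative noise). Genes with any zero signal
#' have no defined geometric mean on the log scale; they are kept with
#' `TR`/`RA` of 0 where the mean is 0 and flagged via the `usable` column,
#' and are excluded from half-life computation downstream.
#'
#' @param sample a [GroExperiment].
#' @return A [S4Vectors::DataFrame] with columns `gene_id`, `TR`, `RA`,
#'   `usable`.
#' @export
aggregateReplicates <- function(sample) {
  stopifnot(is(sample, "GroExperiment"))
  ntr <- assay(sample, "ntr")
  ra <- assay(sample, "ra")
  if (ncol(ntr) < 1) stop("sample has no replicates")
  gm <- function(m) {
    out <- exp(rowMeans(log(m)))
    out[apply(m == 0, 1, any)] <- 0
    unname(out)
  }
  TR <- gm(ntr)
  RA <- gm(ra)
  DataFrame(gene_id = rownames(ntr), TR = TR, RA = RA,
            usable = TR > 0 & RA > 0)
}

#' Steady-state half-life from abundance and synthesis rate
#'
#' At steady state `dM/dt = TR - kd * M = 0`, so `M / TR = 1 / kd`: the
#' ratio of mRNA abundance to transcription rate is proportional to the
#' half-life. `HL = RA / TR`, in arbitrary units. Genes with nonpositive
#' `TR` get `NA` (undefined half-life), not an error.
#'
#' @param RA mRNA abundance (a.u.), `>= 0`.
#' @param TR transcription rate (a.u./min).
#' @return `RA / TR`, with `NA` where `TR <= 0`.
#' @examples
#' computeHalfLife(RA = 10, TR = 5)
#' @export
computeHalfLife <- function(RA, TR) {
  hl <- RA / TR
  hl[!is.na(TR) & TR <= 0] <- NA_real_
  hl
}

#' Total RNA polymerase II transcription rate
#'
#' The genome-wide Pol II output: the arithmetic sum of all individual
#' per-gene TR values.
#'
#' @param TRs numeric vector of per-gene transcription rates.
#' @param na.rm drop `NA`s before summing.
#' @return A scalar sum (0 for an empty vector).
#' @export
totalPolIITr <- function(TRs, na.rm = FALSE) {
  sum(TRs, na.rm = na.rm)
}

#' Full GRO inference: signals to a KineticsTable
#'
#' Undoes the cell-volume factor, aggregates replicates by geometric mean,
#' and computes `HL = RA / TR`. Genes flagged unusable (a zero signal in
#' any replicate) get `NA` half-lives; their count is reported via a
#' message and the `n_dropped` attribute.
#'
#' @param sample a [GroExperiment].
#' @param cellVolume volume factor to divide out; defaults to the one
#'   recorded in the sample's metadata.
#' @param strain strain label; defaults to the recorded one.
#' @return A [KineticsTable].
#' @examples
#' tr <- generateTruth(20, seed = 1)
#' g <- simulateGro(applyCondition(tr, conditionSpec("WT")),
#'                  measurementConfig(sigmaNoise = 0, seed = 1))
#' groKinetics(g)
#' @export
groKinetics <- function(sample, cellVolume = metadata(sample)$cell_volume,
                        strain = metadata(sample)$strain) {
  stopifnot(is(sample, "GroExperiment"))
  if (is.null(cellVolume)) cellVolume <- 1
  agg <- aggregateReplicates(sample)
  TR <- normalizeToCellVolume(agg$TR, cellVolume)
  RA <- normalizeToCellVolume(agg$RA, cellVolume)
  HL <- computeHalfLife(RA, TR)
  HL[!agg$usable] <- NA_real_
  nd <- sum(!agg$usable)
  if (nd > 0)
    message(nd, " gene(s) with zero signal excluded from half-life")
  out <- KineticsTable(gene_id = agg$gene_id,
                       strain = if (is.null(strain)) NA_character_ else strain,
                       TR = TR, RA = RA, HL = HL)
  metadata(out)$n_dropped <- nd
  out
}

#' Fit an exponential decay curve to a shutoff time course
#'
#' For each gene, levels are first normalized by the stable reference
#' transcript at each timepoint (correcting loading), then an unweighted
#' least-squares line is fitted to `ln(level)` versus time. The half-life
#' is `ln(2) / |slope|`. Fits with fewer than 3 usable (positive) points
#' give `NA`; a slope of zero within `slopeTolerance` signals an
#' effectively stable transcript (`Inf` half-life); a positive slope
#' beyond the tolerance is rejected (`NA`, flagged in `status`).
#'
#' @param course a [DecayTimeCourse] or a data.frame with columns
#'   `gene_id`, `minutes`, `level`.
#' @param reference reference transcript id (default from metadata, else
#'   `"SCR1"`).
#' @param slopeTolerance absolute slope below which the transcript is
#'   treated as stable.
#' @return A [S4Vectors::DataFrame] with one row per gene: `gene_id`,
#'   `half_life` (minutes), `slope`, `r_squared`, `n_points`, `status`
#'   (`"ok"`, `"stable"`, `"rejected"`, `"insufficient"`).
#' @examples
#' tc <- data.frame(gene_id = "g", minutes = c(0, 5, 10, 20),
#'                  level = exp(-0.1 * c(0, 5, 10, 20)))
#' tc <- rbind(tc, data.frame(gene_id = "SCR1", minutes = c(0, 5, 10, 20),
#'                            level = 1))
#' fitDecayCurve(tc)
#' @export
fitDecayCurve <- function(course, reference = NULL, slopeTolerance = 1e-10) {
  if (is(course, "DecayTimeCourse")) {
    if (is.null(reference)) reference <- metadata(course)$reference
    course <- as.data.frame(course)
  }
  if (is.null(reference)) reference <- "SCR1"
  stopifnot(all(c("gene_id", "minutes", "level") %in% colnames(course)))
  ref <- course[course$gene_id == reference, ]
  if (nrow(ref) == 0) stop("reference transcript '", reference, "' not found")
  refLevel <- ref$level[match(course$minutes, ref$minutes)]
  course$norm <- course$level / refLevel
  genes <- setdiff(unique(course$gene_id), reference)
  fit1 <- function(g) {
    d <- course[course$gene_id == g & is.finite(course$norm) &
                  course$norm > 0, ]
    n <- nrow(d)
    if (n < 3)
      return(list(NA_real_, NA_real_, NA_real_, n, "insufficient"))
    m <- lm(log(norm) ~ minutes, data = d)
    slope <- unname(coef(m)[2])
    sst <- sum((log(d$norm) - mean(log(d$norm)))^2)
    r2 <- if (sst == 0) 1 else 1 - sum(m$residuals^2) / sst
    if (abs(slope) <= slopeTolerance)
      return(list(Inf, slope, r2, n, "stable"))
    if (slope > slopeTolerance)
      return(list(NA_real_, slope, r2, n, "rejected"))
    list(log(2) / abs(slope), slope, r2, n, "ok")
  }
  res <- lapply(genes, fit1)
  DataFrame(gene_id = genes,
            half_life = vapply(res, function(x) x[[1]], 0),
            slope = vapply(res, function(x) x[[2]], 0),
            r_squared = vapply(res, function(x) x[[3]], 0),
            n_points = vapply(res, function(x) x[[4]], 0L),
            status = vapply(res, function(x) x[[5]], ""))
}

#' Spike-in normalization of count tables
#'
#' Scales each sample's counts by `referenceSpike / spikeCounts`, so that
#' samples with more spike-in reads (larger effective library) are scaled
#' down proportionally. With equal spike counts this is the identity.
#'
#' @param counts numeric vector (one sample) or gene-by-sample matrix.
#' @param spikeCounts positive spike-in read total(s), one per sample.
#' @param referenceSpike the spike-in total to normalize to (default: the
#'   mean of `spikeCounts`).
#' @return Normalized counts, same shape as `counts`.
#' @examples
#' spikeNormalize(c(a = 10, b = 20), spikeCounts = 4, referenceSpike = 2)
#' @export
spikeNormalize <- function(counts, spikeCounts,
                           referenceSpike = mean(spikeCounts)) {
  if (any(spikeCounts <= 0)) stop("spikeCounts must be > 0")
  if (is.matrix(counts)) {
    stopifnot(length(spikeCounts) == ncol(counts))
    sweep(counts, 2, referenceSpike / spikeCounts, `*`)
  } else {
    stopifnot(length(spikeCounts) == 1)
    counts * referenceSpike / spikeCounts
  }
}
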