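#' @importFrom stats phyper wilcox.test cor quantile var
NULL

#' Compute per-gene Kis values from two kinetics tables
#'
#' The Kis value of a gene quantifies how much blocking nuclear import of
#' the exonuclease affects its two kinetic parameters, as the sum of two
#' fold-changes: the half-life ratio `HL_mut / HL_wt` (stabilization) and
#' the inverse transcription-rate ratio `TR_wt / TR_mut` (synthesis
#' defect). Under perfect buffering the two terms are equal, and a gene
#' untouched by the perturbation scores 2 (1 + 1).
#'
#' Genes missing in either table, or with undefined half-life or
#' nonpositive TR/HL in either strain, are dropped with a message; the
#' count is stored in `metadata(x)$n_dropped`.
#'
#' @param wt,mut [KineticsTable]s for the wild-type and mutant strain.
#' @return A [KisTable] (with `is_kis` and `bin` set to `NA` until
#'   [classifyKis()] / [assignBins()] are applied).
#' @examples
#' wt <- KineticsTable("g1", "WT", TR = 2, RA = 4)
#' mut <- KineticsTable("g1", "dNLS12", TR = 1, RA = 4)
#' computeKisValues(wt, mut)
#' @export
computeKisValues <- function(wt, mut) {
  stopifnot(is(wt, "KineticsTable"), is(mut, "KineticsTable"))
  common <- intersect(wt$gene_id, mut$gene_id)
  w <- wt[match(common, wt$gene_id), ]
  m <- mut[match(common, mut$gene_id), ]
  ok <- !is.na(w$HL) & !is.na(m$HL) & w$TR > 0 & m$TR > 0 &
    w$HL > 0 & m$HL > 0
  nDropped <- length(union(wt$gene_id, mut$gene_id)) - sum(ok)
  if (nDropped > 0)
    message(nDropped, " gene(s) dropped from Kis scoring ",
            "(missing or undefined kinetics)")
  w <- w[ok, ]
  m <- m[ok, ]
  hl_ratio <- m$HL / w$HL
  tr_ratio_inv <- w$TR / m$TR
  out <- new("KisTable", DataFrame(
    gene_id = w$gene_id,
    hl_ratio = hl_ratio,
    tr_ratio_inv = tr_ratio_inv,
    kis_value = hl_ratio + tr_ratio_inv,
    is_kis = rep(NA, length(hl_ratio)),
    bin = rep(NA_integer_, length(hl_ratio))))
  metadata(out)$n_dropped <- nDropped
  out
}

#' Classify import-sensitive (Kis) mRNAs
#'
#' A gene is Kis if both its half-life and its synthesis rate are affected
#' at least `threshold`-fold by blocking import: `hl_ratio >= threshold`
#' AND `tr_ratio_inv >= threshold` (boundary inclusive). Returns the
#' updated table plus the three gene sets — half-life-affected,
#' synthesis-affected, and their intersection (the Kis set).
#'
#' @param table a [KisTable].
#' @param threshold fold-change threshold, `> 1` (default 2).
#' @return A list with `table` (the [KisTable] with `is_kis` filled),
#'   `hl_affected`, `tr_affected`, `kis` (character vectors of gene ids)
#'   and `counts` (named integer vector).
#' @examples
#' wt <- KineticsTable(c("g1", "g2"), "WT", TR = c(2, 2), RA = c(4, 4))
#' mut <- KineticsTable(c("g1", "g2"), "mut", TR = c(1, 2), RA = c(8, 4))
#' classifyKis(computeKisValues(wt, mut))$counts
#' @export
classifyKis <- function(table, threshold = 2) {
  stopifnot(is(table, "KisTable"))
  if (threshold <= 1) stop("threshold must be > 1")
  hlAff <- table$gene_id[table$hl_ratio >= threshold]
  trAff <- table$gene_id[table$tr_ratio_inv >= threshold]
  kis <- intersect(hlAff, trAff)
  table <- .setColumn(table, "is_kis", table$gene_id %in% kis)
  list(table = table,
       hl_affected = hlAff, tr_affected = trAff, kis = kis,
       counts = c(hl_affected = length(hlAff),
                  tr_affected = length(trAff),
                  kis = length(kis)))
}

#' Hypergeometric significance of a gene-set overlap
#'
#' Upper-tail hypergeometric probability of observing an intersection at
#' least as large as the one seen, when a set of size `|B|` is drawn
#' uniformly from a universe containing `|A|` marked genes.
#'
#' @param setA,setB character vectors of gene ids (or, if
#'   `overlap` is given, integer sizes `|A|` and `|B|`).
#' @param universeSize total number of genes in the universe.
#' @param overlap optional observed intersection size; computed from the
#'   sets when omitted.
#' @return The p-value `P(X >= overlap)`.
#' @examples
#' overlapSignificance(letters[1:5], letters[1:5], universeSize = 10)
#' @export
overlapSignificance <- function(setA, setB, universeSize, overlap = NULL) {
  if (is.null(overlap)) {
    a <- length(unique(setA)); b <- length(unique(setB))
    overlap <- length(intersect(setA, setB))
  } else {
    a <- setA; b <- setB
  }
  if (a > universeSize || b > universeSize)
    stop("set sizes cannot exceed the universe")
  if (overlap > min(a, b)) stop("overlap larger than the smaller set")
  phyper(overlap - 1, a, universeSize - a, b, lower.tail = FALSE)
}

#' Assign genes to equal-size bins by Kis value
#'
#' Genes are ranked by Kis value in descending order — bin 1 holds the
#' most affected mRNAs (highest Kis values) — and split into `nBins`
#' groups whose sizes differ by at most one (earlier bins take the
#' remainder). Ties are broken by gene id lexicographically, so the
#' assignment is deterministic.
#'
#' @param kisValues numeric vector of Kis values (or a [KisTable]).
#' @param nBins number of bins, between 1 and the number of genes.
#' @param geneIds gene ids for tie-breaking; taken from the table when a
#'   [KisTable] is supplied, else defaults to the element order.
#' @param ascending if `TRUE`, flip the orientation so bin 1 holds the
#'   lowest Kis values.
#' @return An integer vector of bin ids aligned with the input (or the
#'   [KisTable] with its `bin` column filled).
#' @examples
#' assignBins(1:12, nBins = 6)
#' @export
assignBins <- function(kisValues, nBins, geneIds = NULL, ascending = FALSE) {
  isTable <- is(kisValues, "KisTable")
  if (isTable) {
    tab <- kisValues
    geneIds <- tab$gene_id
    kisValues <- tab$kis_value
  }
  n <- length(kisValues)
  if (nBins < 1 || nBins > n) stop("nBins must be in [1, number of genes]")
  if (is.null(geneIds)) geneIds <- sprintf("%09d", seq_len(n))
  ord <- order(if (ascending) kisValues else -kisValues, geneIds)
  sizes <- rep(n %/% nBins, nBins) + (seq_len(nBins) <= n %% nBins)
  bins <- integer(n)
  bins[ord] <- rep(seq_len(nBins), times = sizes)
  if (isTable) .setColumn(tab, "bin", bins) else bins
}

#' Per-bin median summaries of log2 values
#'
#' Summarizes a log2-scale quantity (e.g. log2 half-life ratios) within
#' each bin: the median plus the quartiles used for box plotting.
#'
#' @param valuesLog2 numeric vector, already on the log2 scale.
#' @param bins integer bin ids aligned with `valuesLog2`.
#' @return A [S4Vectors::DataFrame] with columns `bin`, `n_genes`,
#'   `median`, `q25`, `q75`, ordered by bin.
#' @export
binSummary <- function(valuesLog2, bins) {
  stopifnot(length(valuesLog2) == length(bins))
  ids <- sort(unique(bins))
  DataFrame(
    bin = ids,
    n_genes = vapply(ids, function(b) sum(bins == b), 0L),
    median = vapply(ids, function(b) median(valuesLog2[bins == b]), 0),
    q25 = vapply(ids, function(b)
      unname(quantile(valuesLog2[bins == b], 0.25)), 0),
    q75 = vapply(ids, function(b)
      unname(quantile(valuesLog2[bins == b], 0.75)), 0))
}

#' Test mRNA-abundance buffering between strains
#'
#' Buffering predicts that although synthesis and decay are both
#' compromised in the import mutant, steady-state abundances are
#' unchanged. Compares the two abundance distributions with a two-sided
#' Wilcoxon rank-sum test and reports the medians.
#'
#' @param raWt,raMut numeric abundance vectors (a.u.), nonempty.
#' @return A list with `median_wt`, `median_mut`, `p_value`.
#' @export
bufferingTest <- function(raWt, raMut) {
  stopifnot(length(raWt) > 0, length(raMut) > 0)
  p <- suppressWarnings(
    wilcox.test(raMut, raWt, alternative = "two.sided", exact = FALSE))
  list(median_wt = median(raWt), median_mut = median(raMut),
       p_value = p$p.value)
}

#' Pearson correlation of log2 fold-change vectors
#'
#' The coupling of the synthesis and decay defects is assessed as the
#' Pearson correlation between two per-gene ratio vectors on the log2
#' scale (matching ratio scatter-plot axes).
#'
#' @param xRatios,yRatios aligned positive ratio vectors, `n >= 3`.
#' @return Pearson r of `log2(xRatios)` vs `log2(yRatios)`; `NA` when
#'   either vector is constant (zero variance, correlation undefined).
#' @export
correlateLogRatios <- function(xRatios, yRatios) {
  stopifnot(length(xRatios) == length(yRatios), length(xRatios) >= 3,
            all(is.finite(xRatios)), all(is.finite(yRatios)),
            all(xRatios > 0), all(yRatios > 0))
  lx <- log2(xRatios)
  ly <- log2(yRatios)
  if (var(lx) == 0 || var(ly) == 0) return(NA_real_)
  cor(lx, ly)
}
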