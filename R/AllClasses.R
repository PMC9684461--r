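#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<- mcols
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays colData
NULL

# replace one column on a DFrame subclass: S4Vectors' `$<-` does not
# dispatch cleanly on derived classes, so edit the plain DFrame and rebuild
.setColumn <- function(x, name, value) {
  df <- as(x, "DFrame", strict = TRUE)
  df[[name]] <- value
  new(class(x), df)
}

.checkColumns <- function(object, required) {
  missing <- setdiff(required, colnames(object))
  if (length(missing))
    return(sprintf("missing column(s): %s", paste(missing, collapse = ", ")))
  NULL
}

#' GeneTruth: ground-truth gene kinetics under the two-pathway decay model
#'
#' A per-gene table of the simulator's ground truth. Each gene carries a
#' wild-type synthesis rate `tr_wt` (arbitrary units/min) and its total
#' wild-type decay rate split between two pathways: `kd_cls`, the classical
#' cytoplasmic pathway that does not require nuclear import of the
#' exonuclease, and `kd_kis`, the import-sensitive (Kis) pathway that
#' initiates in the nucleus. `kd_exo` is the slower exosome-backup rate that
#' takes over when the exonuclease is deleted entirely.
#'
#' Invariants enforced by the validity method: `tr_wt > 0`,
#' `kd_cls > 0`, `kd_kis >= 0`, `kd_exo > 0`, and the Kis fraction
#' `f = kd_kis / (kd_cls + kd_kis)` lies in `[0, 1)`.
#'
#' @seealso [generateTruth()], [applyCondition()], [kisFraction()]
#' @export
setClass("GeneTruth", contains = "DFrame")

setValidity("GeneTruth", function(object) {
  msg <- .checkColumns(object, c("gene_id", "tr_wt", "kd_cls", "kd_kis", "kd_exo"))
  if (!is.null(msg)) return(msg)
  if (anyDuplicated(object$gene_id)) return("duplicated gene_id")
  if (any(object$tr_wt <= 0)) return("tr_wt must be > 0")
  if (any(object$kd_cls <= 0)) return("kd_cls must be > 0")
  if (any(object$kd_kis < 0)) return("kd_kis must be >= 0")
  if (any(object$kd_exo <= 0)) return("kd_exo must be > 0")
  f <- object$kd_kis / (object$kd_cls + object$kd_kis)
  if (any(f < 0 | f >= 1)) return("Kis fraction must lie in [0, 1)")
  TRUE
})

#' @rdname GeneTruth-class
#' @param gene_id character vector of unique gene identifiers.
#' @param tr_wt,kd_cls,kd_kis,kd_exo numeric vectors; see the class
#'   description for units and constraints.
#' @return A `GeneTruth` object.
#' @export
GeneTruth <- function(gene_id, tr_wt, kd_cls, kd_kis, kd_exo) {
  new("GeneTruth", DataFrame(gene_id = as.character(gene_id),
                             tr_wt = tr_wt, kd_cls = kd_cls,
                             kd_kis = kd_kis, kd_exo = kd_exo))
}

#' KineticsTable: per-gene TR, RA and HL for one strain
#'
#' The product of GRO-style steady-state inference: per-gene transcription
#' rate (`TR`, a.u./min), mRNA abundance (`RA`, a.u.) and half-life
#' (`HL = RA / TR`, a.u.), all replicate-aggregated, for a single strain.
#' `HL` is `NA` for genes whose aggregated `TR` is nonpositive or undefined.
#'
#' @seealso [groKinetics()], [computeHalfLife()]
#' @export
setClass("KineticsTable", contains = "DFrame")

setValidity("KineticsTable", function(object) {
  msg <- .checkColumns(object, c("gene_id", "strain", "TR", "RA", "HL"))
  if (!is.null(msg)) return(msg)
  ok <- !is.na(object$HL)
  if (any(ok & object$TR <= 0))
    return("TR must be > 0 wherever HL is defined")
  if (any(ok & abs(object$HL - object$RA / object$TR) >
            1e-8 * pmax(abs(object$HL), 1)))
    return("HL must equal RA / TR row-wise")
  TRUE
})

#' @rdname KineticsTable-class
#' @param gene_id,strain,TR,RA,HL column vectors (see class description).
#' @return A `KineticsTable`.
#' @export
KineticsTable <- function(gene_id, strain, TR, RA, HL = RA / TR) {
  new("KineticsTable", DataFrame(gene_id = as.character(gene_id),
                                 strain = as.character(strain),
                                 TR = TR, RA = RA, HL = HL))
}

#' KisTable: per-gene fold-changes, Kis value, classification and bin
#'
#' For each gene, the mutant/wild-type half-life ratio (`hl_ratio`), the
#' inverse transcription-rate ratio (`tr_ratio_inv` = TR_wt / TR_mut), their
#' sum the `kis_value`, the boolean `is_kis` classification (both ratios at
#' or above the fold-change threshold) and the equal-size `bin` assignment
#' (bin 1 = highest Kis values; `NA` before binning).
#'
#' @seealso [computeKisValues()], [classifyKis()], [assignBins()]
#' @export
setClass("KisTable", contains = "DFrame")

setValidity("KisTable", function(object) {
  msg <- .checkColumns(object,
    c("gene_id", "hl_ratio", "tr_ratio_inv", "kis_value", "is_kis", "bin"))
  if (!is.null(msg)) return(msg)
  if (any(object$kis_value < 0)) return("kis_value must be >= 0")
  bad <- abs(object$kis_value - (object$hl_ratio + object$tr_ratio_inv)) >
    1e-8 * pmax(object$kis_value, 1)
  if (any(bad, na.rm = TRUE))
    return("kis_value must equal hl_ratio + tr_ratio_inv row-wise")
  TRUE
})

#' DecayTimeCourse: gene levels vs minutes post transcription shutoff
#'
#' Long-format table with columns `gene_id`, `minutes` and `level` (a.u.).
#' The stable reference transcript used for loading normalization (a Pol III
#' transcript, SCR1 by default) is included as an ordinary row set; its name
#' is stored in `metadata(x)$reference`.
#'
#' @seealso [simulateShutoff()], [fitDecayCurve()]
#' @export
setClass("DecayTimeCourse", contains = "DFrame")

setValidity("DecayTimeCourse", function(object) {
  msg <- .checkColumns(object, c("gene_id", "minutes", "level"))
  if (!is.null(msg)) return(msg)
  if (any(object$minutes < 0)) return("minutes must be >= 0")
  if (!0 %in% object$minutes) return("timepoint 0 must be present")
  TRUE
})

#' @rdname DecayTimeCourse-class
#' @param gene_id,minutes,level column vectors (long format).
#' @param reference name of the stable reference transcript.
#' @return A `DecayTimeCourse`.
#' @export
DecayTimeCourse <- function(gene_id, minutes, level, reference = "SCR1") {
  out <- new("DecayTimeCourse",
             DataFrame(gene_id = as.character(gene_id),
                       minutes = minutes, level = level))
  metadata(out)$reference <- reference
  out
}

#' GroExperiment: a genomic run-on sample for one strain
#'
#' A [SummarizedExperiment::SummarizedExperiment] with two gene-by-replicate
#' assays: `ntr` (nascent transcription signal, a.u.) and `ra` (cDNA
#' hybridization mRNA-abundance signal, a.u.). `colData` holds the replicate
#' index; metadata records the strain, the cell-volume factor applied to the
#' signals, and the noise level used if simulated.
#'
#' @seealso [simulateGro()], [aggregateReplicates()], [groKinetics()]
#' @export
setClass("GroExperiment", contains = "SummarizedExperiment")

setValidity("GroExperiment", function(object) {
  if (!all(c("ntr", "ra") %in% names(SummarizedExperiment::assays(object))))
    return("assays 'ntr' and 'ra' are required")
  if (any(assay(object, "ntr") < 0) || any(assay(object, "ra") < 0))
    return("signals must be >= 0")
  TRUE
})

#' @rdname GroExperiment-class
#' @param ntr,ra gene-by-replicate signal matrices with rownames = gene ids.
#' @param strain strain/condition name.
#' @param cellVolume cell-volume scale factor baked into the signals.
#' @param sigmaNoise log-space noise s.d. used if simulated, else `NA`.
#' @return A `GroExperiment`.
#' @export
GroExperiment <- function(ntr, ra, strain, cellVolume = 1, sigmaNoise = NA_real_) {
  stopifnot(identical(dim(ntr), dim(ra)),
            identical(rownames(ntr), rownames(ra)))
  se <- SummarizedExperiment(
    assays = list(ntr = ntr, ra = ra),
    colData = S4Vectors::DataFrame(replicate = seq_len(ncol(ntr))))
  out <- new("GroExperiment", se)
  metadata(out)$strain <- strain
  metadata(out)$cell_volume <- cellVolume
  metadata(out)$sigma_noise <- sigmaNoise
  out
}

#' KineticModel: single-gene mRNA dynamics specification
#'
#' Deterministic linear kinetics `dM/dt = TR(t) - kd * M` with a
#' piecewise-constant transcription-rate schedule. `trTimes` are the segment
#' start times (minutes, first must be 0, strictly increasing) and
#' `trValues` the TR (a.u./min) holding from each start time onward.
#'
#' @slot trTimes numeric, segment start times.
#' @slot trValues numeric, TR per segment.
#' @slot kd numeric(1), decay rate in 1/min, `> 0`.
#' @slot M0 numeric(1), initial mRNA level, `>= 0`.
#' @seealso [simulateResponse()], [steadyState()], [responseHalftime()]
#' @export
setClass("KineticModel",
         representation(trTimes = "numeric", trValues = "numeric",
                        kd = "numeric", M0 = "numeric"))

setValidity("KineticModel", function(object) {
  if (length(object@trTimes) != length(object@trValues))
    return("trTimes and trValues must have equal length")
  if (length(object@trTimes) < 1 || object@trTimes[1] != 0)
    return("schedule must start at time 0")
  if (is.unsorted(object@trTimes, strictly = TRUE))
    return("trTimes must be strictly increasing")
  if (any(object@trValues < 0)) return("TR must be >= 0")
  if (length(object@kd) != 1 || object@kd <= 0) return("kd must be a positive scalar")
  if (length(object@M0) != 1 || object@M0 < 0) return("M0 must be >= 0")
  TRUE
})

#' @rdname KineticModel-class
#' @param trTimes,trValues,kd,M0 see slots.
#' @return A `KineticModel`.
#' @export
KineticModel <- function(trTimes = 0, trValues, kd, M0 = trValues[1] / kd) {
  new("KineticModel", trTimes = as.numeric(trTimes),
      trValues = as.numeric(trValues), kd = as.numeric(kd),
      M0 = as.numeric(M0))
}

setMethod("show", "KineticModel", function(object) {
  cat("KineticModel: kd =", object@kd, "/min, M0 =", object@M0, "\n")
  cat("  TR schedule:",
      paste(sprintf("t>=%g: %g", object@trTimes, object@trValues),
            collapse = "; "), "\n")
})
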