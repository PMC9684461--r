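#' @importFrom utils read.delim write.table
#' @importFrom rtracklayer export.bed import.bed
#' @importFrom jsonlite write_json
#' @importFrom yaml read_yaml
NULL

.writeTsv <- function(x, path) {
  write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

.readTsv <- function(path) {
  read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}

#' Read and write the package's tab-separated tables
#'
#' All tabular outputs are TSV with a single header row and a stable
#' column order, so every file round-trips through its reader to the same
#' in-memory table. `writeKineticsTable`/`readKineticsTable` handle the
#' per-gene TR/RA/HL table; `writeKisTable`/`readKisTable` the Kis scoring
#' table; `writeDecayCourse`/`readDecayCourse` the long-format shutoff
#' course; `writeGroSample`/`readGroSample` the gene-by-replicate GRO
#' signals in long format (columns strain, gene_id, replicate, ntr, ra).
#'
#' @param x the object to write.
#' @param path file path.
#' @return Readers return the reconstructed object; writers the path,
#'   invisibly.
#' @name table-io
NULL

#' @rdname table-io
#' @export
writeKineticsTable <- function(x, path) {
  stopifnot(is(x, "KineticsTable"))
  .writeTsv(x[, c("gene_id", "strain", "TR", "RA", "HL")], path)
}

#' @rdname table-io
#' @export
readKineticsTable <- function(path) {
  d <- .readTsv(path)
  KineticsTable(d$gene_id, d$strain, d$TR, d$RA, d$HL)
}

#' @rdname table-io
#' @export
writeKisTable <- function(x, path) {
  stopifnot(is(x, "KisTable"))
  .writeTsv(x[, c("gene_id", "hl_ratio", "tr_ratio_inv", "kis_value",
                  "is_kis", "bin")], path)
}

#' @rdname table-io
#' @export
readKisTable <- function(path) {
  d <- .readTsv(path)
  new("KisTable", DataFrame(
    gene_id = as.character(d$gene_id), hl_ratio = d$hl_ratio,
    tr_ratio_inv = d$tr_ratio_inv, kis_value = d$kis_value,
    is_kis = as.logical(d$is_kis), bin = as.integer(d$bin)))
}

#' @rdname table-io
#' @export
writeTruthTable <- function(x, path) {
  stopifnot(is(x, "GeneTruth"))
  .writeTsv(x[, c("gene_id", "tr_wt", "kd_cls", "kd_kis", "kd_exo")], path)
}

#' @rdname table-io
#' @export
readTruthTable <- function(path) {
  d <- .readTsv(path)
  GeneTruth(d$gene_id, d$tr_wt, d$kd_cls, d$kd_kis, d$kd_exo)
}

#' @rdname table-io
#' @export
writeDecayCourse <- function(x, path) {
  stopifnot(is(x, "DecayTimeCourse"))
  .writeTsv(x[, c("gene_id", "minutes", "level")], path)
}

#' @rdname table-io
#' @param reference stable reference transcript id.
#' @export
readDecayCourse <- function(path, reference = "SCR1") {
  d <- .readTsv(path)
  DecayTimeCourse(d$gene_id, d$minutes, d$level, reference = reference)
}

#' @rdname table-io
#' @export
writeGroSample <- function(x, path) {
  stopifnot(is(x, "GroExperiment"))
  ntr <- assay(x, "ntr"); ra <- assay(x, "ra")
  long <- data.frame(
    strain = metadata(x)$strain,
    gene_id = rep(rownames(ntr), ncol(ntr)),
    replicate = rep(seq_len(ncol(ntr)), each = nrow(ntr)),
    ntr = as.vector(ntr), ra = as.vector(ra))
  .writeTsv(long, path)
}

#' @rdname table-io
#' @param cellVolume,sigmaNoise metadata to attach on read.
#' @export
readGroSample <- function(path, cellVolume = 1, sigmaNoise = NA_real_) {
  d <- .readTsv(path)
  genes <- unique(d$gene_id)
  reps <- sort(unique(d$replicate))
  shape <- function(col) {
    m <- matrix(NA_real_, length(genes), length(reps),
                dimnames = list(genes, paste0("rep", reps)))
    m[cbind(match(d$gene_id, genes), match(d$replicate, reps))] <- d[[col]]
    m
  }
  GroExperiment(shape("ntr"), shape("ra"), strain = d$strain[1],
                cellVolume = cellVolume, sigmaNoise = sigmaNoise)
}

#' Write and read primary polyadenylation sites as BED
#'
#' Sites are single-base intervals; BED is 0-based half-open, and the
#' conversion is handled by rtracklayer. The BED name field carries the
#' gene id.
#'
#' @param sites a [GenomicRanges::GRanges] with a `gene_id` column.
#' @param path file path.
#' @return `readPolyASites` returns a GRanges with `gene_id` restored.
#' @export
writePolyASites <- function(sites, path) {
  stopifnot(is(sites, "GRanges"), !is.null(sites$gene_id))
  out <- sites
  out$name <- out$gene_id
  out$gene_id <- NULL
  rtracklayer::export.bed(out, path)
  invisible(path)
}

#' @rdname writePolyASites
#' @export
readPolyASites <- function(path) {
  gr <- rtracklayer::import.bed(path)
  gr$gene_id <- gr$name
  names(gr) <- gr$gene_id
  gr
}

#' @rdname table-io
#' @export
writeReadRecords <- function(x, path) {
  .writeTsv(as.data.frame(x)[, c("read_id", "gene_id", "distance_bp",
                                 "trailing_A")], path)
}

#' @rdname table-io
#' @export
readReadRecords <- function(path) {
  d <- .readTsv(path)
  DataFrame(read_id = as.character(d$read_id),
            gene_id = as.character(d$gene_id),
            distance_bp = as.integer(d$distance_bp),
            trailing_A = as.integer(d$trailing_A))
}

# deterministic per-stage seed derived from the one global run seed
.substreamSeed <- function(seed, stage) {
  if (is.null(seed)) return(NULL)
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 48271 + h * 10007) %% 2147483647)
}

#' Validate and normalize a pipeline run configuration
#'
#' A run configuration is a named list (or a YAML file holding one) with
#' fields `preset`, `n_genes`, `conditions` (strain names; the first
#' non-WT one is scored against WT), `n_replicates`, `sigma_noise`,
#' `cell_volume` (scalar or one per condition), `n_bins`, `threshold`,
#' `seed`, and optional `import_efficiency`/`buffering_strength`
#' overrides and `output_dir`. Every field is checked against its schema
#' before any stage runs; defaults fill the gaps.
#'
#' @param config a named list or a path to a YAML file.
#' @return The validated configuration list, class `RunConfig`.
#' @export
runConfig <- function(config = list()) {
  if (is.character(config) && length(config) == 1)
    config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  defaults <- list(preset = "headline", n_genes = 5000L,
                   conditions = c("WT", "dNLS12"), n_replicates = 3L,
                   sigma_noise = 0.2, cell_volume = 1, n_bins = 6L,
                   threshold = 2, seed = 1L,
                   import_efficiency = NULL, buffering_strength = 1,
                   output_dir = NULL)
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown))
    stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  cfg <- modifyList(defaults, config[!vapply(config, is.null, TRUE)])
  if (!cfg$preset %in% c("headline", "uniform", "null"))
    stop("preset must be headline, uniform or null")
  if (cfg$n_genes < 1) stop("n_genes must be >= 1")
  allowed <- c("WT", "dNLS1", "dNLS2", "dNLS12", "dKAP120", "dXRN1")
  if (!all(cfg$conditions %in% allowed))
    stop("conditions must be a subset of: ", paste(allowed, collapse = ", "))
  if (!"WT" %in% cfg$conditions || length(cfg$conditions) < 2)
    stop("conditions must include WT and at least one mutant")
  if (cfg$n_replicates < 1) stop("n_replicates must be >= 1")
  if (cfg$sigma_noise < 0) stop("sigma_noise must be >= 0")
  if (any(cfg$cell_volume <= 0)) stop("cell_volume must be > 0")
  if (!length(cfg$cell_volume) %in% c(1, length(cfg$conditions)))
    stop("cell_volume must be scalar or one per condition")
  if (cfg$n_bins < 1 || cfg$n_bins > cfg$n_genes) stop("invalid n_bins")
  if (cfg$threshold <= 1) stop("threshold must be > 1")
  structure(cfg, class = "RunConfig")
}

#' Run the full synthesis-decay analysis pipeline
#'
#' Chains the whole desk study end to end: generate ground truth, apply
#' each condition, simulate GRO measurements, infer per-strain kinetics
#' (TR, RA, HL), score Kis values of the first mutant against WT,
#' classify at the fold-change threshold, bin, summarize per bin, test
#' abundance buffering, and correlate the log2 synthesis and decay
#' defects. All randomness flows from the single configured seed through
#' named per-stage substreams, so identical configurations give identical
#' outputs. When `output_dir` is set, every table is written as TSV and
#' the report as JSON.
#'
#' @param config a [runConfig()] (or the list/YAML path to build one).
#' @return A list: `truth`, `kinetics` (named list of [KineticsTable]s),
#'   `kis` (the binned [KisTable]), `bin_summary`, `report` (affected-set
#'   counts, overlap p, median ratios, buffering medians and p,
#'   correlation), and `config`.
#' @examples
#' res <- runPipeline(runConfig(list(n_genes = 200, seed = 7)))
#' res$report$counts
#' @export
runPipeline <- function(config = runConfig()) {
  if (!inherits(config, "RunConfig")) config <- runConfig(config)
  cfg <- config
  truth <- generateTruth(cfg$n_genes, preset = cfg$preset,
                         seed = .substreamSeed(cfg$seed, "truth"))
  vols <- if (length(cfg$cell_volume) == 1)
    rep(cfg$cell_volume, length(cfg$conditions)) else cfg$cell_volume
  names(vols) <- cfg$conditions
  kinetics <- list()
  for (cn in cfg$conditions) {
    cond <- conditionSpec(cn,
      importEfficiency = if (cn == "WT") 1 else cfg$import_efficiency,
      bufferingStrength = cfg$buffering_strength)
    prof <- applyCondition(truth, cond)
    gro <- simulateGro(prof, measurementConfig(
      nReplicates = cfg$n_replicates, sigmaNoise = cfg$sigma_noise,
      cellVolume = vols[[cn]],
      seed = .substreamSeed(cfg$seed, paste0("gro_", cn))))
    kinetics[[cn]] <- groKinetics(gro)
  }
  mutName <- setdiff(cfg$conditions, "WT")[1]
  kis <- computeKisValues(kinetics[["WT"]], kinetics[[mutName]])
  cls <- classifyKis(kis, threshold = cfg$threshold)
  kis <- assignBins(cls$table, nBins = cfg$n_bins)
  bs <- binSummary(log2(kis$hl_ratio), kis$bin)
  bsTr <- binSummary(log2(kis$tr_ratio_inv), kis$bin)
  idx <- match(kis$gene_id, kinetics[["WT"]]$gene_id)
  buf <- bufferingTest(kinetics[["WT"]]$RA[idx],
                       kinetics[[mutName]]$RA[idx])
  report <- list(
    mutant = mutName,
    n_genes_scored = nrow(kis),
    n_dropped = metadata(kis)$n_dropped,
    counts = as.list(cls$counts),
    overlap_p = overlapSignificance(cls$hl_affected, cls$tr_affected,
                                    universeSize = nrow(kis)),
    median_hl_ratio = median(kis$hl_ratio),
    median_tr_ratio_inv = median(kis$tr_ratio_inv),
    median_kis_value = median(kis$kis_value),
    buffering = buf,
    cor_log2_hl_vs_tr = correlateLogRatios(kis$hl_ratio, kis$tr_ratio_inv),
    seed = cfg$seed)
  out <- list(truth = truth, kinetics = kinetics, kis = kis,
              bin_summary = bs, bin_summary_tr = bsTr, report = report,
              config = cfg)
  if (!is.null(cfg$output_dir)) {
    dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
    op <- function(f) file.path(cfg$output_dir, f)
    writeTruthTable(truth, op("truth.tsv"))
    for (cn in names(kinetics))
      writeKineticsTable(kinetics[[cn]], op(sprintf("kinetics_%s.tsv", cn)))
    writeKisTable(kis, op("kis.tsv"))
    .writeTsv(bs, op("bin_summary_hl.tsv"))
    .writeTsv(bsTr, op("bin_summary_tr.tsv"))
    jsonlite::write_json(report, op("report.json"), auto_unbox = TRUE,
                         digits = NA)
  }
  out
}
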