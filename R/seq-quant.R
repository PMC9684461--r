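#' @importFrom Biostrings readDNAStringSet
NULL

#' Select poly(A) reads by trailing-adenine count
#'
#' Reads whose 3' homopolymer contains more than `minAExclusive` adenines
#' represent mainly full-length mRNAs (degradation intermediates usually
#' carry 10 or fewer); the filter is strict, so the default keeps reads
#' with 16 or more trailing As.
#'
#' @param reads a DataFrame/data.frame of read records with a
#'   `trailing_A` column.
#' @param minAExclusive strict lower bound on trailing As (default 15,
#'   i.e. keep `trailing_A > 15`). Must be `>= 0`.
#' @return The filtered reads, same class as the input.
#' @examples
#' r <- data.frame(read_id = c("a", "b"), trailing_A = c(15, 16))
#' filterPolyaReads(r)
#' @export
filterPolyaReads <- function(reads, minAExclusive = 15) {
  if (minAExclusive < 0) stop("minAExclusive must be >= 0")
  stopifnot("trailing_A" %in% colnames(reads))
  reads[reads$trailing_A > minAExclusive, , drop = FALSE]
}

#' Count reads within a window around primary polyadenylation sites
#'
#' For each annotated gene, counts the reads mapping within `windowBp` of
#' its primary polyA site. The window is symmetric and inclusive:
#' `|distance_bp| <= windowBp`. With `upstreamOnly = TRUE` only reads at
#' or upstream of the site (`-windowBp <= distance_bp <= 0`) are counted.
#' Genes with no reads are still emitted with count 0.
#'
#' @param reads read records with columns `gene_id` and `distance_bp`
#'   (signed bp, mapped position minus site position).
#' @param sites a [GenomicRanges::GRanges] from [makePolyASites()] /
#'   [readPolyASites()], or anything with a `gene_id` column/metadata —
#'   defines the gene universe. Every read's gene must be annotated.
#' @param windowBp window half-width in bp, `>= 0` (default 250).
#' @param upstreamOnly restrict to reads upstream of the site.
#' @return A named integer vector of per-gene counts, in site order.
#' @examples
#' sites <- makePolyASites(c("g1", "g2"))
#' r <- data.frame(gene_id = c("g1", "g1", "g2"),
#'                 distance_bp = c(0, 251, -250), trailing_A = 20)
#' countNearPolya(r, sites)
#' @export
countNearPolya <- function(reads, sites, windowBp = 250,
                           upstreamOnly = FALSE) {
  if (windowBp < 0) stop("windowBp must be >= 0")
  geneIds <- if (is(sites, "GRanges")) sites$gene_id
             else as.character(sites$gene_id)
  if (anyDuplicated(geneIds))
    stop("one primary site per gene expected")
  stopifnot(all(c("gene_id", "distance_bp") %in% colnames(reads)))
  if (!all(reads$gene_id %in% geneIds))
    stop("reads refer to genes absent from the site annotation")
  keep <- if (upstreamOnly)
    reads$distance_bp >= -windowBp & reads$distance_bp <= 0
  else
    abs(reads$distance_bp) <= windowBp
  tab <- table(factor(reads$gene_id[keep], levels = geneIds))
  counts <- as.integer(tab)
  names(counts) <- geneIds
  counts
}

#' Sum count tables across replicates
#'
#' Per-gene counts from replicate libraries are added together
#' element-wise. All tables must cover the identical gene universe.
#'
#' @param countTables a list of named numeric vectors (or a single one).
#' @return The element-wise sum, a named vector in the first table's
#'   gene order.
#' @export
sumReplicates <- function(countTables) {
  if (!is.list(countTables)) countTables <- list(countTables)
  if (length(countTables) == 0) stop("no count tables supplied")
  genes <- names(countTables[[1]])
  for (tab in countTables)
    if (!setequal(names(tab), genes))
      stop("count tables must share an identical gene universe")
  Reduce(`+`, lapply(countTables, function(tab) tab[genes]))
}

#' Reads per kilobase per million mapped reads
#'
#' `RPKM = count / (length_kb * total_mapped_millions)`.
#'
#' @param counts per-gene read counts.
#' @param geneLengthsBp transcript lengths in bp, all `> 0`.
#' @param totalMapped total mapped reads in the library, `> 0`.
#' @return Per-gene RPKM values.
#' @examples
#' rpkm(10, geneLengthsBp = 1000, totalMapped = 1e6)
#' @export
rpkm <- function(counts, geneLengthsBp, totalMapped) {
  if (any(geneLengthsBp <= 0)) stop("gene lengths must be > 0")
  if (totalMapped <= 0) stop("totalMapped must be > 0")
  counts / ((geneLengthsBp / 1000) * (totalMapped / 1e6))
}

#' Centered per-bin medians of count log2 fold-changes
#'
#' Computes per-gene `log2((mut + pseudocount) / (wt + pseudocount))`,
#' centers by subtracting the global median over all genes, and reports
#' the median within each predefined Kis bin. After centering the global
#' median is exactly 0 regardless of input scale, so bins are compared
#' relative to the transcriptome-wide behaviour.
#'
#' @param countsMut,countsWt aligned per-gene count vectors.
#' @param bins integer bin ids aligned with the counts.
#' @param pseudocount added to both counts before the ratio (default 0.5).
#' @return A list with `per_gene` (centered log2 fold-changes) and
#'   `bin_medians` (a [S4Vectors::DataFrame]: `bin`, `n_genes`, `median`,
#'   `q25`, `q75`).
#' @export
binnedLog2fc <- function(countsMut, countsWt, bins, pseudocount = 0.5) {
  if (length(countsMut) != length(countsWt) ||
      length(countsMut) != length(bins))
    stop("counts and bins must be aligned")
  if (!is.null(names(countsMut)) && !is.null(names(countsWt)) &&
      !identical(names(countsMut), names(countsWt)))
    stop("count vectors are not aligned by gene")
  lfc <- log2((countsMut + pseudocount) / (countsWt + pseudocount))
  centered <- lfc - median(lfc)
  list(per_gene = centered, bin_medians = binSummary(centered, bins))
}

#' Correlation of two RPKM profiles on the log scale
#'
#' Pearson r of `log2(RPKM + pseudocount)` between two binding profiles
#' (e.g. full-length protein vs an isolated domain), as used for RNA
#' interactome comparisons.
#'
#' @param rpkmA,rpkmB aligned nonnegative RPKM vectors.
#' @param pseudocount added before the log (default 0.5).
#' @return Pearson r.
#' @export
cracRpkmCorrelation <- function(rpkmA, rpkmB, pseudocount = 0.5) {
  stopifnot(length(rpkmA) == length(rpkmB), length(rpkmA) >= 3,
            all(rpkmA + pseudocount > 0), all(rpkmB + pseudocount > 0))
  cor(log2(rpkmA + pseudocount), log2(rpkmB + pseudocount))
}

#' Extract trailing-adenine counts from a FASTQ file
#'
#' Reads a plain (uncompressed, 4-line) FASTQ file and reports, per read,
#' the length of the 3'-terminal adenine homopolymer — the quantity the
#' poly(A) read filter consumes. Qualities are ignored.
#'
#' @param path path to a FASTQ file.
#' @return A [S4Vectors::DataFrame] with `read_id` and `trailing_A`.
#' @export
trailingAFromFastq <- function(path) {
  seqs <- readDNAStringSet(path, format = "fastq")
  chars <- as.character(seqs)
  m <- regexpr("A+$", chars)
  trailing <- ifelse(m == -1L, 0L, attr(m, "match.length"))
  ids <- sub("\\s.*$", "", names(seqs))
  DataFrame(read_id = ids, trailing_A = as.integer(trailing))
}
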