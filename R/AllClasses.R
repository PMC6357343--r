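#' @import methods
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors isSorted
NULL

## Canonical relationship category codes, in classification priority order
## (most specific overlap first); "intergenic" is the fall-through.
## "sense_overlap" is a legacy display label found in published Arraystar
## panels: the fixture reader maps it, the classifier never emits it.
.CATEGORIES <- c("exon_sense_overlapping", "intron_sense_overlapping",
                 "intronic_antisense", "natural_antisense",
                 "bidirectional", "intergenic")
.LEGACY_CATEGORIES <- c(.CATEGORIES, "sense_overlap")

#' Relationship category codes
#'
#' The six positional relationship categories a lncRNA can have to a
#' coding transcript, in the priority order used by [classifyPair()]:
#' exon sense-overlapping, intron sense-overlapping, intronic antisense,
#' natural antisense, bidirectional, and intergenic.
#'
#' @param legacy logical; if `TRUE`, append `"sense_overlap"`, a legacy
#'   display label that occurs in published Arraystar biomarker panels
#'   but is never emitted by the classifier.
#' @return Character vector of category codes.
#' @export
#' @examples
#' relationshipCategories()
relationshipCategories <- function(legacy = FALSE) {
  if (legacy) .LEGACY_CATEGORIES else .CATEGORIES
}

# ---------------------------------------------------------------------------
# TranscriptModel
# ---------------------------------------------------------------------------

#' TranscriptModel: a stranded, exon-structured transcript
#'
#' The unit consumed by the positional classifier: a transcript on one
#' chromosome with an ordered, disjoint exon structure and a biotype
#' (`"mRNA"` or `"lncRNA"`). Coordinates are 1-based, fully closed
#' (GTF convention) throughout the package.
#'
#' @slot transcriptId single character, unique transcript identifier.
#' @slot geneId single character, identifier of the parent gene.
#' @slot chrom single character, chromosome name.
#' @slot strand `"+"` or `"-"`.
#' @slot exons an [IRanges::IRanges] of exon intervals, sorted ascending,
#'   non-overlapping, at least one exon.
#' @slot biotype `"mRNA"` or `"lncRNA"`.
#'
#' @aliases TranscriptModel-class
#' @export TranscriptModel
#' @exportClass TranscriptModel
TranscriptModel <- setClass("TranscriptModel",
  representation(
    transcriptId = "character",
    geneId       = "character",
    chrom        = "character",
    strand       = "character",
    exons        = "IRanges",
    biotype      = "character"
  )
)

setValidity("TranscriptModel", function(object) {
  msg <- character()
  for (s in c("transcriptId", "geneId", "chrom", "strand", "biotype"))
    if (length(slot(object, s)) != 1L || is.na(slot(object, s)))
      msg <- c(msg, sprintf("slot '%s' must be a single non-NA string", s))
  if (length(object@strand) == 1L && !object@strand %in% c("+", "-"))
    msg <- c(msg, "strand must be '+' or '-'")
  if (length(object@biotype) == 1L && !object@biotype %in% c("mRNA", "lncRNA"))
    msg <- c(msg, "biotype must be 'mRNA' or 'lncRNA'")
  ex <- object@exons
  if (length(ex) == 0L) {
    msg <- c(msg, "at least one exon is required")
  } else {
    if (any(IRanges::start(ex) > IRanges::end(ex)))
      msg <- c(msg, "every exon must satisfy start <= end")
    if (is.unsorted(IRanges::start(ex)))
      msg <- c(msg, "exons must be sorted by start position")
    if (length(ex) > 1L &&
        any(IRanges::start(ex)[-1L] <= IRanges::end(ex)[-length(ex)]))
      msg <- c(msg, "exons must be non-overlapping and non-adjacent-overlapping")
    if (any(IRanges::start(ex) < 1L))
      msg <- c(msg, "coordinates are 1-based; exon start < 1")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a TranscriptModel
#'
#' @param transcriptId,geneId,chrom,strand,biotype see
#'   [TranscriptModel-class].
#' @param exons exon intervals: an [IRanges::IRanges], or a two-column
#'   matrix / data.frame of (start, end). Exons are sorted by start.
#' @return A validated [TranscriptModel-class] object.
#' @export
#' @examples
#' tx <- transcriptModel("tx1", "g1", "chr1", "+",
#'                       cbind(c(100, 300), c(200, 400)), "mRNA")
#' txSpan(tx)
transcriptModel <- function(transcriptId, geneId = transcriptId, chrom,
                            strand, exons, biotype) {
  if (!methods::is(exons, "IRanges")) {
    exons <- as.matrix(exons)
    exons <- IRanges::IRanges(start = as.integer(exons[, 1L]),
                              end = as.integer(exons[, 2L]))
  }
  exons <- exons[order(IRanges::start(exons))]
  methods::new("TranscriptModel", transcriptId = as.character(transcriptId),
               geneId = as.character(geneId), chrom = as.character(chrom),
               strand = as.character(strand), exons = exons,
               biotype = as.character(biotype))
}

#' @describeIn transcriptModel transcript identifier
#' @param x a `TranscriptModel`
#' @export
transcriptId <- function(x) x@transcriptId

#' @describeIn transcriptModel parent gene identifier
#' @export
geneId <- function(x) x@geneId

#' @describeIn transcriptModel exon intervals as an IRanges
#' @export
exonRanges <- function(x) x@exons

#' @describeIn transcriptModel transcript biotype ("mRNA" or "lncRNA")
#' @export
txBiotype <- function(x) x@biotype

#' @describeIn transcriptModel chromosome name
#' @export
txChrom <- function(x) x@chrom

#' @describeIn transcriptModel strand ("+" or "-")
#' @export
txStrand <- function(x) x@strand

#' @describeIn transcriptModel genomic span (first exon start to last
#'   exon end) as a length-1 IRanges
#' @export
txSpan <- function(x) {
  IRanges::IRanges(start = min(IRanges::start(x@exons)),
                   end = max(IRanges::end(x@exons)))
}

#' @describeIn transcriptModel transcription start site: span start on
#'   the + strand, span end on the - strand
#' @export
txTSS <- function(x) {
  if (x@strand == "+") min(IRanges::start(x@exons))
  else max(IRanges::end(x@exons))
}

#' @describeIn transcriptModel intron intervals (gaps between exons
#'   within the span); empty IRanges for single-exon transcripts
#' @export
intronRanges <- function(x) {
  IRanges::gaps(IRanges::reduce(x@exons),
                start = min(IRanges::start(x@exons)),
                end = max(IRanges::end(x@exons)))
}

setMethod("show", "TranscriptModel", function(object) {
  sp <- txSpan(object)
  cat(sprintf("TranscriptModel %s (%s, %s) %s:%d-%d [%s], %d exon(s)\n",
              object@transcriptId, object@geneId, object@biotype,
              object@chrom, IRanges::start(sp), IRanges::end(sp),
              object@strand, length(object@exons)))
})

# ---------------------------------------------------------------------------
# ExpressionStudy
# ---------------------------------------------------------------------------

#' ExpressionStudy: a grouped feature-by-sample expression matrix
#'
#' A [SummarizedExperiment::SummarizedExperiment] with a single `exprs`
#' assay, a per-sample `group` column (`"tumor"` / `"normal"`) in
#' `colData`, and a platform tag (`"microarray"` or `"rnaseq"`) in
#' `metadata(x)$platform`. Microarray-style values must be strictly
#' positive so the Box-Cox transform is defined.
#'
#' @aliases ExpressionStudy-class
#' @export
#' @exportClass ExpressionStudy
setClass("ExpressionStudy", contains = "SummarizedExperiment")

setValidity("ExpressionStudy", function(object) {
  msg <- character()
  if (!"exprs" %in% SummarizedExperiment::assayNames(object))
    return("assay 'exprs' is required")
  v <- SummarizedExperiment::assay(object, "exprs")
  if (anyNA(v)) msg <- c(msg, "missing values are not allowed")
  cd <- SummarizedExperiment::colData(object)
  if (!"group" %in% colnames(cd)) {
    msg <- c(msg, "colData must contain a 'group' column")
  } else {
    g <- as.character(cd$group)
    if (!all(g %in% c("tumor", "normal")))
      msg <- c(msg, "groups must be 'tumor' or 'normal'")
    if (any(table(factor(g, levels = c("tumor", "normal"))) < 2L))
      msg <- c(msg, "each group needs at least 2 samples")
  }
  pl <- S4Vectors::metadata(object)$platform
  if (is.null(pl) || !pl %in% c("microarray", "rnaseq"))
    msg <- c(msg, "metadata 'platform' must be 'microarray' or 'rnaseq'")
  if (length(msg)) msg else TRUE
})

#' Construct an ExpressionStudy
#'
#' @param values numeric matrix, features in rows, samples in columns.
#' @param groups character vector of per-sample labels, `"tumor"` or
#'   `"normal"`, length `ncol(values)`.
#' @param platform `"microarray"` or `"rnaseq"`.
#' @param featureIds,sampleIds optional dimnames; taken from `values`
#'   when omitted.
#' @return An [ExpressionStudy-class].
#' @export
#' @examples
#' m <- matrix(rlnorm(40), nrow = 4,
#'             dimnames = list(paste0("f", 1:4), paste0("s", 1:10)))
#' es <- expressionStudy(m, rep(c("tumor", "normal"), each = 5), "microarray")
#' sampleGroups(es)
expressionStudy <- function(values, groups, platform = c("microarray", "rnaseq"),
                            featureIds = rownames(values),
                            sampleIds = colnames(values)) {
  platform <- match.arg(platform)
  values <- as.matrix(values)
  if (is.null(featureIds))
    featureIds <- sprintf("feature%03d", seq_len(nrow(values)))
  if (is.null(sampleIds))
    sampleIds <- sprintf("sample%03d", seq_len(ncol(values)))
  stopifnot(length(featureIds) == nrow(values),
            length(sampleIds) == ncol(values),
            length(groups) == ncol(values))
  dimnames(values) <- list(featureIds, sampleIds)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(exprs = values),
    colData = S4Vectors::DataFrame(group = as.character(groups),
                                   row.names = sampleIds),
    metadata = list(platform = platform))
  methods::new("ExpressionStudy", se)
}

#' @describeIn expressionStudy the expression matrix (features x samples)
#' @param x an `ExpressionStudy`
#' @export
exprValues <- function(x) SummarizedExperiment::assay(x, "exprs")

#' @describeIn expressionStudy per-sample group labels
#' @export
sampleGroups <- function(x)
  as.character(SummarizedExperiment::colData(x)$group)

#' @describeIn expressionStudy platform tag
#' @export
platformName <- function(x) S4Vectors::metadata(x)$platform

setMethod("show", "ExpressionStudy", function(object) {
  g <- table(factor(sampleGroups(object), levels = c("tumor", "normal")))
  cat(sprintf("ExpressionStudy (%s): %d features x %d samples (%d tumor, %d normal)\n",
              platformName(object), nrow(object), ncol(object),
              g[["tumor"]], g[["normal"]]))
})
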