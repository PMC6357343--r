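#' Read transcript models from a GTF file
#'
#' Parses a GTF annotation into a list of [TranscriptModel-class]
#' objects, one per `transcript_id`, taking the biotype from the
#' `gene_biotype` attribute (`protein_coding` maps to `"mRNA"`,
#' `lncRNA` to `"lncRNA"`). Only `exon` features are used; exons are
#' sorted and validated per transcript.
#'
#' @param path path to a GTF file.
#' @return Named list of [TranscriptModel-class] objects (names are
#'   transcript ids). An empty file yields an empty list with a warning.
#' @export
#' @seealso [writeTranscripts()] for the inverse operation.
readTranscripts <- function(path) {
  stopifnot(file.exists(path))
  if (length(readLines(path, n = 1L)) == 0L) {
    warning("GTF file '", path, "' contains no features")
    return(list())
  }
  gr <- tryCatch(rtracklayer::import(path, format = "gtf"),
                 error = function(e) stop("failed to parse GTF '", path,
                                          "': ", conditionMessage(e)))
  if (length(gr) == 0L) {
    warning("GTF file '", path, "' contains no features")
    return(list())
  }
  ex <- gr[gr$type == "exon"]
  if (length(ex) == 0L)
    stop("GTF file '", path, "' has no exon features")
  str <- as.character(GenomicRanges::strand(ex))
  if (any(str == "*")) {
    bad <- which(str == "*")[1L]
    stop("unknown strand '*' for exon of transcript '",
         ex$transcript_id[bad], "' in '", path, "'")
  }
  if (is.null(ex$transcript_id) || anyNA(ex$transcript_id))
    stop("exon feature without transcript_id attribute in '", path, "'")
  bt <- ex$gene_biotype
  if (is.null(bt)) bt <- rep(NA_character_, length(ex))
  bt <- ifelse(bt %in% c("protein_coding", "mRNA"), "mRNA",
               ifelse(bt %in% c("lncRNA", "lincRNA"), "lncRNA", bt))
  idx <- split(seq_along(ex), ex$transcript_id)
  out <- lapply(idx, function(i) {
    e <- ex[i]
    gid <- if (is.null(e$gene_id)) e$transcript_id[1L] else e$gene_id[1L]
    b <- bt[i][1L]
    if (is.na(b) || !b %in% c("mRNA", "lncRNA"))
      stop("transcript '", e$transcript_id[1L],
           "' has missing or unrecognised gene_biotype")
    transcriptModel(
      transcriptId = e$transcript_id[1L], geneId = gid,
      chrom = as.character(GenomicRanges::seqnames(e))[1L],
      strand = as.character(GenomicRanges::strand(e))[1L],
      exons = IRanges::reduce(IRanges::ranges(e)),
      biotype = b)
  })
  out[order(names(out))]
}

#' Write transcript models to a GTF file
#'
#' Emits gene, transcript and exon features with `gene_id`,
#' `transcript_id` and `gene_biotype` attributes
#' (`protein_coding` / `lncRNA`), re-readable by [readTranscripts()].
#'
#' @param models list of [TranscriptModel-class] objects.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeTranscripts <- function(models, path) {
  stopifnot(is.list(models))
  if (length(models) == 0L) {
    writeLines(character(), path)
    return(invisible(path))
  }
  recs <- lapply(models, function(tx) {
    sp <- txSpan(tx)
    bt <- if (txBiotype(tx) == "mRNA") "protein_coding" else "lncRNA"
    n <- length(exonRanges(tx))
    GenomicRanges::GRanges(
      seqnames = txChrom(tx),
      ranges = c(sp, sp, exonRanges(tx)),
      strand = txStrand(tx),
      type = c("gene", "transcript", rep("exon", n)),
      source = "lncoLink",
      gene_id = geneId(tx),
      transcript_id = transcriptId(tx),
      gene_biotype = bt)
  })
  gr <- suppressWarnings(do.call(c, unname(recs)))
  rtracklayer::export(gr, path, format = "gtf")
  invisible(path)
}

#' Read an expression matrix with group labels as an ExpressionStudy
#'
#' @param exprPath TSV whose first column is the feature id and whose
#'   remaining columns are samples.
#' @param groupsPath two-column TSV (sample id, group) with group in
#'   `tumor` / `normal`; header optional but expected as
#'   `sample\tgroup`.
#' @param platform `"microarray"` or `"rnaseq"`.
#' @return An [ExpressionStudy-class].
#' @export
readExpressionStudy <- function(exprPath, groupsPath,
                                platform = c("microarray", "rnaseq")) {
  platform <- match.arg(platform)
  ex <- utils::read.delim(exprPath, check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(ex[, -1L, drop = FALSE])
  rownames(m) <- ex[[1L]]
  g <- utils::read.delim(groupsPath, stringsAsFactors = FALSE)
  grp <- g[[2L]][match(colnames(m), g[[1L]])]
  if (anyNA(grp))
    stop("group labels missing for samples: ",
         paste(colnames(m)[is.na(grp)], collapse = ", "))
  expressionStudy(m, grp, platform)
}

#' Write an ExpressionStudy as TSV files
#'
#' @param study an [ExpressionStudy-class].
#' @param exprPath output TSV for the matrix (first column `feature`).
#' @param groupsPath output TSV for sample group labels.
#' @return `exprPath`, invisibly.
#' @export
writeExpressionStudy <- function(study, exprPath, groupsPath) {
  m <- exprValues(study)
  df <- data.frame(feature = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, exprPath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(
    data.frame(sample = colnames(m), group = sampleGroups(study)),
    groupsPath, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(exprPath)
}
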