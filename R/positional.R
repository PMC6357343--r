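# Positional relationship classification of lncRNA-mRNA pairs.
#
# Decision procedure (priority order; first match wins):
#   1. same strand,  any lncRNA exon overlaps an mRNA exon
#        -> exon_sense_overlapping
#   2. same strand,  spans overlap, no exon-exon overlap, and the lncRNA
#      span covers mRNA intronic bases
#        -> intron_sense_overlapping
#   3. opposite strand, lncRNA span lies entirely inside one mRNA intron
#        -> intronic_antisense
#   4. opposite strand, any span overlap not entirely intronic
#        -> natural_antisense
#   5. no span overlap, opposite strands, head-to-head (each TSS is the
#      end facing the other transcript) with TSS-to-TSS distance
#      <= 1000 bp -> bidirectional
#   6. otherwise -> intergenic
#
# All coordinates 1-based closed; TSS distance = |tss_lnc - tss_mrna|,
# inclusive threshold.

# total overlapping bases between two sets of disjoint sorted closed
# intervals, given as start/end vectors (direct arithmetic: exon lists
# are tiny and this avoids heavy interval-set machinery)
.olap_bp <- function(as_, ae_, bs_, be_) {
  if (!length(as_) || !length(bs_)) return(0L)
  lo <- outer(as_, bs_, pmax)
  hi <- outer(ae_, be_, pmin)
  w <- hi - lo + 1L
  sum(w[w > 0L])
}

#' Classify the positional relationship of one lncRNA-mRNA pair
#'
#' Assigns one of the six relationship categories (see
#' [relationshipCategories()]) using a fixed priority order: exon
#' sense-overlapping, then intron sense-overlapping, intronic antisense,
#' natural antisense, bidirectional, and finally intergenic when no rule
#' applies. A multi-exon lncRNA overlapping both exon and intron of an
#' antisense mRNA is natural antisense, since intronic antisense
#' requires full containment in a single intron.
#'
#' @param lnc,mrna [TranscriptModel-class] objects with biotypes
#'   `"lncRNA"` and `"mRNA"` respectively.
#' @param maxGap maximum TSS-to-TSS distance (bp, inclusive) for a
#'   bidirectional call; 1000 by default.
#' @return One-row data.frame with columns `lnc_id`, `mrna_id`,
#'   `category`, `overlap_bp` and `tss_distance`. `mrna_id` is `NA` and
#'   `overlap_bp` 0 for an intergenic call; `tss_distance` is only
#'   non-`NA` for bidirectional calls. `overlap_bp` is the overlap the
#'   category is defined by: exon-exon bases (rule 1), lncRNA-span over
#'   mRNA-intron bases (rules 2-3), span-span bases (rule 4).
#' @export
#' @examples
#' lnc  <- transcriptModel("L1", chrom = "chr1", strand = "+",
#'                         exons = cbind(100, 200), biotype = "lncRNA")
#' mrna <- transcriptModel("M1", chrom = "chr1", strand = "+",
#'                         exons = cbind(150, 400), biotype = "mRNA")
#' classifyPair(lnc, mrna)   # exon_sense_overlapping, 51 bp
classifyPair <- function(lnc, mrna, maxGap = 1000L) {
  stopifnot(methods::is(lnc, "TranscriptModel"),
            methods::is(mrna, "TranscriptModel"))
  intergenic <- data.frame(lnc_id = transcriptId(lnc),
                           mrna_id = NA_character_,
                           category = "intergenic", overlap_bp = 0L,
                           tss_distance = NA_integer_,
                           stringsAsFactors = FALSE)
  if (txChrom(lnc) != txChrom(mrna)) return(intergenic)

  call_row <- function(category, overlap_bp, tss_distance = NA_integer_)
    data.frame(lnc_id = transcriptId(lnc), mrna_id = transcriptId(mrna),
               category = category, overlap_bp = as.integer(overlap_bp),
               tss_distance = as.integer(tss_distance),
               stringsAsFactors = FALSE)

  sL <- IRanges::start(lnc@exons);  eL <- IRanges::end(lnc@exons)
  sM <- IRanges::start(mrna@exons); eM <- IRanges::end(mrna@exons)
  spanLs <- sL[1L]; spanLe <- eL[length(eL)]   # exons sorted by validity
  spanMs <- sM[1L]; spanMe <- eM[length(eM)]
  spanOv <- max(0L, min(spanLe, spanMe) - max(spanLs, spanMs) + 1L)
  iS <- eM[-length(eM)] + 1L; iE <- sM[-1L] - 1L   # mRNA introns
  keep <- iE >= iS; iS <- iS[keep]; iE <- iE[keep]
  same <- txStrand(lnc) == txStrand(mrna)

  if (same) {
    exonOv <- .olap_bp(sL, eL, sM, eM)
    if (exonOv > 0L) return(call_row("exon_sense_overlapping", exonOv))
    intrOv <- .olap_bp(spanLs, spanLe, iS, iE)
    if (spanOv > 0L && intrOv > 0L)
      return(call_row("intron_sense_overlapping", intrOv))
    return(intergenic)
  }
  # opposite strands
  intrOv <- .olap_bp(spanLs, spanLe, iS, iE)
  if (intrOv == spanLe - spanLs + 1L)       # span fully inside one intron
    return(call_row("intronic_antisense", intrOv))
  if (spanOv > 0L) return(call_row("natural_antisense", spanOv))
  # disjoint spans: bidirectional = divergent, TSSs facing each other
  lncLeft <- spanLe < spanMs
  headToHead <- if (lncLeft)
    txStrand(lnc) == "-" && txStrand(mrna) == "+"
  else
    txStrand(mrna) == "-" && txStrand(lnc) == "+"
  if (headToHead) {
    tssL <- if (txStrand(lnc) == "+") spanLs else spanLe
    tssM <- if (txStrand(mrna) == "+") spanMs else spanMe
    d <- abs(tssL - tssM)
    if (d <= maxGap)
      return(call_row("bidirectional", 0L, d))
  }
  intergenic
}

#' Map each lncRNA to its best-related mRNA
#'
#' Classifies every lncRNA against nearby mRNAs and emits one
#' relationship call per lncRNA. When several mRNAs qualify, the call
#' with the highest-priority category wins; ties are broken by larger
#' `overlap_bp`, then smaller `tss_distance`, then lexicographic
#' `mrna_id`. lncRNAs with no qualifying mRNA are called intergenic.
#'
#' @param lncs,mrnas lists of [TranscriptModel-class] objects.
#' @param maxGap passed to [classifyPair()].
#' @return data.frame of relationship calls, one row per lncRNA, in the
#'   input order of `lncs` (columns as in [classifyPair()]).
#' @export
mapRelationships <- function(lncs, mrnas, maxGap = 1000L) {
  ids <- c(vapply(lncs, transcriptId, ""), vapply(mrnas, transcriptId, ""))
  if (anyDuplicated(ids))
    stop("duplicate transcript ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  if (length(lncs) == 0L)
    return(data.frame(lnc_id = character(), mrna_id = character(),
                      category = character(), overlap_bp = integer(),
                      tss_distance = integer(), stringsAsFactors = FALSE))
  # candidate prefilter: mRNAs whose span is within maxGap of the lncRNA
  # span on the same chromosome (any non-intergenic category requires
  # span distance <= maxGap)
  mrnaChrom <- vapply(mrnas, txChrom, "")
  mrnaSpan <- if (length(mrnas))
    do.call(c, lapply(mrnas, txSpan)) else IRanges::IRanges()
  priority <- stats::setNames(seq_along(.CATEGORIES), .CATEGORIES)
  rows <- lapply(lncs, function(lnc) {
    keep <- which(mrnaChrom == txChrom(lnc))
    if (length(keep)) {
      hits <- IRanges::findOverlaps(txSpan(lnc), mrnaSpan[keep],
                                    maxgap = maxGap)
      keep <- keep[S4Vectors::subjectHits(hits)]
    }
    calls <- lapply(mrnas[keep], function(m) classifyPair(lnc, m, maxGap))
    calls <- Filter(function(d) d$category != "intergenic", calls)
    if (length(calls) == 0L)
      return(classifyPair_intergenic(lnc))
    df <- do.call(rbind, calls)
    df <- df[order(priority[df$category], -df$overlap_bp,
                   ifelse(is.na(df$tss_distance), Inf, df$tss_distance),
                   df$mrna_id), , drop = FALSE]
    df[1L, , drop = FALSE]
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

classifyPair_intergenic <- function(lnc) {
  data.frame(lnc_id = transcriptId(lnc), mrna_id = NA_character_,
             category = "intergenic", overlap_bp = 0L,
             tss_distance = NA_integer_, stringsAsFactors = FALSE)
}

#' Write relationship calls as TSV
#'
#' @param calls data.frame from [mapRelationships()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
writeRelationshipCalls <- function(calls, path) {
  utils::write.table(calls, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
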