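# Paired-significance biomarker selection: join the mRNA and lncRNA DE
# tables through the positional relationship map.

#' Select lncRNA-related, coexpressed mRNA biomarkers
#'
#' A (mRNA, lncRNA) pair qualifies when (1) the mRNA is differentially
#' expressed at `q < qThreshold`, (2) its positionally related lncRNA
#' is differentially expressed at `q < qThreshold`, and (3) the
#' relationship is not intergenic. "Coexpressed" is joint significance,
#' not direction concordance: discordant pairs qualify (an informative
#' `concordant` column is emitted). One record per qualifying
#' (mrna_id, lnc_id) pair, probe-level granularity.
#'
#' @param mrnaDE,lncDE data.frames from [runDE()] for the two panels
#'   (q-values adjusted separately per panel).
#' @param calls relationship calls from [mapRelationships()].
#' @param qThreshold significance threshold on both q-values (0.05).
#' @param geneMap optional named character vector mapping mRNA
#'   probe/feature ids to gene symbols; defaults to the ids themselves.
#' @return data.frame sorted by `mrna_q` ascending with columns
#'   `mrna_id`, `gene_symbol`, `mrna_direction`, `mrna_q`, `lnc_id`,
#'   `relationship`, `lnc_direction`, `lnc_q`, `concordant`.
#' @export
selectBiomarkers <- function(mrnaDE, lncDE, calls, qThreshold = 0.05,
                             geneMap = NULL) {
  keep <- !is.na(calls$mrna_id) & calls$category != "intergenic"
  calls <- calls[keep, , drop = FALSE]
  unknown <- c(setdiff(calls$mrna_id, mrnaDE$feature_id),
               setdiff(calls$lnc_id, lncDE$feature_id))
  if (length(unknown))
    stop("relationship calls reference unknown features: ",
         paste(unique(unknown), collapse = ", "))
  mi <- match(calls$mrna_id, mrnaDE$feature_id)
  li <- match(calls$lnc_id, lncDE$feature_id)
  if (is.null(geneMap))
    geneMap <- stats::setNames(mrnaDE$feature_id, mrnaDE$feature_id)
  rec <- data.frame(
    mrna_id = calls$mrna_id,
    gene_symbol = unname(geneMap[calls$mrna_id]),
    mrna_direction = mrnaDE$direction[mi],
    mrna_q = mrnaDE$q_value[mi],
    lnc_id = calls$lnc_id,
    relationship = calls$category,
    lnc_direction = lncDE$direction[li],
    lnc_q = lncDE$q_value[li],
    stringsAsFactors = FALSE)
  rec$concordant <- rec$mrna_direction == rec$lnc_direction
  rec <- rec[rec$mrna_q < qThreshold & rec$lnc_q < qThreshold, , drop = FALSE]
  rec <- rec[order(rec$mrna_q), , drop = FALSE]
  rownames(rec) <- NULL
  rec
}

#' Tally biomarker records by relationship category
#'
#' @param records data.frame with a `relationship` column (e.g. from
#'   [selectBiomarkers()] or [loadBiomarkerPanel()]).
#' @return Named integer vector over all canonical categories (plus any
#'   extra labels present, such as the legacy `sense_overlap`); sums to
#'   `nrow(records)`.
#' @export
tallyRelationships <- function(records) {
  lev <- union(setdiff(.CATEGORIES, "intergenic"),
               unique(records$relationship))
  tab <- table(factor(records$relationship, levels = lev))
  out <- stats::setNames(as.integer(tab), names(tab))
  stopifnot(sum(out) == nrow(records))
  out
}

#' Collapse biomarker records to unique gene symbols
#'
#' @param records data.frame with a `gene_symbol` column.
#' @return Character vector of unique gene symbols in order of first
#'   appearance.
#' @export
collapseToGenes <- function(records) {
  unique(as.character(records$gene_symbol))
}

#' Load the packaged HCC biomarker panel fixture
#'
#' A published panel of 41 mRNA probes significantly coexpressed with
#' positionally related lncRNAs in a 16 tumor vs 16 adjacent-normal
#' hepatocellular carcinoma microarray cohort (both q-values < 0.05).
#' Relationship display labels are mapped to the package's category
#' codes; the panel contains one occurrence of the legacy
#' `sense_overlap` label, preserved verbatim (never emitted by
#' [classifyPair()]).
#'
#' @return data.frame with the [selectBiomarkers()] record columns.
#' @export
loadBiomarkerPanel <- function() {
  path <- system.file("extdata", "hcc_biomarker_panel.tsv",
                      package = "lncoLink", mustWork = TRUE)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  labmap <- c("exon sense-overlapping" = "exon_sense_overlapping",
              "intron sense-overlapping" = "intron_sense_overlapping",
              "intronic antisense" = "intronic_antisense",
              "natural antisense" = "natural_antisense",
              "bidirectional" = "bidirectional",
              "sense overlap" = "sense_overlap")
  rel <- labmap[df$relationship]
  if (anyNA(rel))
    stop("unknown relationship label(s) in panel fixture: ",
         paste(unique(df$relationship[is.na(rel)]), collapse = ", "))
  df$relationship <- unname(rel)
  df$concordant <- df$mrna_direction == df$lnc_direction
  df
}
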