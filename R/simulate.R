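# Synthetic data with known ground truth: transcript-pair geometries for
# every positional category, microarray-style log-intensity studies with
# planted coexpressed differential pairs, and an RPKM-style RNA-seq
# validation matrix. All generators are deterministic for a fixed seed.

#' Specification of a synthetic two-biotype genome
#'
#' @param counts named integer vector or list: number of lncRNA-mRNA
#'   pairs to generate per relationship category (names from
#'   [relationshipCategories()]); categories omitted default to 0.
#' @param chromLength chromosome length in bp.
#' @param minGeneLen,maxGeneLen mRNA gene length bounds (bp).
#' @param exonsPerGene length-2 integer range of exon counts per mRNA.
#' @param seed integer RNG seed.
#' @return A validated `GenomeSpec` list (class `"GenomeSpec"`).
#' @export
#' @examples
#' gs <- genomeSpec(counts = c(bidirectional = 2, natural_antisense = 3),
#'                  seed = 1)
genomeSpec <- function(counts, chromLength = 5e7, minGeneLen = 3000,
                       maxGeneLen = 12000, exonsPerGene = c(3L, 8L),
                       seed = 1L) {
  full <- stats::setNames(rep(0L, length(.CATEGORIES)), .CATEGORIES)
  counts <- unlist(counts)
  if (length(counts)) {
    bad <- setdiff(names(counts), .CATEGORIES)
    if (length(bad)) stop("unknown categories: ", paste(bad, collapse = ", "))
    if (any(counts < 0)) stop("category counts must be non-negative")
    full[names(counts)] <- as.integer(counts)
  }
  spec <- list(counts = full, chromLength = as.numeric(chromLength),
               minGeneLen = as.integer(minGeneLen),
               maxGeneLen = as.integer(maxGeneLen),
               exonsPerGene = as.integer(exonsPerGene),
               seed = as.integer(seed))
  stopifnot(spec$minGeneLen >= 300, spec$maxGeneLen >= spec$minGeneLen,
            length(spec$exonsPerGene) == 2L, spec$exonsPerGene[1L] >= 1L)
  # each pair occupies a slot of maxGeneLen*2 plus a >= 10 kb guard gap
  slot <- .pairSlotWidth(spec)
  if (sum(full) * slot > spec$chromLength)
    stop("chromLength too small for the requested pair counts ",
         "(need >= ", sum(full) * slot, " bp)")
  structure(spec, class = "GenomeSpec")
}

.pairSlotWidth <- function(spec) 2L * spec$maxGeneLen + 10000L + 2000L

#' Specification of a synthetic tumor/normal expression study
#'
#' Defaults mirror a 16-vs-16 discovery cohort on a log-intensity
#' microarray scale.
#'
#' @param nTumor,nNormal samples per group (each >= 2).
#' @param nDePairs number of planted differential lncRNA-mRNA pairs.
#' @param effectSize standardized mean shift (Cohen's d) on the log
#'   scale.
#' @param baselineMean,baselineSd log-intensity baseline parameters.
#' @param concordantFraction fraction of planted pairs whose lncRNA
#'   shifts in the same direction as its mRNA.
#' @param seed integer RNG seed.
#' @return A validated `StudySpec` list (class `"StudySpec"`).
#' @export
studySpec <- function(nTumor = 16L, nNormal = 16L, nDePairs = 50L,
                      effectSize = 2, baselineMean = 8, baselineSd = 1,
                      concordantFraction = 0.8, seed = 1L) {
  spec <- list(nTumor = as.integer(nTumor), nNormal = as.integer(nNormal),
               nDePairs = as.integer(nDePairs),
               effectSize = as.numeric(effectSize),
               baselineMean = as.numeric(baselineMean),
               baselineSd = as.numeric(baselineSd),
               concordantFraction = as.numeric(concordantFraction),
               seed = as.integer(seed))
  stopifnot(spec$nTumor >= 2L, spec$nNormal >= 2L, spec$nDePairs >= 0L,
            spec$effectSize >= 0, spec$baselineSd > 0,
            spec$concordantFraction >= 0, spec$concordantFraction <= 1)
  structure(spec, class = "StudySpec")
}

# geometry helpers -----------------------------------------------------------

.randExons <- function(start, len, nExons) {
  # partition [start, start+len-1] into nExons exons separated by introns
  if (nExons == 1L)
    return(IRanges::IRanges(start, start + len - 1L))
  # draw interior boundaries; enforce each exon/intron >= 50 bp
  nParts <- 2L * nExons - 1L
  minPart <- 50L
  spare <- len - nParts * minPart
  stopifnot(spare >= 0)
  cuts <- sort(sample.int(spare + nParts - 1L, nParts - 1L))
  widths <- diff(c(0L, cuts, spare + nParts)) - 1L + minPart
  ends <- start - 1L + cumsum(widths)
  starts <- c(start, ends[-nParts] + 1L)
  keep <- seq(1L, nParts, by = 2L)
  IRanges::IRanges(starts[keep], ends[keep])
}

.mkMrna <- function(id, chrom, start, spec, strand, minIntron = 0L) {
  gid <- paste0("G", sub("^M", "", id))
  if (minIntron == 0L) {
    len <- sample(spec$minGeneLen:spec$maxGeneLen, 1L)
    nEx <- sample(spec$exonsPerGene[1L]:spec$exonsPerGene[2L], 1L)
    ex <- .randExons(start, len, nEx)
  } else {
    # constructive: guarantee one intron of at least minIntron bp
    nEx <- sample(max(2L, spec$exonsPerGene[1L]):spec$exonsPerGene[2L], 1L)
    exW <- sample(150:600, nEx, replace = TRUE)
    inW <- sample(200:1500, nEx - 1L, replace = TRUE)
    inW[sample.int(nEx - 1L, 1L)] <- minIntron + sample.int(1000L, 1L)
    starts <- integer(nEx); starts[1L] <- start
    for (k in seq_len(nEx - 1L))
      starts[k + 1L] <- starts[k] + exW[k] + inW[k]
    ex <- IRanges::IRanges(starts, starts + exW - 1L)
  }
  transcriptModel(id, gid, chrom, strand, ex, "mRNA")
}

# one constructive geometry per category; the pair lives inside a slot
# starting at `base`, guaranteed >= 10 kb from every other pair
.buildPair <- function(category, idx, base, chrom, spec) {
  strand <- sample(c("+", "-"), 1L)
  anti <- if (strand == "+") "-" else "+"
  mid <- sprintf("M%04d", idx)
  lid <- sprintf("L%04d", idx)
  lncLen <- sample(300:1500, 1L)
  mk_lnc <- function(start, len, s, nEx = sample(1:2, 1L)) {
    transcriptModel(lid, paste0("G", sub("^L", "", lid)), chrom, s,
                    .randExons(start, len, nEx), "lncRNA")
  }
  if (category == "exon_sense_overlapping") {
    m <- .mkMrna(mid, chrom, base, spec, strand)
    # single-exon lncRNA overlapping the mRNA's first exon
    e1 <- exonRanges(m)[1L]
    st <- max(1L, IRanges::start(e1) - lncLen %/% 2L)
    l <- mk_lnc(st, lncLen, strand, nEx = 1L)
  } else if (category == "intron_sense_overlapping") {
    m <- .mkMrna(mid, chrom, base, spec, strand,
                 minIntron = lncLen + 20L)
    l <- .lncInLargestIntron(lid, m, lncLen, strand, chrom)
  } else if (category == "intronic_antisense") {
    m <- .mkMrna(mid, chrom, base, spec, strand,
                 minIntron = lncLen + 20L)
    l <- .lncInLargestIntron(lid, m, lncLen, anti, chrom)
  } else if (category == "natural_antisense") {
    m <- .mkMrna(mid, chrom, base, spec, strand)
    # antisense lncRNA overlapping the mRNA 5' span end (covers exon 1)
    e1 <- exonRanges(m)[1L]
    st <- max(1L, IRanges::start(e1) - lncLen %/% 2L)
    l <- mk_lnc(st, lncLen, anti, nEx = 1L)
  } else if (category == "bidirectional") {
    # divergent: lncRNA(-) upstream, mRNA(+) downstream;
    # TSS-to-TSS distance uniform in [1, 1000]
    gap <- sample.int(1000L, 1L)
    lncEnd <- base + lncLen - 1L
    l <- mk_lnc(base, lncLen, "-", nEx = 1L)
    m <- .mkMrna(mid, chrom, lncEnd + gap, spec, "+")
  } else if (category == "intergenic") {
    m <- .mkMrna(mid, chrom, base, spec, strand)
    sp <- txSpan(m)
    l <- mk_lnc(IRanges::end(sp) + 10000L, lncLen, sample(c("+", "-"), 1L),
                nEx = 1L)
  } else stop("unknown category: ", category)
  list(lnc = l, mrna = m, category = category)
}

.lncInLargestIntron <- function(lid, m, lncLen, strand, chrom) {
  introns <- intronRanges(m)
  i <- introns[which.max(IRanges::width(introns))]
  st <- IRanges::start(i) + sample.int(IRanges::width(i) - lncLen - 1L, 1L)
  transcriptModel(lid, paste0("G", sub("^L", "", lid)), chrom, strand,
                  IRanges::IRanges(st, st + lncLen - 1L), "lncRNA")
}

#' Generate lncRNA-mRNA transcript pairs with known relationships
#'
#' Constructively builds, for each requested category, pair geometries
#' that satisfy that category's definition and no other. Distinct pairs
#' are placed at least 10 kb apart on one chromosome so relationships
#' never leak across pairs. Deterministic for a fixed
#' `spec$seed`.
#'
#' @param spec a [genomeSpec()].
#' @return List of pairs; each element has `lnc` and `mrna`
#'   ([TranscriptModel-class]) and the `category` label. Attribute
#'   `"truth"` carries a data.frame of (lnc_id, mrna_id, category).
#' @export
simulateTranscriptPairs <- function(spec) {
  stopifnot(inherits(spec, "GenomeSpec"))
  total <- sum(spec$counts)
  if (total == 0L) {
    out <- list()
    attr(out, "truth") <- data.frame(lnc_id = character(),
                                     mrna_id = character(),
                                     category = character(),
                                     stringsAsFactors = FALSE)
    return(out)
  }
  slot <- .pairSlotWidth(spec)
  old <- .Random.seed_safe()
  on.exit(.restore_seed(old), add = TRUE)
  set.seed(spec$seed)
  cats <- rep(names(spec$counts), spec$counts)
  out <- vector("list", total)
  for (i in seq_len(total)) {
    base <- as.integer((i - 1L) * slot + 1L)
    out[[i]] <- .buildPair(cats[i], i, base, "chrS", spec)
  }
  attr(out, "truth") <- data.frame(
    lnc_id = vapply(out, function(p) transcriptId(p$lnc), ""),
    mrna_id = vapply(out, function(p) transcriptId(p$mrna), ""),
    category = cats, stringsAsFactors = FALSE)
  out
}

.Random.seed_safe <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Generate a tumor/normal expression study pair with planted signal
#'
#' Creates matched microarray-style studies for the mRNA and lncRNA
#' panels of a set of transcript pairs. Log intensities are normal
#' (`baselineMean`, `baselineSd`) and exponentiated, so values are
#' strictly positive and the Box-Cox optimum is near lambda = 0.
#' `nDePairs` non-intergenic pairs are planted: the mRNA log mean is
#' shifted by `effectSize * baselineSd` in tumor samples (direction
#' random), and the lncRNA partner is shifted in the same direction
#' with probability `concordantFraction`, otherwise oppositely.
#'
#' @param pairs output of [simulateTranscriptPairs()].
#' @param spec a [studySpec()].
#' @return List with elements `mrna` and `lnc`
#'   ([ExpressionStudy-class]) and `truth`, a data.frame with one row
#'   per pair: ids, category, `planted`, `mrna_direction`,
#'   `lnc_direction`, `concordant`.
#' @export
simulateExpressionStudy <- function(pairs, spec) {
  stopifnot(inherits(spec, "StudySpec"))
  truth <- attr(pairs, "truth")
  if (is.null(truth)) stop("pairs must come from simulateTranscriptPairs()")
  eligible <- which(truth$category != "intergenic")
  if (spec$nDePairs > length(eligible))
    stop("nDePairs (", spec$nDePairs, ") exceeds the number of ",
         "non-intergenic pairs (", length(eligible), ")")
  old <- .Random.seed_safe(); on.exit(.restore_seed(old), add = TRUE)
  set.seed(spec$seed)
  n <- spec$nTumor + spec$nNormal
  groups <- rep(c("tumor", "normal"), c(spec$nTumor, spec$nNormal))
  samples <- sprintf("S%02d", seq_len(n))
  planted <- sort(sample(eligible, spec$nDePairs))
  nP <- nrow(truth)
  mdir <- rep(NA_character_, nP); ldir <- rep(NA_character_, nP)
  conc <- rep(NA, nP)
  mdir[planted] <- sample(c("up", "down"), spec$nDePairs, replace = TRUE)
  conc[planted] <- stats::runif(spec$nDePairs) < spec$concordantFraction
  ldir[planted] <- ifelse(conc[planted], mdir[planted],
                          ifelse(mdir[planted] == "up", "down", "up"))
  mkMatrix <- function(dirs) {
    shift <- ifelse(is.na(dirs), 0, ifelse(dirs == "up", 1, -1)) *
      spec$effectSize * spec$baselineSd
    logm <- matrix(stats::rnorm(nP * n, spec$baselineMean, spec$baselineSd),
                   nrow = nP)
    tumorCols <- which(groups == "tumor")
    logm[, tumorCols] <- logm[, tumorCols] + shift
    exp(logm)
  }
  mrnaM <- mkMatrix(mdir); rownames(mrnaM) <- truth$mrna_id
  lncM <- mkMatrix(ldir); rownames(lncM) <- truth$lnc_id
  colnames(mrnaM) <- colnames(lncM) <- samples
  truth$planted <- seq_len(nP) %in% planted
  truth$mrna_direction <- mdir
  truth$lnc_direction <- ldir
  truth$concordant <- conc
  list(mrna = expressionStudy(mrnaM, groups, "microarray"),
       lnc = expressionStudy(lncM, groups, "microarray"),
       truth = truth)
}

#' Generate an RPKM-style RNA-seq validation study
#'
#' Simulates positive RPKM-like values (log-normal around gene-specific
#' gamma-distributed baselines) for a fixed gene panel, with the same
#' planted shift directions as the training truth for shared genes.
#' Tagged `platform = "rnaseq"`.
#'
#' @param genes character vector of gene (feature) ids for the panel.
#' @param nPerGroup samples per group (default 21, a 21-vs-21 design).
#' @param effectSize Cohen's d of the planted log-scale shift.
#' @param directions optional named vector (`"up"`/`"down"`, names in
#'   `genes`); genes not named get no shift.
#' @param seed integer RNG seed.
#' @param sdLog log-scale biological standard deviation.
#' @return An [ExpressionStudy-class] with platform `"rnaseq"`.
#' @export
simulateValidationRnaseq <- function(genes, nPerGroup = 21L, effectSize = 2,
                                     directions = NULL, seed = 1L,
                                     sdLog = 0.6) {
  stopifnot(length(genes) > 0L)
  old <- .Random.seed_safe(); on.exit(.restore_seed(old), add = TRUE)
  set.seed(seed)
  nG <- length(genes); n <- 2L * as.integer(nPerGroup)
  groups <- rep(c("tumor", "normal"), each = nPerGroup)
  base <- stats::rgamma(nG, shape = 2, rate = 0.2) + 0.5  # RPKM baselines
  shift <- numeric(nG)
  if (!is.null(directions)) {
    idx <- match(names(directions), genes)
    ok <- !is.na(idx)
    shift[idx[ok]] <- ifelse(directions[ok] == "up", 1, -1) *
      effectSize * sdLog
  }
  logm <- matrix(stats::rnorm(nG * n, 0, sdLog), nrow = nG) + log(base)
  logm[, groups == "tumor"] <- logm[, groups == "tumor"] + shift
  m <- exp(logm)
  dimnames(m) <- list(genes, sprintf("R%02d", seq_len(n)))
  expressionStudy(m, groups, "rnaseq")
}
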