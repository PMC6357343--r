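# Independent brute-force oracle for the positional classifier: works
# base by base with logical membership vectors instead of interval
# algebra, following the documented decision procedure.

oracleClassify <- function(lnc, mrna, maxGap = 1000L) {
  if (txChrom(lnc) != txChrom(mrna)) return("intergenic")
  L <- max(IRanges::end(exonRanges(lnc)), IRanges::end(exonRanges(mrna)))
  paint <- function(ir) {
    v <- rep(FALSE, L)
    for (i in seq_along(ir))
      v[IRanges::start(ir)[i]:IRanges::end(ir)[i]] <- TRUE
    v
  }
  eL <- paint(exonRanges(lnc)); eM <- paint(exonRanges(mrna))
  sL <- rep(FALSE, L); sL[min(which(eL)):max(which(eL))] <- TRUE
  sM <- rep(FALSE, L); sM[min(which(eM)):max(which(eM))] <- TRUE
  iM <- sM & !eM
  if (txStrand(lnc) == txStrand(mrna)) {
    if (any(eL & eM)) return("exon_sense_overlapping")
    if (any(sL & sM) && any(sL & iM)) return("intron_sense_overlapping")
    return("intergenic")
  }
  if (all(iM[sL])) return("intronic_antisense")
  if (any(sL & sM)) return("natural_antisense")
  lncLeft <- max(which(sL)) < min(which(sM))
  h2h <- if (lncLeft) txStrand(lnc) == "-" && txStrand(mrna) == "+"
         else txStrand(lnc) == "+" && txStrand(mrna) == "-"
  tssOf <- function(tx, sp) if (txStrand(tx) == "+") min(which(sp))
                            else max(which(sp))
  if (h2h && abs(tssOf(lnc, sL) - tssOf(mrna, sM)) <= maxGap)
    return("bidirectional")
  "intergenic"
}

# independent Box-Cox profile-likelihood oracle: fine grid, step 0.001
oracleBoxCoxLambda <- function(x, step = 0.001) {
  grid <- seq(-3, 3, by = step)
  sumlog <- sum(log(x)); n <- length(x)
  ll <- vapply(grid, function(l) {
    y <- if (abs(l) < 1e-12) log(x) else (x^l - 1) / l
    s2 <- mean((y - mean(y))^2)
    -n / 2 * log(s2) + (l - 1) * sumlog
  }, 0)
  grid[which.max(ll)]
}

# trapezoidal ROC-integration oracle for the AUC
oracleAucTrapezoid <- function(scores, labels) {
  pos <- labels == "tumor"
  th <- sort(unique(scores), decreasing = TRUE)
  tpr <- c(0, vapply(th, function(t) mean(scores[pos] >= t), 0), 1)
  fpr <- c(0, vapply(th, function(t) mean(scores[!pos] >= t), 0), 1)
  sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
}
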