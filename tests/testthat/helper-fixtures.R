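# Small programmatic fixtures shared across tests.

# a transcript with explicit exon coordinates
tx <- function(id, strand, exons, biotype, chrom = "chr1") {
  transcriptModel(id, chrom = chrom, strand = strand,
                  exons = matrix(exons, ncol = 2, byrow = TRUE),
                  biotype = biotype)
}

# a small positive expression study with optional planted shift on the
# first `nShift` features (log-scale shift `delta` in tumor samples)
makeStudy <- function(nFeatures = 20, nTumor = 5, nNormal = 5,
                      nShift = 0, delta = 0, seed = 1,
                      platform = "microarray") {
  set.seed(seed)
  n <- nTumor + nNormal
  logm <- matrix(rnorm(nFeatures * n, 6, 1), nrow = nFeatures)
  if (nShift > 0)
    logm[seq_len(nShift), seq_len(nTumor)] <-
      logm[seq_len(nShift), seq_len(nTumor)] + delta
  m <- exp(logm)
  dimnames(m) <- list(sprintf("f%03d", seq_len(nFeatures)),
                      sprintf("s%02d", seq_len(n)))
  expressionStudy(m, rep(c("tumor", "normal"), c(nTumor, nNormal)),
                  platform)
}

# the standard six-category synthetic genome used in several tests
makePairs <- function(nPerCategory = 10, seed = 1) {
  counts <- stats::setNames(rep(as.integer(nPerCategory), 6),
                            relationshipCategories())
  simulateTranscriptPairs(genomeSpec(counts = counts,
                                     chromLength = 6 * nPerCategory * 40000,
                                     seed = seed))
}
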