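test_that("exon-exon sense overlap is called with closed-interval arithmetic", {
  lnc <- tx("L1", "+", c(100, 200), "lncRNA")
  mrna <- tx("M1", "+", c(150, 400), "mRNA")
  call <- classifyPair(lnc, mrna)
  expect_equal(call$category, "exon_sense_overlapping")
  expect_equal(call$overlap_bp, 51L)  # [150,200], 1-based closed
})

test_that("antisense lncRNA inside an intron is intronic antisense", {
  mrna <- tx("M1", "+", c(500, 899, 2001, 2400), "mRNA")  # intron [900,2000]
  lnc <- tx("L1", "-", c(1000, 1500), "lncRNA")
  expect_equal(classifyPair(lnc, mrna)$category, "intronic_antisense")
  # same strand inside the intron -> intron sense-overlapping
  lncS <- tx("L2", "+", c(1000, 1500), "lncRNA")
  expect_equal(classifyPair(lncS, mrna)$category, "intron_sense_overlapping")
})

test_that("antisense overlap spanning exon and intron is natural antisense", {
  mrna <- tx("M1", "+", c(500, 899, 2001, 2400), "mRNA")
  lnc <- tx("L1", "-", c(700, 1200), "lncRNA")  # covers exon1 end + intron
  expect_equal(classifyPair(lnc, mrna)$category, "natural_antisense")
})

test_that("bidirectional requires divergent orientation within 1000 bp", {
  mrna <- tx("M1", "+", c(5000, 8000), "mRNA")
  lnc <- function(s, e, strand) tx("L1", strand, c(s, e), "lncRNA")
  expect_equal(classifyPair(lnc(3000, 4500, "-"), mrna)$category,
               "bidirectional")             # TSS distance 500
  expect_equal(classifyPair(lnc(3000, 4500, "-"), mrna)$tss_distance, 500L)
  expect_equal(classifyPair(lnc(3000, 4000, "-"), mrna)$category,
               "bidirectional")             # TSS distance exactly 1000
  expect_equal(classifyPair(lnc(3000, 3999, "-"), mrna)$category,
               "intergenic")                # 1001 bp: outside the window
  expect_equal(classifyPair(lnc(3000, 4500, "+"), mrna)$category,
               "intergenic")                # tandem, not head-to-head
})

test_that("different chromosomes are always intergenic", {
  lnc <- tx("L1", "+", c(100, 200), "lncRNA", chrom = "chr2")
  mrna <- tx("M1", "+", c(150, 400), "mRNA", chrom = "chr1")
  call <- classifyPair(lnc, mrna)
  expect_equal(call$category, "intergenic")
  expect_true(is.na(call$mrna_id))
})

test_that("classifier matches the brute-force base-overlap oracle on random geometries", {
  set.seed(42)
  for (i in 1:300) {
    mrnaExons <- sort(sample(500:4500, 2 * sample(1:3, 1)))
    mrna <- tx("M1", sample(c("+", "-"), 1),
               as.vector(rbind(mrnaExons[c(TRUE, FALSE)],
                               mrnaExons[c(FALSE, TRUE)])), "mRNA")
    lncStart <- sample(1:5000, 1)
    lnc <- tx("L1", sample(c("+", "-"), 1),
              c(lncStart, lncStart + sample(50:800, 1)), "lncRNA")
    expect_equal(classifyPair(lnc, mrna)$category, oracleClassify(lnc, mrna),
                 info = sprintf("case %d", i))
  }
})

test_that("strand-consistency: flipping both strands preserves sense/antisense calls", {
  # bidirectional is excluded by design: flipping both strands of a
  # divergent pair makes it convergent, which is intergenic
  pairs <- makePairs(5, seed = 7)
  flip <- function(t) transcriptModel(transcriptId(t), geneId(t), txChrom(t),
                                      if (txStrand(t) == "+") "-" else "+",
                                      exonRanges(t), txBiotype(t))
  for (p in pairs) {
    if (p$category == "bidirectional") next
    expect_equal(classifyPair(flip(p$lnc), flip(p$mrna))$category,
                 classifyPair(p$lnc, p$mrna)$category)
  }
})

test_that("mapRelationships is invariant to input order and applies priority", {
  pairs <- makePairs(5, seed = 3)
  lncs <- lapply(pairs, `[[`, "lnc"); mrnas <- lapply(pairs, `[[`, "mrna")
  calls <- mapRelationships(lncs, mrnas)
  set.seed(1)
  perm <- sample(length(lncs))
  calls2 <- mapRelationships(lncs[perm], mrnas[sample(length(mrnas))])
  expect_equal(calls2[order(match(calls2$lnc_id, calls$lnc_id)), ],
               calls, ignore_attr = TRUE)
  # priority: exon-sense beats a nearby bidirectional partner
  lnc <- tx("L1", "+", c(100, 400), "lncRNA")
  a <- tx("A", "+", c(300, 900), "mRNA")
  b <- tx("B", "-", c(450, 1400), "mRNA")  # would also overlap
  best <- mapRelationships(list(lnc), list(a, b))
  expect_equal(best$category, "exon_sense_overlapping")
  expect_equal(best$mrna_id, "A")
})

test_that("lncRNA with no qualifying mRNA is intergenic with null partner", {
  lnc <- tx("L1", "+", c(100, 400), "lncRNA")
  far <- tx("M1", "+", c(50000, 60000), "mRNA")
  calls <- mapRelationships(list(lnc), list(far))
  expect_equal(calls$category, "intergenic")
  expect_true(is.na(calls$mrna_id))
  expect_error(mapRelationships(list(lnc, lnc), list(far)), "duplicate")
})

test_that("GTF round trip preserves transcript models", {
  pairs <- makePairs(2, seed = 9)
  models <- c(lapply(pairs, `[[`, "lnc"), lapply(pairs, `[[`, "mrna"))
  gtf <- withr::local_tempfile(fileext = ".gtf")
  writeTranscripts(models, gtf)
  back <- readTranscripts(gtf)
  expect_setequal(names(back), vapply(models, transcriptId, ""))
  for (m in models) {
    b <- back[[transcriptId(m)]]
    expect_equal(txStrand(b), txStrand(m))
    expect_equal(txBiotype(b), txBiotype(m))
    expect_equal(as.data.frame(exonRanges(b)), as.data.frame(exonRanges(m)))
  }
  # empty file -> empty list with a warning
  empty <- withr::local_tempfile(fileext = ".gtf")
  writeLines(character(), empty)
  expect_warning(res <- readTranscripts(empty), "no features")
  expect_length(res, 0)
})

test_that("transcript model validity catches malformed exon structures", {
  expect_error(transcriptModel("t", chrom = "c", strand = "*",
                               exons = cbind(1, 10), biotype = "mRNA"))
  expect_error(transcriptModel("t", chrom = "c", strand = "+",
                               exons = cbind(c(1, 5), c(10, 20)),
                               biotype = "mRNA"), "non-overlapping")
  expect_error(transcriptModel("t", chrom = "c", strand = "+",
                               exons = cbind(10, 5), biotype = "mRNA"))
})
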