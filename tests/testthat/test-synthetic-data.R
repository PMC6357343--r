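test_that("zero requested pairs yield an empty generator result", {
  out <- simulateTranscriptPairs(genomeSpec(counts = list(), seed = 1))
  expect_length(out, 0)
  expect_equal(nrow(attr(out, "truth")), 0)
})

test_that("a requested bidirectional pair satisfies the category definition", {
  out <- simulateTranscriptPairs(genomeSpec(counts = c(bidirectional = 1),
                                            seed = 7))
  expect_length(out, 1)
  p <- out[[1]]
  expect_true(txStrand(p$lnc) != txStrand(p$mrna))
  ov <- IRanges::intersect(txSpan(p$lnc), txSpan(p$mrna))
  expect_equal(sum(IRanges::width(ov)), 0)
  expect_lte(abs(txTSS(p$lnc) - txTSS(p$mrna)), 1000)
})

test_that("generator output is bit-identical for a fixed seed", {
  a <- makePairs(3, seed = 5)
  b <- makePairs(3, seed = 5)
  expect_identical(lapply(a, function(p) as.data.frame(exonRanges(p$lnc))),
                   lapply(b, function(p) as.data.frame(exonRanges(p$lnc))))
  expect_identical(attr(a, "truth"), attr(b, "truth"))
  spec <- studySpec(nDePairs = 5, seed = 2)
  s1 <- simulateExpressionStudy(a, spec)
  s2 <- simulateExpressionStudy(b, spec)
  expect_identical(exprValues(s1$mrna), exprValues(s2$mrna))
  expect_identical(s1$truth, s2$truth)
})

test_that("generated geometries are recovered by the classifier (round trip)", {
  pairs <- makePairs(25, seed = 11)
  truth <- attr(pairs, "truth")
  calls <- mapRelationships(lapply(pairs, `[[`, "lnc"),
                            lapply(pairs, `[[`, "mrna"))
  expect_equal(calls$category, truth$category)
  nonInter <- truth$category != "intergenic"
  expect_equal(calls$mrna_id[nonInter], truth$mrna_id[nonInter])
})

test_that("infeasible geometry is rejected up front", {
  expect_error(genomeSpec(counts = c(bidirectional = 100),
                          chromLength = 50000), "chromLength too small")
  expect_error(genomeSpec(counts = c(nonsense = 1)), "unknown categories")
})

test_that("planted features carry the requested log-scale effect", {
  pairs <- makePairs(10, seed = 2)
  spec <- studySpec(nTumor = 16, nNormal = 16, nDePairs = 30,
                    effectSize = 2, concordantFraction = 1, seed = 4)
  st <- simulateExpressionStudy(pairs, spec)
  truth <- st$truth
  expect_equal(sum(truth$planted), 30)
  expect_true(all(truth$category[truth$planted] != "intergenic"))
  # concordantFraction = 1 forces identical directions
  expect_equal(truth$mrna_direction[truth$planted],
               truth$lnc_direction[truth$planted])
  expect_true(all(exprValues(st$mrna) > 0))
  # mean log shift of planted 'up' mRNAs close to d * sd = 2
  lm <- log(exprValues(st$mrna))
  grp <- sampleGroups(st$mrna) == "tumor"
  up <- which(truth$planted & truth$mrna_direction == "up")
  if (length(up) >= 5) {
    shifts <- rowMeans(lm[truth$mrna_id[up], grp, drop = FALSE]) -
      rowMeans(lm[truth$mrna_id[up], !grp, drop = FALSE])
    expect_lt(abs(mean(shifts) - 2), 0.5)
  }
  expect_error(simulateExpressionStudy(pairs, studySpec(nDePairs = 1000)),
               "exceeds")
})

test_that("null studies control the Welch type-I error near alpha", {
  pairs <- makePairs(25, seed = 8)
  st <- simulateExpressionStudy(pairs, studySpec(nDePairs = 20,
                                                 effectSize = 0, seed = 9))
  de <- rbind(runDE(st$mrna), runDE(st$lnc))
  n <- nrow(de)  # 300 features, all null (effect size 0)
  se <- sqrt(0.05 * 0.95 / n)
  expect_lt(abs(mean(de$p_value < 0.05) - 0.05), 3 * se)
  # truth table still records the planted (zero-shift) features
  expect_equal(sum(st$truth$planted), 20)
})

test_that("RPKM-style validation study has the requested design and signal", {
  genes <- sprintf("G%02d", 1:38)
  dirs <- stats::setNames(rep(c("up", "down"), 19), genes)
  st <- simulateValidationRnaseq(genes, nPerGroup = 21, effectSize = 2,
                                 directions = dirs, seed = 11)
  expect_equal(dim(exprValues(st)), c(38L, 42L))
  expect_equal(platformName(st), "rnaseq")
  expect_equal(table(sampleGroups(st))[["tumor"]], 21L)
  expect_true(all(exprValues(st) > 0))
  # identical for same seed
  st2 <- simulateValidationRnaseq(genes, nPerGroup = 21, effectSize = 2,
                                  directions = dirs, seed = 11)
  expect_identical(exprValues(st), exprValues(st2))
  # no-signal null: group AUC of a single gene hovers near 0.5
  null <- simulateValidationRnaseq(genes, nPerGroup = 21, effectSize = 0,
                                   seed = 12)
  aucs <- apply(exprValues(null), 1, aucFromScores,
                labels = sampleGroups(null))
  expect_lt(abs(mean(aucs) - 0.5), 0.1)
})
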