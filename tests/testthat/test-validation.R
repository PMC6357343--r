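test_that("probe-to-gene averaging equals the brute-force per-gene loop", {
  st <- makeStudy(nFeatures = 12, seed = 31)
  map <- stats::setNames(rep(sprintf("g%d", 1:4), each = 3),
                         rownames(exprValues(st)))
  avg <- averageByGene(st, map)
  v <- exprValues(st)
  for (g in unique(map)) {
    manual <- colMeans(v[names(map)[map == g], , drop = FALSE])
    expect_equal(unname(exprValues(avg)[g, ]), unname(manual))
  }
  # single-probe genes pass through unchanged; constant probes average
  one <- expressionStudy(rbind(p1 = c(1, 1, 1, 1), p2 = c(1, 2, 3, 4),
                               p3 = c(2, 2, 2, 2), p4 = c(3, 3, 3, 3)),
                         rep(c("tumor", "normal"), each = 2), "microarray")
  avg2 <- averageByGene(one, c(p1 = "solo", p2 = "solo2",
                               p3 = "trip", p4 = "trip"))
  expect_equal(unname(exprValues(avg2)["solo2", ]), c(1, 2, 3, 4))
  expect_equal(unname(exprValues(avg2)["trip", ]), rep(2.5, 4))
  expect_error(averageByGene(one, c(p1 = "a", p2 = "b", p3 = "c")),
               "unmapped")
})

test_that("min-max normalization maps each feature onto [0, 1] and is idempotent", {
  st <- expressionStudy(rbind(a = c(2, 4, 6, 3), b = c(10, 30, 20, 40)),
                        rep(c("tumor", "normal"), each = 2), "microarray")
  nm <- minmaxNormalize(st)
  expect_equal(unname(exprValues(nm)["a", ]), c(0, 0.5, 1, 0.25))
  expect_equal(unname(exprValues(nm)["b", ]), c(0, 2/3, 1/3, 1))
  expect_equal(exprValues(minmaxNormalize(nm)), exprValues(nm))
  cst <- expressionStudy(rbind(a = c(1, 2, 3, 4), k = rep(7, 4)),
                         rep(c("tumor", "normal"), each = 2), "microarray")
  expect_warning(ncst <- minmaxNormalize(cst), "constant")
  expect_equal(unname(exprValues(ncst)["k", ]), rep(0.5, 4))
})

test_that("min-max + SVM pipeline is invariant to per-feature affine rescaling", {
  st <- makeStudy(nFeatures = 10, nTumor = 8, nNormal = 8,
                  nShift = 4, delta = 2, seed = 33)
  v <- exprValues(st)
  scaled <- v * runif(nrow(v), 0.5, 5) + runif(nrow(v), 0, 10)
  st2 <- expressionStudy(scaled, sampleGroups(st), "microarray")
  r1 <- crossvalidateSvm(minmaxNormalize(st), seed = 3)
  r2 <- crossvalidateSvm(minmaxNormalize(st2), seed = 3)
  expect_equal(r1$predicted, r2$predicted)
  expect_equal(r1$scores, r2$scores, tolerance = 1e-8)
})

test_that("confusion metrics follow the standard formulas", {
  perfect <- confusionMetrics(list(tp = 10, fp = 0, fn = 0, tn = 12))
  expect_equal(perfect$sensitivity, 1)
  expect_equal(perfect$specificity, 1)
  expect_equal(perfect$precision, 1)
  expect_equal(perfect$accuracy, 1)
  m <- confusionMetrics(list(tp = 15, fp = 3, fn = 6, tn = 18))
  expect_equal(m$sensitivity, 15 / 21)
  expect_equal(m$specificity, 18 / 21)
  expect_equal(m$precision, 15 / 18)
  expect_equal(m$accuracy, 33 / 42)
  expect_error(confusionMetrics(list(tp = 0, fp = 0, fn = 0, tn = 0)),
               "all-zero")
  expect_warning(nd <- confusionMetrics(list(tp = 0, fp = 0, fn = 3, tn = 5)),
                 "precision")
  expect_true(is.na(nd$precision))
})

test_that("rank AUC matches the trapezoidal ROC oracle and is monotone-invariant", {
  set.seed(35)
  for (i in 1:50) {
    n <- sample(10:40, 1)
    labels <- sample(c("tumor", "normal"), n, replace = TRUE,
                     prob = c(0.5, 0.5))
    if (length(unique(labels)) < 2) next
    scores <- round(rnorm(n), sample(0:2, 1))  # rounding induces ties
    a <- aucFromScores(scores, labels)
    expect_equal(a, oracleAucTrapezoid(scores, labels), tolerance = 1e-9)
    expect_equal(aucFromScores(exp(scores) + 3, labels), a)
  }
  labels <- rep(c("tumor", "normal"), each = 4)
  expect_equal(aucFromScores(c(1, 1, 1, 1, 0, 0, 0, 0), labels), 1)
  expect_equal(aucFromScores(rep(2, 8), labels), 0.5)
  expect_error(aucFromScores(1:4, rep("tumor", 4)), "both classes")
})

test_that("rank AUC agrees with pROC on random scores", {
  skip_if_not_installed("pROC")
  set.seed(36)
  scores <- rnorm(30)
  labels <- sample(rep(c("tumor", "normal"), 15))
  ref <- as.numeric(pROC::auc(pROC::roc(response = labels,
                                        predictor = scores,
                                        levels = c("normal", "tumor"),
                                        direction = "<", quiet = TRUE)))
  expect_equal(aucFromScores(scores, labels), ref, tolerance = 1e-12)
})

test_that("cross-validated SVM separates separable clusters and is seeded", {
  st <- makeStudy(nFeatures = 8, nTumor = 8, nNormal = 8,
                  nShift = 8, delta = 4, seed = 37)
  cv <- crossvalidateSvm(minmaxNormalize(st), seed = 5)
  expect_equal(cv$report$accuracy, 1)
  expect_equal(cv$report$auc, 1)
  cv2 <- crossvalidateSvm(minmaxNormalize(st), seed = 5)
  expect_identical(cv$folds, cv2$folds)
  expect_equal(cv$scores, cv2$scores)
  expect_error(crossvalidateSvm(st, k = 20), "at least k")
})

test_that("label permutation drives the CV AUC to chance", {
  st <- makeStudy(nFeatures = 10, nTumor = 10, nNormal = 10,
                  nShift = 5, delta = 2, seed = 38)
  nm <- minmaxNormalize(st)
  set.seed(39)
  aucs <- replicate(30, {
    perm <- expressionStudy(exprValues(nm), sample(sampleGroups(nm)),
                            "microarray")
    crossvalidateSvm(perm, seed = 1)$report$auc
  })
  expect_lt(abs(mean(aucs) - 0.5), 0.1)
})

test_that("stratified split utility reproduces a seeded 8+8/8+8 design", {
  st <- makeStudy(nFeatures = 5, nTumor = 16, nNormal = 16, seed = 40)
  sp <- splitStudy(st, nPerGroupTrain = 8, seed = 2)
  g <- sampleGroups(st)
  expect_equal(sum(g[sp$train] == "tumor"), 8)
  expect_equal(sum(g[sp$train] == "normal"), 8)
  expect_equal(sort(c(sp$train, sp$test)), seq_along(g))
  expect_identical(splitStudy(st, 8, seed = 2)$train, sp$train)
})

test_that("cross-platform evaluation keeps the blind test blind but accurate", {
  train <- makeStudy(nFeatures = 20, nTumor = 16, nNormal = 16,
                     nShift = 10, delta = 2, seed = 41)
  genes <- rownames(exprValues(train))
  dirs <- stats::setNames(rep("up", 10), genes[1:10])
  test <- simulateValidationRnaseq(genes, nPerGroup = 21, effectSize = 2,
                                   directions = dirs, seed = 42)
  res <- crossPlatformEval(train, test, genes, seed = 7)
  expect_gte(res$report$auc, 0.8)
  expect_equal(res$confusion$tp + res$confusion$fp + res$confusion$fn +
                 res$confusion$tn, 42)
  expect_error(crossPlatformEval(train, test, c(genes, "missing"), seed = 1),
               "missing")
  # degenerate check: testing on the training data equals resubstitution
  res2 <- crossPlatformEval(train, train, genes, seed = 7)
  nm <- minmaxNormalize(train)
  fit <- e1071::svm(x = t(exprValues(nm)),
                    y = factor(sampleGroups(nm),
                               levels = c("tumor", "normal")),
                    kernel = "radial", cost = 1,
                    gamma = 1 / length(genes), scale = FALSE)
  resub <- as.character(predict(fit, t(exprValues(nm))))
  expect_equal(res2$predicted, resub)
})
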