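# Panel validation: probe-to-gene averaging, min-max normalization,
# stratified k-fold RBF-SVM cross-validation, and cross-platform
# (microarray train / RNA-seq blind test) evaluation.

#' Average probe-level values to gene level
#'
#' Arithmetic mean of each gene's probes, per sample.
#'
#' @param study an [ExpressionStudy-class] with probe-level features.
#' @param probeToGene named character vector mapping every probe
#'   (feature id) to a gene symbol.
#' @return Gene-level [ExpressionStudy-class]; genes appear in order of
#'   first appearance in `probeToGene[rownames]`.
#' @export
averageByGene <- function(study, probeToGene) {
  v <- exprValues(study)
  genes <- unname(probeToGene[rownames(v)])
  if (anyNA(genes))
    stop("unmapped probes: ",
         paste(rownames(v)[is.na(genes)], collapse = ", "))
  f <- factor(genes, levels = unique(genes))
  m <- rowsum(v, f, reorder = FALSE) / as.vector(table(f))
  expressionStudy(m, sampleGroups(study), platformName(study))
}

#' Min-max normalize each feature to [0, 1]
#'
#' `y = (x - min) / (max - min)` per feature (row) across that study's
#' samples, so each platform is scaled with its own per-feature
#' extremes. A constant feature is set to 0.5 everywhere with a
#' warning.
#'
#' @param study an [ExpressionStudy-class].
#' @return Normalized [ExpressionStudy-class] (same platform tag).
#' @export
minmaxNormalize <- function(study) {
  v <- exprValues(study)
  rng <- apply(v, 1L, range)
  const <- rng[1L, ] == rng[2L, ]
  if (any(const))
    warning("constant feature(s) set to 0.5: ",
            paste(rownames(v)[const], collapse = ", "))
  den <- rng[2L, ] - rng[1L, ]
  den[const] <- 1
  out <- (v - rng[1L, ]) / den
  out[const, ] <- 0.5
  expressionStudy(out, sampleGroups(study), platformName(study))
}

.stratifiedFolds <- function(groups, k, seed) {
  tab <- table(groups)
  if (any(tab < k))
    stop("need at least k = ", k, " samples per class; got ",
         paste(names(tab), tab, sep = "=", collapse = ", "))
  old <- .Random.seed_safe(); on.exit(.restore_seed(old), add = TRUE)
  set.seed(seed)
  fold <- integer(length(groups))
  for (g in unique(groups)) {
    idx <- sample(which(groups == g))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

.fitSvm <- function(x, y, cost = 1, gamma = NULL) {
  if (is.null(gamma)) gamma <- 1 / ncol(x)   # library default: 1/n_features
  e1071::svm(x = x, y = y, kernel = "radial", cost = cost, gamma = gamma,
             scale = FALSE, probability = FALSE)
}

# decision scores oriented so larger = more tumor-like
.svmScores <- function(fit, x) {
  pr <- stats::predict(fit, x, decision.values = TRUE)
  dv <- attr(pr, "decision.values")
  s <- dv[, 1L]
  if (!grepl("^tumor", colnames(dv)[1L])) s <- -s
  list(pred = as.character(pr), score = unname(s))
}

#' Stratified k-fold cross-validation of an RBF-kernel SVM
#'
#' Each sample is predicted exactly once by a model not trained on its
#' fold. Hyperparameters follow common library defaults: `C = 1`,
#' `gamma = 1 / n_features`; features are used as-is (normalize first
#' with [minmaxNormalize()]). Decision scores are pooled out-of-fold
#' and oriented so that larger means more tumor-like.
#'
#' @param study an [ExpressionStudy-class] (features x samples).
#' @param k number of folds (default 5).
#' @param seed RNG seed for the stratified fold assignment.
#' @param cost,gamma SVM hyperparameters; `gamma = NULL` means
#'   `1 / n_features`.
#' @return List: `predicted` (character per sample), `scores` (pooled
#'   out-of-fold decision values), `folds` (fold index per sample),
#'   `confusion` (tp/fp/fn/tn list, positive class = tumor), `report`
#'   (from [confusionMetrics()], with `auc` filled in).
#' @export
crossvalidateSvm <- function(study, k = 5L, seed = 1L, cost = 1,
                             gamma = NULL) {
  g <- sampleGroups(study)
  if (length(unique(g)) < 2L) stop("both classes must be present")
  x <- t(exprValues(study))
  y <- factor(g, levels = c("tumor", "normal"))
  fold <- .stratifiedFolds(g, k, seed)
  pred <- character(length(g)); score <- numeric(length(g))
  for (f in seq_len(k)) {
    te <- fold == f
    fit <- .fitSvm(x[!te, , drop = FALSE], droplevels(y[!te]),
                   cost = cost, gamma = gamma)
    out <- .svmScores(fit, x[te, , drop = FALSE])
    pred[te] <- out$pred; score[te] <- out$score
  }
  cm <- confusionCounts(pred, g)
  rep <- confusionMetrics(cm)
  rep$auc <- aucFromScores(score, g)
  list(predicted = pred, scores = score, folds = fold, confusion = cm,
       report = rep)
}

#' Seeded stratified train/test split
#'
#' Reproduces a random split with a fixed number of samples per group
#' in the training set (e.g. 8 tumor + 8 normal train, remainder test).
#'
#' @param study an [ExpressionStudy-class].
#' @param nPerGroupTrain training samples per group.
#' @param seed RNG seed.
#' @return List with integer sample indices `train` and `test`.
#' @export
splitStudy <- function(study, nPerGroupTrain, seed = 1L) {
  g <- sampleGroups(study)
  old <- .Random.seed_safe(); on.exit(.restore_seed(old), add = TRUE)
  set.seed(seed)
  train <- unlist(lapply(unique(g), function(gr) {
    idx <- which(g == gr)
    if (length(idx) < nPerGroupTrain + 2L)
      stop("not enough '", gr, "' samples to keep >= 2 in the test set")
    sample(idx, nPerGroupTrain)
  }))
  train <- sort(train)
  list(train = train, test = setdiff(seq_along(g), train))
}

#' Cross-platform blind-test evaluation
#'
#' Trains the RBF-SVM on the full training study and applies it once to
#' a blind test study from another platform over a shared gene panel.
#' Both studies are min-max normalized independently (each with its own
#' per-feature extremes); no test data touches training. Internal
#' k-fold cross-validation on the training study is reported alongside.
#'
#' @param train,test gene-level [ExpressionStudy-class] objects.
#' @param genes character vector: the shared gene panel.
#' @param seed RNG seed (fold assignment of the internal CV).
#' @param k internal CV folds on the training study.
#' @param cost,gamma SVM hyperparameters as in [crossvalidateSvm()].
#' @param normalize apply [minmaxNormalize()] to each study (default).
#' @return List: `cv` (internal CV result on the training study),
#'   `confusion` and `report` for the blind test, `predicted`,
#'   `scores`, and `hyperparameters`.
#' @export
crossPlatformEval <- function(train, test, genes, seed = 1L, k = 5L,
                              cost = 1, gamma = NULL, normalize = TRUE) {
  stopifnot(length(genes) > 0L)
  missTr <- setdiff(genes, rownames(exprValues(train)))
  missTe <- setdiff(genes, rownames(exprValues(test)))
  if (length(missTr) || length(missTe))
    stop("panel genes missing from ",
         if (length(missTr)) paste0("training study: ",
                                    paste(missTr, collapse = ", ")) else "",
         if (length(missTr) && length(missTe)) "; " else "",
         if (length(missTe)) paste0("test study: ",
                                    paste(missTe, collapse = ", ")) else "")
  sub <- function(st) expressionStudy(exprValues(st)[genes, , drop = FALSE],
                                      sampleGroups(st), platformName(st))
  train <- sub(train); test <- sub(test)
  if (normalize) {
    train <- minmaxNormalize(train)
    test <- minmaxNormalize(test)
  }
  cv <- crossvalidateSvm(train, k = k, seed = seed, cost = cost,
                         gamma = gamma)
  xTr <- t(exprValues(train)); xTe <- t(exprValues(test))
  yTr <- factor(sampleGroups(train), levels = c("tumor", "normal"))
  if (is.null(gamma)) gamma <- 1 / length(genes)
  fit <- .fitSvm(xTr, yTr, cost = cost, gamma = gamma)
  out <- .svmScores(fit, xTe)
  cm <- confusionCounts(out$pred, sampleGroups(test))
  rep <- confusionMetrics(cm)
  rep$auc <- aucFromScores(out$score, sampleGroups(test))
  list(cv = cv, confusion = cm, report = rep, predicted = out$pred,
       scores = out$score,
       hyperparameters = list(kernel = "radial", cost = cost,
                              gamma = gamma, k = k, seed = seed))
}

#' Confusion counts from predicted and true labels
#'
#' @param predicted,truth character vectors of `tumor` / `normal`
#'   labels; the positive class is `tumor` (HCC).
#' @return List with integer `tp`, `fp`, `fn`, `tn`.
#' @export
confusionCounts <- function(predicted, truth) {
  list(tp = sum(predicted == "tumor" & truth == "tumor"),
       fp = sum(predicted == "tumor" & truth == "normal"),
       fn = sum(predicted == "normal" & truth == "tumor"),
       tn = sum(predicted == "normal" & truth == "normal"))
}

#' Performance metrics from a confusion matrix
#'
#' sensitivity = tp/(tp+fn), specificity = tn/(tn+fp), precision =
#' tp/(tp+fp), accuracy = (tp+tn)/total. A metric whose denominator is
#' zero is returned as `NA` with a warning.
#'
#' @param cm list or vector with `tp`, `fp`, `fn`, `tn` (positive
#'   class = tumor/HCC).
#' @return List with `sensitivity`, `specificity`, `precision`,
#'   `accuracy`, `auc` (`NA` here; filled by score-based callers).
#' @export
#' @examples
#' confusionMetrics(list(tp = 15, fp = 3, fn = 6, tn = 18))
confusionMetrics <- function(cm) {
  cm <- as.list(cm)
  tp <- cm$tp; fp <- cm$fp; fn <- cm$fn; tn <- cm$tn
  total <- tp + fp + fn + tn
  if (total == 0) stop("all-zero confusion matrix")
  safe <- function(num, den, what) {
    if (den == 0) { warning("undefined ", what, " (zero denominator)");
      return(NA_real_) }
    num / den
  }
  list(sensitivity = safe(tp, tp + fn, "sensitivity"),
       specificity = safe(tn, tn + fp, "specificity"),
       precision = safe(tp, tp + fp, "precision"),
       accuracy = (tp + tn) / total,
       auc = NA_real_)
}

#' Rank-based AUC (Mann-Whitney)
#'
#' Area under the ROC curve computed from the rank statistic, with ties
#' counted half. Invariant under strictly monotone transforms of the
#' scores.
#'
#' @param scores numeric vector, larger = more tumor-like.
#' @param labels character vector of `tumor` / `normal`.
#' @return AUC in `[0, 1]`.
#' @export
aucFromScores <- function(scores, labels) {
  pos <- labels == "tumor"
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L) stop("both classes must be present")
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
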