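# Per-feature Box-Cox transformation, Welch two-sample test of
# H0: mu_tumor = mu_normal, and Storey q-value FDR adjustment.

#' Box-Cox power transform
#'
#' `y = (x^lambda - 1) / lambda` for `lambda != 0`, `log(x)` for
#' `lambda = 0`. An `NA` lambda (degenerate estimation, e.g. constant
#' input) falls back to the identity transform.
#'
#' @param x strictly positive numeric vector.
#' @param lambda power parameter.
#' @return Transformed numeric vector.
#' @export
boxCoxTransform <- function(x, lambda) {
  if (is.na(lambda)) return(x)
  if (any(x <= 0)) stop("Box-Cox transform requires strictly positive values")
  if (abs(lambda) < .Machine$double.eps^0.5) log(x) else (x^lambda - 1) / lambda
}

# profile log-likelihood of the Box-Cox model at lambda (normal theory,
# MLE variance, plus the Jacobian term)
.bcLogLik <- function(x, lambda) {
  n <- length(x)
  y <- if (abs(lambda) < 1e-12) log(x) else (x^lambda - 1) / lambda
  s2 <- stats::var(y) * (n - 1) / n
  if (s2 <= 0) return(-Inf)
  -n / 2 * log(s2) + (lambda - 1) * sum(log(x))
}

#' Estimate the Box-Cox lambda by profile likelihood
#'
#' Maximizes the Box-Cox profile log-likelihood over a grid on
#' `[-3, 3]` with step 0.01, then refines the maximum by golden-section
#' search to a tolerance of 1e-5. Log-normal data yield lambda near 0,
#' already-normal positive data lambda near 1.
#'
#' @param x strictly positive numeric vector, length >= 3.
#' @param feature optional feature name used in error messages.
#' @return The estimated lambda; `NA` with a warning for (near-)
#'   constant input, where the likelihood is flat.
#' @export
#' @examples
#' set.seed(1)
#' estimateBoxCoxLambda(exp(rnorm(200)))  # close to 0
estimateBoxCoxLambda <- function(x, feature = NULL) {
  lab <- if (is.null(feature)) "" else paste0(" for feature '", feature, "'")
  if (any(x <= 0))
    stop("non-positive value", lab, "; Box-Cox requires positive data")
  if (length(x) < 3L) stop("need at least 3 values", lab)
  if (stats::sd(x) == 0) {
    warning("constant vector", lab, "; Box-Cox lambda undefined")
    return(NA_real_)
  }
  grid <- seq(-3, 3, by = 0.01)
  ll <- vapply(grid, function(l) .bcLogLik(x, l), 0)
  i <- which.max(ll)
  lo <- grid[max(1L, i - 1L)]; hi <- grid[min(length(grid), i + 1L)]
  stats::optimize(function(l) .bcLogLik(x, l), c(lo, hi), maximum = TRUE,
                  tol = 1e-5)$maximum
}

#' Welch's two-sample t-test
#'
#' Two-sided test of equal means with Welch-Satterthwaite degrees of
#' freedom (no equal-variance assumption). When both groups have zero
#' variance the t statistic is undefined: equal means give `p = 1`
#' (with `t = 0`), unequal means `p = 0` (with infinite `t`), both
#' flagged via the `degenerate` field.
#'
#' @param x,y numeric vectors, each of length >= 2.
#' @return List with `t_stat`, `df`, `p_value`, `degenerate`.
#' @export
welchTest <- function(x, y) {
  stopifnot(length(x) >= 2L, length(y) >= 2L)
  if (stats::sd(x) == 0 && stats::sd(y) == 0) {
    eq <- isTRUE(all.equal(mean(x), mean(y)))
    return(list(t_stat = if (eq) 0 else sign(mean(x) - mean(y)) * Inf,
                df = NA_real_, p_value = if (eq) 1 else 0,
                degenerate = TRUE))
  }
  tt <- stats::t.test(x, y, var.equal = FALSE)
  list(t_stat = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value, degenerate = FALSE)
}

#' Storey q-values
#'
#' False discovery rate adjustment with the null proportion pi0
#' estimated from the p-value distribution: pi0(lambda) =
#' \#\{p > lambda\} / (m (1 - lambda)) on the grid lambda = 0.05, 0.10,
#' ..., 0.95, smoothed with a cubic spline whose lambda -> 1 limit is
#' read off at the top of the grid, then clamped to (0, 1]. q-values are the step-up
#' minima `q(p_(i)) = min_{j >= i} pi0 m p_(j) / j`, returned in input
#' order. With `pi0 = 1` this reduces exactly to Benjamini-Hochberg.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @param pi0 optional fixed null proportion; estimated when `NULL`.
#'   Fewer than 10 p-values force `pi0 = 1` (BH) with a warning.
#' @return Numeric vector of q-values (input order) with attribute
#'   `"pi0"`.
#' @export
storeyQvalues <- function(p, pi0 = NULL) {
  stopifnot(all(p >= 0 & p <= 1))
  m <- length(p)
  if (is.null(pi0)) {
    if (m < 10L) {
      warning("fewer than 10 p-values; falling back to pi0 = 1 (BH)")
      pi0 <- 1
    } else {
      lam <- seq(0.05, 0.95, by = 0.05)
      pi0l <- vapply(lam, function(l) mean(p > l) / (1 - l), 0)
      fit <- stats::smooth.spline(lam, pi0l, df = 3)
      # lambda -> 1 limit read off the smoother at the top of the grid;
      # extrapolating the spline beyond its support is unstable for
      # small m and can collapse pi0 (and hence FDR control) to zero
      pi0 <- stats::predict(fit, x = max(lam))$y
      pi0 <- min(1, max(pi0, 1 / m))  # clamp to (0, 1]
    }
  }
  o <- order(p)  # stable: ties keep input order
  qo <- pi0 * m * p[o] / seq_len(m)
  qo <- pmin(rev(cummin(rev(qo))), 1)
  q <- numeric(m)
  q[o] <- qo
  attr(q, "pi0") <- pi0
  q
}

#' Per-feature differential expression with Box-Cox / Welch / q-values
#'
#' For each feature: a single Box-Cox lambda is estimated on all
#' samples pooled, both groups are transformed with that lambda, and a
#' Welch two-sided test compares tumor vs normal transformed means.
#' Storey q-values are then computed across all features of the study
#' (call separately per panel to keep mRNA and lncRNA adjustments as
#' distinct families). Features containing non-positive values are
#' shifted by `1 - min` before transformation and flagged.
#'
#' @param study an [ExpressionStudy-class].
#' @param pi0 optional fixed pi0 passed to [storeyQvalues()].
#' @return data.frame sorted by `q_value` ascending with columns
#'   `feature_id`, `lambda`, `mean_tumor`, `mean_normal`, `direction`
#'   (`up` iff transformed tumor mean exceeds normal mean), `t_stat`,
#'   `df`, `p_value`, `q_value`, `shifted`.
#' @export
runDE <- function(study, pi0 = NULL) {
  stopifnot(methods::is(study, "ExpressionStudy"))
  v <- exprValues(study)
  grp <- sampleGroups(study)
  tumor <- grp == "tumor"
  rows <- lapply(seq_len(nrow(v)), function(i) {
    x <- v[i, ]
    shifted <- FALSE
    if (any(x <= 0)) { x <- x + (1 - min(x)); shifted <- TRUE }
    lam <- suppressWarnings(estimateBoxCoxLambda(x, feature = rownames(v)[i]))
    y <- boxCoxTransform(x, lam)
    wt <- welchTest(y[tumor], y[!tumor])
    mT <- mean(y[tumor]); mN <- mean(y[!tumor])
    data.frame(feature_id = rownames(v)[i], lambda = lam,
               mean_tumor = mT, mean_normal = mN,
               direction = if (mT > mN) "up" else "down",
               t_stat = wt$t_stat, df = wt$df, p_value = wt$p_value,
               shifted = shifted, stringsAsFactors = FALSE)
  })
  de <- do.call(rbind, rows)
  q <- storeyQvalues(de$p_value, pi0 = pi0)
  de$q_value <- as.numeric(q)
  de <- de[order(de$q_value), c("feature_id", "lambda", "mean_tumor",
                                "mean_normal", "direction", "t_stat",
                                "df", "p_value", "q_value", "shifted")]
  rownames(de) <- NULL
  attr(de, "pi0") <- attr(q, "pi0")
  de
}

#' Write a differential-expression table as TSV
#'
#' @param de data.frame from [runDE()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
writeDETable <- function(de, path) {
  utils::write.table(de, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
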