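#' Binary confusion counts
#'
#' Tallies TP/TN/FP/FN for a binary task. Inputs are 0/1 integer vectors
#' or 2-level factors; the second level (code 1) is the positive class.
#'
#' @param yTrue,yPred Equal-length label vectors.
#' @return Named list with \code{TP}, \code{TN}, \code{FP}, \code{FN}.
#' @export
binaryCounts <- function(yTrue, yPred) {
  t01 <- as01(yTrue); p01 <- as01(yPred)
  if (length(t01) != length(p01)) stop("length mismatch")
  if (length(t01) == 0L) stop("need at least one sample")
  list(TP = sum(t01 == 1 & p01 == 1), TN = sum(t01 == 0 & p01 == 0),
       FP = sum(t01 == 0 & p01 == 1), FN = sum(t01 == 1 & p01 == 0))
}

as01 <- function(y) {
  if (is.factor(y)) return(as.integer(y) - 1L)
  y <- as.integer(y)
  if (!all(y %in% c(0L, 1L))) stop("binary labels must be 0/1")
  y
}

#' Binary classification metrics from confusion counts
#'
#' Accuracy, sensitivity (= recall), specificity, precision and
#' \eqn{F1 = 2 P R / (P + R)}. A zero denominator yields 0 with a
#' warning (the usual convention for degenerate predictors).
#'
#' @param counts Output of \code{\link{binaryCounts}}.
#' @return Named numeric vector of the five metrics.
#' @export
binaryMetrics <- function(counts) {
  n <- counts$TP + counts$TN + counts$FP + counts$FN
  if (n == 0L) stop("empty counts")
  safe <- function(num, den, what) {
    if (den == 0) { warning(what, ": zero denominator, returning 0"); 0 }
    else num / den
  }
  acc <- (counts$TP + counts$TN) / n
  rec <- safe(counts$TP, counts$TP + counts$FN, "sensitivity")
  spe <- safe(counts$TN, counts$TN + counts$FP, "specificity")
  pre <- safe(counts$TP, counts$TP + counts$FP, "precision")
  f1 <- if (pre + rec == 0) 0 else 2 * pre * rec / (pre + rec)
  c(accuracy = acc, sensitivity = rec, specificity = spe,
    precision = pre, f1 = f1)
}

#' Mann-Whitney AUC
#'
#' The pairwise form of the area under the ROC curve:
#' \deqn{AUC = \frac{1}{m_+ m_-} \sum_{x_+} \sum_{x_-}
#'   \big[ 1(f(x_+) > f(x_-)) + \tfrac12\, 1(f(x_+) = f(x_-)) \big]}
#' computed via midranks, so ties contribute one half.
#'
#' @param scores Positive-class scores, one per sample.
#' @param yTrue Binary labels (0/1 or 2-level factor, second level
#'   positive).
#' @return AUC in [0, 1].
#' @examples
#' aucMannWhitney(c(0.9, 0.8, 0.7, 0.8), c(1, 1, 0, 0))  # 0.875
#' @export
aucMannWhitney <- function(scores, yTrue) {
  y <- as01(yTrue)
  mPos <- sum(y == 1); mNeg <- sum(y == 0)
  if (mPos == 0L || mNeg == 0L)
    stop("AUC needs at least one positive and one negative sample")
  r <- rank(scores)                       # midranks handle ties as 1/2
  (sum(r[y == 1]) - mPos * (mPos + 1) / 2) / (mPos * mNeg)
}

#' Multiclass confusion matrix
#'
#' @param yTrue,yPred Factors or integer codes over the same C classes.
#' @param nClasses Number of classes (inferred from factor levels when
#'   omitted).
#' @return C x C integer matrix, rows = true class, columns = predicted.
#' @export
confusionMatrix <- function(yTrue, yPred, nClasses = NULL) {
  if (is.factor(yTrue)) {
    if (is.null(nClasses)) nClasses <- nlevels(yTrue)
    yTrue <- as.integer(yTrue); yPred <- as.integer(yPred)
  } else if (is.null(nClasses)) nClasses <- max(yTrue, yPred)
  if (length(yTrue) != length(yPred)) stop("length mismatch")
  cm <- matrix(0L, nClasses, nClasses)
  for (i in seq_along(yTrue))
    cm[yTrue[i], yPred[i]] <- cm[yTrue[i], yPred[i]] + 1L
  cm
}

perClassPR <- function(cm) {
  tp <- diag(cm)
  predTot <- colSums(cm); trueTot <- rowSums(cm)
  P <- ifelse(predTot > 0, tp / pmax(predTot, 1L), 0)
  R <- ifelse(trueTot > 0, tp / pmax(trueTot, 1L), 0)
  list(P = P, R = R)
}

#' Macro F1 (harmonic mean of macro-averaged precision and recall)
#'
#' \deqn{F1_{macro} = \frac{2 \cdot P_{macro} \cdot R_{macro}}
#'   {P_{macro} + R_{macro}}}
#' with \eqn{P_{macro}} and \eqn{R_{macro}} the unweighted means of the
#' per-class precisions and recalls. Note this is \emph{not} the mean of
#' per-class F1 scores (the two differ on imbalanced confusions); a class
#' with undefined precision or recall contributes 0.
#'
#' @param cm C x C confusion matrix (rows = true class).
#' @return Macro F1 in [0, 1].
#' @export
f1Macro <- function(cm) {
  if (length(cm) == 0L || nrow(cm) < 2L) stop("need a C x C matrix, C >= 2")
  pr <- perClassPR(cm)
  Pm <- mean(pr$P); Rm <- mean(pr$R)
  if (Pm + Rm == 0) 0 else 2 * Pm * Rm / (Pm + Rm)
}

#' Support-weighted F1
#'
#' \eqn{\sum_c w_c F1_c} with per-class one-vs-rest F1 scores and weights
#' \eqn{w_c} equal to each class's share of the true labels.
#'
#' @param cm C x C confusion matrix (rows = true class).
#' @return Weighted F1 in [0, 1].
#' @export
f1Weighted <- function(cm) {
  if (length(cm) == 0L || nrow(cm) < 2L) stop("need a C x C matrix, C >= 2")
  pr <- perClassPR(cm)
  f1 <- ifelse(pr$P + pr$R > 0, 2 * pr$P * pr$R / pmax(pr$P + pr$R, 1e-300), 0)
  w <- rowSums(cm) / sum(cm)
  sum(w * f1)
}

#' Accuracy from a confusion matrix
#' @param cm C x C confusion matrix.
#' @return Fraction of correctly classified samples.
#' @export
accuracyFromConfusion <- function(cm) sum(diag(cm)) / sum(cm)
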