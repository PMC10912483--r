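#' Chi-square association scores for every feature
#'
#' Scores each feature of an omics view for association with the class
#' labels. Because omics values are continuous, the contingency table is
#' built from non-negative "feature mass": the observed count for class c
#' is the sum of the feature over the samples of class c, and the expected
#' count is the class share of the feature's total. The score is the usual
#' \eqn{\sum_c (O_c - E_c)^2 / E_c}; a feature whose class-wise sums match
#' the class sizes exactly (e.g. any constant feature) scores 0.
#'
#' Values must be non-negative; views that contain negatives (CNV log
#' ratios, for instance) should be min-max shifted per feature first.
#'
#' @param view An \code{\linkS4class{OmicsView}} with non-negative values.
#' @param labels Named factor of class labels covering the view's samples.
#' @return A \code{FeatureRanking}: list with \code{featureIDs},
#'   \code{scores} (one per feature of the view, in view order) and
#'   \code{selected} (all feature indices, sorted by descending score,
#'   ties broken by ascending index).
#' @export
chi2Scores <- function(view, labels) {
  X <- omicsValues(view)
  y <- labels[rownames(X)]
  if (anyNA(y)) stop("labels missing for some samples of the view")
  y <- droplevels(y)
  if (nlevels(y) < 2L) stop("need at least 2 classes present")
  if (any(table(y) == 0L)) stop("a class has 0 samples")
  if (min(X) < 0)
    stop("negative values: min-max normalize (shift) the view before chi-square scoring")
  Z <- stats::model.matrix(~ y - 1)           # n x C indicator
  O <- crossprod(Z, X)                        # C x d class-wise sums
  total <- colSums(X)
  prop <- as.numeric(table(y)) / nrow(X)
  E <- outer(prop, total)                     # C x d expected
  dev <- (O - E)^2
  sc <- colSums(ifelse(E > 0, dev / pmax(E, .Machine$double.xmin), 0))
  sc[total == 0] <- 0
  newFeatureRanking(featureIDs(view), as.numeric(sc))
}

newFeatureRanking <- function(ids, scores, selected = NULL) {
  if (is.null(selected))
    selected <- order(-scores, seq_along(scores))
  structure(list(featureIDs = ids, scores = scores, selected = selected),
            class = "FeatureRanking")
}

#' @export
print.FeatureRanking <- function(x, ...) {
  cat(sprintf("FeatureRanking: %d features scored, %d selected\n",
              length(x$scores), length(x$selected)))
  top <- utils::head(x$selected, 5L)
  cat("  top:", paste(sprintf("%s (%.3g)", x$featureIDs[top],
                              x$scores[top]), collapse = ", "), "\n")
  invisible(x)
}

#' Keep the k best-scoring features of a ranking
#'
#' Ties are broken by ascending original feature index, so the result is
#' deterministic. If \code{k} exceeds the number of features, all features
#' are kept.
#'
#' @param ranking A \code{FeatureRanking}.
#' @param k Number of features to keep (default 5000).
#' @return The ranking with \code{selected} truncated to the top k.
#' @export
selectTopK <- function(ranking, k = 5000L) {
  if (k <= 0) stop("k must be >= 1")
  ord <- order(-ranking$scores, seq_along(ranking$scores))
  newFeatureRanking(ranking$featureIDs, ranking$scores,
                    ord[seq_len(min(k, length(ord)))])
}

#' Per-feature linear min-max normalization to [0, 1]
#'
#' Each feature column is mapped by \eqn{(x - min) / (max - min)}.
#' Constant columns (zero range) map to 0 everywhere.
#'
#' @param view An \code{\linkS4class{OmicsView}}.
#' @return The normalized \code{\linkS4class{OmicsView}}.
#' @export
minmaxNormalize <- function(view) {
  X <- omicsValues(view)
  if (anyNA(X)) stop("missing values in view '", viewName(view), "'")
  lo <- apply(X, 2L, min)
  hi <- apply(X, 2L, max)
  rng <- hi - lo
  Xn <- sweep(X, 2L, lo, "-")
  pos <- rng > 0
  Xn[, pos] <- sweep(Xn[, pos, drop = FALSE], 2L, rng[pos], "/")
  Xn[, !pos] <- 0
  OmicsView(Xn, viewName(view))
}

# Equal-frequency (quantile) discretization of one numeric vector into at
# most `bins` bins; returns integer codes 1..nbins. Degenerate features
# collapse to a single bin.
discretizeQuantile <- function(x, bins) {
  br <- unique(stats::quantile(x, probs = seq(0, 1, length.out = bins + 1),
                               names = FALSE, type = 7))
  if (length(br) < 2L) return(rep.int(1L, length(x)))
  .bincode(x, br, right = TRUE, include.lowest = TRUE)
}

# Discrete mutual information (nats) between two integer code vectors.
mutualInformation <- function(xi, yi, kx = max(xi), ky = max(yi)) {
  n <- length(xi)
  joint <- tabulate((xi - 1L) * ky + yi, kx * ky) / n
  px <- tabulate(xi, kx) / n
  py <- tabulate(yi, ky) / n
  outerp <- as.vector(outer(py, px))          # matches joint's ordering
  pos <- joint > 0
  sum(joint[pos] * log(joint[pos] / outerp[pos]))
}

#' Greedy mRMR feature selection (difference criterion)
#'
#' Minimum-redundancy maximum-relevance forward selection. Relevance and
#' redundancy are discrete mutual information values computed after
#' per-feature quantile discretization into \code{bins} equal-frequency
#' bins. At each step the feature maximizing
#' \deqn{I(f; y) - \frac{1}{|S|}\sum_{g \in S} I(f; g)}
#' is added (the MID, "difference", criterion); the first feature is the
#' one with maximum relevance. Ties break by ascending feature index, so
#' the selection is fully deterministic.
#'
#' @param view An \code{\linkS4class{OmicsView}}, normally already
#'   min-max normalized.
#' @param labels Named factor of class labels.
#' @param m Number of features to select (default 500); clamped to the
#'   number of features with a warning.
#' @param bins Number of quantile bins for discretization (default 5).
#' @return A \code{FeatureRanking} whose \code{selected} is the m chosen
#'   feature indices in selection order and whose \code{scores} hold each
#'   feature's MID score at the step it was selected (relevance for the
#'   first; unselected features score NA).
#' @export
mrmrSelect <- function(view, labels, m = 500L, bins = 5L) {
  X <- omicsValues(view)
  y <- labels[rownames(X)]
  if (anyNA(y)) stop("labels missing for some samples of the view")
  if (m < 1) stop("m must be >= 1")
  if (bins < 2) stop("bins must be >= 2")
  d <- ncol(X)
  if (m > d) {
    warning(sprintf("m = %d exceeds the %d available features; clamping", m, d))
    m <- d
  }
  disc <- lapply(seq_len(d), function(j) discretizeQuantile(X[, j], bins))
  nb <- vapply(disc, max, integer(1))
  yi <- as.integer(droplevels(y)); ky <- max(yi)
  rel <- vapply(seq_len(d), function(j)
    mutualInformation(disc[[j]], yi, nb[j], ky), numeric(1))

  selected <- integer(m)
  stepScore <- rep(NA_real_, d)
  redSum <- numeric(d)
  remaining <- rep(TRUE, d)
  for (s in seq_len(m)) {
    score <- if (s == 1L) rel else rel - redSum / (s - 1L)
    score[!remaining] <- -Inf
    pick <- which.max(score)                  # first max = ascending-index tie-break
    selected[s] <- pick
    stepScore[pick] <- score[pick]
    remaining[pick] <- FALSE
    if (s < m) {
      idx <- which(remaining)
      redSum[idx] <- redSum[idx] + vapply(idx, function(j)
        mutualInformation(disc[[j]], disc[[pick]], nb[j], nb[pick]),
        numeric(1))
    }
  }
  newFeatureRanking(featureIDs(view), stepScore, selected)
}

#' The full per-view feature-selection cascade
#'
#' Applies, in order: chi-square scoring and top-\code{kChi2} cut,
#' per-feature min-max normalization to [0, 1], and greedy mRMR selection
#' of the top \code{mMrmr} features. Views containing negative values are
#' min-max shifted before the chi-square stage so its non-negativity
#' requirement holds. The returned view holds the normalized values of the
#' final feature set, which is what the graph-construction stage consumes.
#'
#' @param view An \code{\linkS4class{OmicsView}}.
#' @param labels Named factor of class labels.
#' @param kChi2 Chi-square stage cut (default 5000).
#' @param mMrmr mRMR stage cut (default 500).
#' @param bins Quantile bins for the mutual-information estimates.
#' @return List with \code{view} (reduced, normalized
#'   \code{\linkS4class{OmicsView}} with \code{min(mMrmr, kChi2, d)}
#'   features), \code{chi2} and \code{mrmr} (the two
#'   \code{FeatureRanking}s, the latter indexed into the chi-square-reduced
#'   view).
#' @export
selectFeatures <- function(view, labels, kChi2 = 5000L, mMrmr = 500L,
                           bins = 5L) {
  if (kChi2 < mMrmr) stop("need kChi2 >= mMrmr")
  X <- omicsValues(view)
  if (min(X) < 0) view <- minmaxNormalize(view)
  chi2 <- selectTopK(chi2Scores(view, labels), kChi2)
  reduced <- OmicsView(
    omicsValues(view)[, chi2$selected, drop = FALSE], viewName(view))
  norm <- minmaxNormalize(reduced)
  mr <- mrmrSelect(norm, labels, m = min(mMrmr, ncol(omicsValues(norm))),
                   bins = bins)
  out <- OmicsView(omicsValues(norm)[, mr$selected, drop = FALSE],
                   viewName(view))
  list(view = out, chi2 = chi2, mrmr = mr)
}
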