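#' Stratified cross-validation folds with a validation hold-out
#'
#' Splits the labelled samples into \code{nFolds} stratified test folds;
#' within each fold's training portion a stratified fraction is held out
#' for early-stopping validation. The split is a deterministic function of
#' the labels and the seed.
#'
#' @param labels Named factor of class labels.
#' @param nFolds Number of folds (default 5).
#' @param valFraction Fraction of each training portion held out for
#'   validation, stratified per class (default 0.2).
#' @param seed Integer seed.
#' @return List of \code{nFolds} splits, each a list with \code{fold},
#'   \code{train}, \code{val}, \code{test} (disjoint integer indices into
#'   the label order).
#' @export
makeFolds <- function(labels, nFolds = 5L, valFraction = 0.2, seed = 1L) {
  y <- droplevels(as.factor(labels))
  if (nFolds < 2L) stop("nFolds must be >= 2")
  tab <- table(y)
  if (any(tab < nFolds))
    stop(sprintf("class '%s' has only %d samples, fewer than %d folds",
                 names(tab)[which(tab < nFolds)[1L]],
                 min(tab), nFolds))
  withSeed(seed, {
    shuffled <- lapply(levels(y), function(cl) sample(which(y == cl)))
    assign <- lapply(shuffled, function(idx)
      rep_len(seq_len(nFolds), length(idx)))
    lapply(seq_len(nFolds), function(f) {
      test <- integer(); val <- integer(); train <- integer()
      for (c in seq_along(shuffled)) {
        idx <- shuffled[[c]]; a <- assign[[c]]
        test <- c(test, idx[a == f])
        pool <- idx[a != f]
        nval <- min(max(1L, round(valFraction * length(pool))),
                    length(pool) - 1L)
        val <- c(val, pool[seq_len(nval)])
        train <- c(train, pool[-seq_len(nval)])
      }
      list(fold = f, train = sort(train), val = sort(val),
           test = sort(test))
    })
  })
}

# ---- parameter flattening for the optimizer -------------------------------

getParams <- function(model) {
  p <- list()
  for (v in seq_along(model@encoders))
    for (l in 1:3) p[[sprintf("enc%d.W%d", v, l)]] <- model@encoders[[v]][[l]]
  p[["fusion.Wa"]] <- model@fusion$Wa
  p[["fusion.a"]] <- model@fusion$a
  p[["cls.C"]] <- model@classifier$C
  p[["cls.b"]] <- model@classifier$b
  p
}

setParams <- function(model, p) {
  for (v in seq_along(model@encoders))
    for (l in 1:3)
      model@encoders[[v]][[l]] <- p[[sprintf("enc%d.W%d", v, l)]]
  model@fusion$Wa <- p[["fusion.Wa"]]
  model@fusion$a <- p[["fusion.a"]]
  model@classifier$C <- p[["cls.C"]]
  model@classifier$b <- p[["cls.b"]]
  model
}

flattenGrads <- function(g) {
  p <- list()
  for (v in seq_along(g$encoders))
    for (l in 1:3) p[[sprintf("enc%d.W%d", v, l)]] <- g$encoders[[v]][[l]]
  p[["fusion.Wa"]] <- g$fusion$Wa
  p[["fusion.a"]] <- g$fusion$a
  p[["cls.C"]] <- g$classifier$C
  p[["cls.b"]] <- g$classifier$b
  p
}

asMatrices <- function(xs, accessor) {
  lapply(xs, function(x) {
    if (is(x, "OmicsView")) omicsValues(x)
    else if (is(x, "PatientGraph")) accessor(x)
    else as.matrix(x)
  })
}

#' Train the multi-view GCN on one fold
#'
#' Transductive full-batch training: every sample sits in the graphs, and
#' the mean masked cross-entropy over the fold's training indices is
#' minimized with Adam (L2 weight decay). After each epoch the loss on
#' the validation indices is evaluated in deterministic mode; training
#' stops when the validation loss has not improved by at least
#' \code{minDelta} for \code{patience} consecutive epochs (or at
#' \code{maxEpochs}), and the parameters from the best validation epoch
#' are returned.
#'
#' @param views List of \code{\linkS4class{OmicsView}} (or matrices),
#'   all with identical sample order.
#' @param graphs List of \code{\linkS4class{PatientGraph}} (or
#'   renormalized adjacency matrices), one per view.
#' @param labels Named factor over the same samples, same order.
#' @param split One fold from \code{\link{makeFolds}}.
#' @param config Configuration list (see \code{\link{defaultConfig}}).
#' @return List with \code{model} (best
#'   \code{\linkS4class{MVGNNModel}}), \code{history} (data.frame of
#'   epoch, trainLoss, valLoss), \code{bestEpoch}, \code{stoppedEpoch}.
#' @export
trainFold <- function(views, graphs, labels, split, config = defaultConfig()) {
  Xs <- asMatrices(views, omicsValues)
  Ms <- asMatrices(graphs, normalizedAdjacency)
  y <- droplevels(as.factor(labels))
  tr <- config$training
  md <- config$model
  viewDims <- vapply(Xs, ncol, integer(1))
  names(viewDims) <- vapply(seq_along(views), function(v)
    if (is(views[[v]], "OmicsView")) viewName(views[[v]])
    else paste0("view", v), character(1))
  minDelta <- if (is.null(tr$minDelta)) 1e-4 else tr$minDelta

  withSeed(tr$seed + 1000L * split$fold, {
    model <- initMVGNN(viewDims, levels(y), hiddenDims = md$hiddenDims,
                       attentionDim = md$attentionDim, dropout = md$dropout)
    p <- getParams(model)
    mAdam <- lapply(p, function(x) x * 0)
    vAdam <- lapply(p, function(x) x * 0)
    b1 <- 0.9; b2 <- 0.999; epsA <- 1e-8
    best <- p; bestVal <- Inf; bestEpoch <- 0L; wait <- 0L
    hist <- data.frame(epoch = integer(), trainLoss = numeric(),
                       valLoss = numeric())
    stoppedEpoch <- tr$maxEpochs
    for (epoch in seq_len(tr$maxEpochs)) {
      gr <- mvgnnGradients(model, Xs, Ms, y, split$train, training = TRUE)
      if (!is.finite(gr$loss))
        stop("training diverged (non-finite loss) at epoch ", epoch)
      g <- flattenGrads(gr$grads)
      for (k in names(p)) {
        gk <- g[[k]] + tr$weightDecay * p[[k]]
        mAdam[[k]] <- b1 * mAdam[[k]] + (1 - b1) * gk
        vAdam[[k]] <- b2 * vAdam[[k]] + (1 - b2) * gk^2
        mhat <- mAdam[[k]] / (1 - b1^epoch)
        vhat <- vAdam[[k]] / (1 - b2^epoch)
        p[[k]] <- p[[k]] - tr$lr * mhat / (sqrt(vhat) + epsA)
      }
      model <- setParams(model, p)
      fwEval <- mvgnnForward(model, Xs, Ms, training = FALSE)
      valLoss <- maskedCrossEntropy(fwEval$probs, y, split$val)
      hist <- rbind(hist, data.frame(epoch = epoch, trainLoss = gr$loss,
                                     valLoss = valLoss))
      if (bestVal - valLoss >= minDelta) {
        bestVal <- valLoss; best <- p; bestEpoch <- epoch; wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= tr$patience) { stoppedEpoch <- epoch; break }
      }
    }
    list(model = setParams(model, best), history = hist,
         bestEpoch = bestEpoch, stoppedEpoch = stoppedEpoch)
  })
}

#' Evaluate a trained model on a fold's test indices
#'
#' Binary tasks report accuracy, Mann-Whitney AUC (positive-class
#' probability as the score) and F1; tasks with three or more classes
#' report accuracy, support-weighted F1 and macro F1. An AUC that is
#' undefined because the test fold contains a single class is reported
#' as NA.
#'
#' @inheritParams trainFold
#' @param model A trained \code{\linkS4class{MVGNNModel}}.
#' @return List with \code{metrics} (named numeric vector) and
#'   \code{predictions} (data.frame: sample_id, true, pred, one score
#'   column per class).
#' @export
evaluateFold <- function(model, views, graphs, labels, split) {
  if (length(split$test) == 0L) stop("empty test fold")
  Xs <- asMatrices(views, omicsValues)
  Ms <- asMatrices(graphs, normalizedAdjacency)
  y <- droplevels(as.factor(labels))
  fw <- mvgnnForward(model, Xs, Ms, training = FALSE)
  idx <- split$test
  pred <- factor(levels(y)[max.col(fw$probs, ties.method = "first")],
                 levels = levels(y))
  cm <- confusionMatrix(y[idx], pred[idx], nClasses = nlevels(y))
  if (nlevels(y) == 2L) {
    auc <- tryCatch(aucMannWhitney(fw$probs[idx, 2L], y[idx]),
                    error = function(e) NA_real_)
    bm <- suppressWarnings(
      binaryMetrics(binaryCounts(y[idx], pred[idx])))
    metrics <- c(accuracy = unname(bm["accuracy"]), auc = auc,
                 f1 = unname(bm["f1"]))
  } else {
    metrics <- c(accuracy = accuracyFromConfusion(cm),
                 f1Weighted = f1Weighted(cm), f1Macro = f1Macro(cm))
  }
  preds <- data.frame(sample_id = names(labels)[idx],
                      true = as.character(y[idx]),
                      pred = as.character(pred[idx]))
  sc <- fw$probs[idx, , drop = FALSE]
  colnames(sc) <- paste0("score_", levels(y))
  list(metrics = metrics, predictions = cbind(preds, sc))
}

#' Cross-validated evaluation of the multi-view GCN pipeline
#'
#' Builds one patient graph per view, forms stratified folds, trains a
#' model per fold (transductively: the graphs span all samples, only
#' labels are masked) and aggregates the per-fold test metrics. The whole
#' run is a deterministic function of the inputs, the configuration and
#' its seed.
#'
#' @param views List of \code{\linkS4class{OmicsView}} objects (already
#'   feature-selected; see \code{\link{selectFeatures}}).
#' @param labels Named factor of class labels.
#' @param config Configuration list (see \code{\link{defaultConfig}}).
#' @return A \code{CVResult}: list with \code{perFold} (data.frame of
#'   fold metrics), \code{summary} (mean and sd per metric),
#'   \code{folds}, \code{histories} and \code{graphs}.
#' @export
crossValidate <- function(views, labels, config = defaultConfig()) {
  al <- alignViews(views, labels)
  views <- al$views; labels <- al$labels
  graphs <- lapply(views, buildPatientGraph, k = config$graph$kAvgDegree)
  folds <- makeFolds(labels, nFolds = config$cv$nFolds,
                     valFraction = config$cv$valFraction,
                     seed = config$training$seed)
  perFold <- NULL; histories <- list()
  for (split in folds) {
    fit <- trainFold(views, graphs, labels, split, config)
    ev <- evaluateFold(fit$model, views, graphs, labels, split)
    perFold <- rbind(perFold,
                     data.frame(fold = split$fold, t(ev$metrics)))
    histories[[split$fold]] <- fit$history
  }
  metricCols <- setdiff(colnames(perFold), "fold")
  summary <- data.frame(
    metric = metricCols,
    mean = vapply(metricCols, function(m) mean(perFold[[m]]), numeric(1)),
    sd = vapply(metricCols, function(m) stats::sd(perFold[[m]]), numeric(1)),
    row.names = NULL)
  structure(list(perFold = perFold, summary = summary, folds = folds,
                 histories = histories, graphs = graphs),
            class = "CVResult")
}

#' @export
print.CVResult <- function(x, ...) {
  cat(sprintf("Cross-validation over %d folds\n", nrow(x$perFold)))
  for (i in seq_len(nrow(x$summary)))
    cat(sprintf("  %-11s %.4f +/- %.4f\n", x$summary$metric[i],
                x$summary$mean[i], x$summary$sd[i]))
  invisible(x)
}

#' View-subset ablation study
#'
#' Runs \code{\link{crossValidate}} for every non-empty subset of the
#' views (2^V - 1 runs) under the same configuration and seed, to measure
#' what each omics layer and each combination contributes.
#'
#' @inheritParams crossValidate
#' @return data.frame with one row per subset: the member view names,
#'   the subset size, and the mean of each CV metric.
#' @export
viewAblation <- function(views, labels, config = defaultConfig()) {
  V <- length(views)
  out <- NULL
  for (size in seq_len(V)) {
    combos <- utils::combn(V, size, simplify = FALSE)
    for (cb in combos) {
      cv <- crossValidate(views[cb], labels, config)
      means <- stats::setNames(cv$summary$mean, cv$summary$metric)
      out <- rbind(out, data.frame(
        views = paste(vapply(views[cb], viewName, character(1)),
                      collapse = "+"),
        nViews = size, t(means)))
    }
  }
  out
}
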