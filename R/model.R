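#' One graph convolutional layer
#'
#' Computes \eqn{\sigma(\tilde A H W)} with \eqn{\sigma} = ReLU when
#' \code{activate} is \code{TRUE} and the identity otherwise. Inverted
#' dropout (scaling by \eqn{1/(1-p)}) is applied to the output only in
#' training mode, drawing from the current RNG stream; evaluation mode is
#' fully deterministic.
#'
#' @param H Node feature matrix (n x d_in).
#' @param Anorm Renormalized adjacency from
#'   \code{\link{normalizeAdjacency}}.
#' @param W Layer weight matrix (d_in x d_out).
#' @param activate Apply ReLU (default \code{TRUE}).
#' @param dropout Dropout rate in [0, 1).
#' @param training Draw and apply a dropout mask (default \code{FALSE}).
#' @return The (n x d_out) output matrix.
#' @export
gcnLayer <- function(H, Anorm, W, activate = TRUE, dropout = 0,
                     training = FALSE) {
  if (ncol(Anorm) != nrow(H)) stop("Anorm and H shapes do not conform")
  if (ncol(H) != nrow(W)) stop("H and W shapes do not conform")
  Z <- Anorm %*% H %*% W
  if (activate) Z <- pmax(Z, 0)
  if (training && dropout > 0) {
    keep <- matrix(stats::runif(length(Z)) >= dropout, nrow(Z), ncol(Z))
    Z <- Z * keep / (1 - dropout)
  }
  Z
}

#' Encode one omics view with a three-layer GCN
#'
#' Applies three stacked graph convolutions: ReLU after layers 1 and 2,
#' no activation after layer 3 (the embedding feeds the attention module).
#' Dropout layers sit after layers 1 and 2 only, and only act in training
#' mode.
#'
#' @param X View feature matrix (n x d).
#' @param Anorm Renormalized adjacency of the view's patient graph.
#' @param weights List of the 3 layer weight matrices.
#' @param dropout Dropout rate for the two dropout layers.
#' @param training Training mode flag.
#' @return The (n x h3) node embedding matrix.
#' @export
encodeView <- function(X, Anorm, weights, dropout = 0, training = FALSE) {
  stopifnot(length(weights) == 3L)
  H1 <- gcnLayer(X, Anorm, weights[[1L]], TRUE, dropout, training)
  H2 <- gcnLayer(H1, Anorm, weights[[2L]], TRUE, dropout, training)
  gcnLayer(H2, Anorm, weights[[3L]], activate = FALSE)
}

#' Attention fusion of per-view node embeddings
#'
#' A shared scorer assigns each view an importance per node:
#' \eqn{e_{iv} = a^\top \tanh(W_a h_{iv})}, normalized across views by a
#' softmax into weights \eqn{\alpha_{iv}}; the fused embedding is
#' \eqn{\sum_v \alpha_{iv} h_{iv}}. With a single view the weights are
#' identically 1; identical embeddings across views give uniform weights
#' \eqn{1/V}.
#'
#' @param embeddings List of V (n x h3) embedding matrices.
#' @param fusion List with \code{Wa} (attention_dim x h3) and \code{a}
#'   (attention_dim).
#' @return List with \code{fused} (n x h3) and \code{alpha} (n x V, rows
#'   summing to 1).
#' @export
attentionFuse <- function(embeddings, fusion) {
  V <- length(embeddings)
  if (V < 1L) stop("need at least one view embedding")
  dims <- vapply(embeddings, dim, integer(2))
  if (any(dims != dims[, 1L])) stop("embeddings must share one shape")
  scores <- vapply(embeddings, function(E)
    as.numeric(tanh(E %*% t(fusion$Wa)) %*% fusion$a),
    numeric(nrow(embeddings[[1L]])))
  scores <- matrix(scores, ncol = V)
  alpha <- softmaxRows(scores)
  fused <- matrix(0, nrow(alpha), ncol(embeddings[[1L]]))
  for (v in seq_len(V)) fused <- fused + alpha[, v] * embeddings[[v]]
  list(fused = fused, alpha = alpha)
}

softmaxRows <- function(L) {
  L <- L - apply(L, 1L, max)
  E <- exp(L)
  E / rowSums(E)
}

#' Softmax classification of fused embeddings
#'
#' @param fused Fused embedding matrix (n x h3).
#' @param classifier List with weight matrix \code{C} (h3 x n_classes)
#'   and bias \code{b}.
#' @return An (n x C) matrix of class probabilities, rows summing to 1.
#' @export
classifyNodes <- function(fused, classifier) {
  logits <- fused %*% classifier$C +
    matrix(classifier$b, nrow(fused), length(classifier$b), byrow = TRUE)
  if (!all(is.finite(logits))) stop("non-finite logits")
  P <- softmaxRows(logits)
  colnames(P) <- colnames(classifier$C)
  rownames(P) <- rownames(fused)
  P
}

#' Masked cross-entropy loss
#'
#' \eqn{L = -\sum_{l \in mask} \ln p_{l, y_l}}, the semi-supervised loss
#' evaluated only on the masked (labelled) nodes. The default divides by
#' the mask size (\code{reduce = "mean"}) so the learning-rate scale does
#' not depend on the number of labelled nodes; \code{reduce = "sum"} gives
#' the plain sum form.
#'
#' @param probs (n x C) class probability matrix.
#' @param y Integer class codes (1..C) or factor, length n.
#' @param mask Integer indices of the nodes entering the loss.
#' @param reduce \code{"mean"} (default) or \code{"sum"}.
#' @return The loss value.
#' @export
maskedCrossEntropy <- function(probs, y, mask, reduce = c("mean", "sum")) {
  reduce <- match.arg(reduce)
  if (length(mask) == 0L) stop("empty mask")
  yi <- if (is.factor(y)) as.integer(y) else as.integer(y)
  p <- probs[cbind(mask, yi[mask])]
  L <- -sum(log(pmax(p, .Machine$double.xmin)))
  if (reduce == "mean") L / length(mask) else L
}

glorot <- function(nin, nout) {
  lim <- sqrt(6 / (nin + nout))
  matrix(stats::runif(nin * nout, -lim, lim), nin, nout)
}

#' Initialise a multi-view GCN model
#'
#' Weights are Glorot-uniform draws from the current RNG stream (seed it
#' for reproducibility); biases start at zero.
#'
#' @param viewDims Named integer vector: input feature count per view.
#' @param classNames Character vector of class labels.
#' @param hiddenDims The 3 hidden layer widths (default 400, 400, 200).
#' @param attentionDim Width of the attention projection (default 64).
#' @param dropout Dropout rate stored in the model config.
#' @return An \code{\linkS4class{MVGNNModel}}.
#' @export
initMVGNN <- function(viewDims, classNames, hiddenDims = c(400L, 400L, 200L),
                      attentionDim = 64L, dropout = 0.5) {
  stopifnot(length(hiddenDims) == 3L)
  h <- as.integer(hiddenDims)
  encoders <- lapply(viewDims, function(d)
    list(glorot(d, h[1L]), glorot(h[1L], h[2L]), glorot(h[2L], h[3L])))
  fusion <- list(Wa = glorot(attentionDim, h[3L]),
                 a = as.numeric(glorot(attentionDim, 1L)))
  C <- glorot(h[3L], length(classNames))
  colnames(C) <- classNames
  classifier <- list(C = C, b = numeric(length(classNames)))
  vn <- names(viewDims)
  if (is.null(vn)) vn <- paste0("view", seq_along(viewDims))
  new("MVGNNModel", encoders = encoders, fusion = fusion,
      classifier = classifier, viewNames = vn,
      classNames = as.character(classNames),
      config = list(hiddenDims = h, attentionDim = as.integer(attentionDim),
                    dropout = dropout))
}

#' Forward pass of the multi-view GCN
#'
#' Encodes every view, fuses the embeddings by attention, and classifies.
#' Evaluation mode (\code{training = FALSE}) is deterministic.
#'
#' @param model An \code{\linkS4class{MVGNNModel}}.
#' @param Xs List of view feature matrices (n x d_v each).
#' @param Anorms List of renormalized adjacencies, one per view.
#' @param training Training mode flag (activates dropout).
#' @return List with \code{probs} (n x C), \code{fused}, \code{alpha},
#'   and \code{embeddings} (list per view).
#' @export
mvgnnForward <- function(model, Xs, Anorms, training = FALSE) {
  dropout <- if (training) model@config$dropout else 0
  emb <- lapply(seq_along(Xs), function(v)
    encodeView(Xs[[v]], Anorms[[v]], model@encoders[[v]], dropout, training))
  fz <- attentionFuse(emb, model@fusion)
  probs <- classifyNodes(fz$fused, model@classifier)
  list(probs = probs, fused = fz$fused, alpha = fz$alpha, embeddings = emb)
}

# ---- internal: forward with caches + analytic gradients -------------------

# Forward pass retaining every intermediate needed for backpropagation.
# Dropout masks are drawn here (training mode) so the backward pass reuses
# the identical masks.
mvgnnForwardCached <- function(model, Xs, Anorms, training, dropout) {
  V <- length(Xs)
  caches <- vector("list", V)
  emb <- vector("list", V)
  for (v in seq_len(V)) {
    W <- model@encoders[[v]]
    M <- Anorms[[v]]
    P0 <- M %*% Xs[[v]]
    Z1 <- P0 %*% W[[1L]]
    H1 <- pmax(Z1, 0)
    if (training && dropout > 0) {
      B1 <- matrix(stats::runif(length(H1)) >= dropout, nrow(H1), ncol(H1))
      D1 <- H1 * B1 / (1 - dropout)
    } else { B1 <- NULL; D1 <- H1 }
    P1 <- M %*% D1
    Z2 <- P1 %*% W[[2L]]
    H2 <- pmax(Z2, 0)
    if (training && dropout > 0) {
      B2 <- matrix(stats::runif(length(H2)) >= dropout, nrow(H2), ncol(H2))
      D2 <- H2 * B2 / (1 - dropout)
    } else { B2 <- NULL; D2 <- H2 }
    P2 <- M %*% D2
    E <- P2 %*% W[[3L]]
    emb[[v]] <- E
    caches[[v]] <- list(P0 = P0, Z1 = Z1, B1 = B1, P1 = P1, Z2 = Z2,
                        B2 = B2, P2 = P2)
  }
  Wa <- model@fusion$Wa; a <- model@fusion$a
  Tl <- lapply(emb, function(E) tanh(E %*% t(Wa)))     # n x A per view
  scores <- vapply(Tl, function(Tm) as.numeric(Tm %*% a),
                   numeric(nrow(emb[[1L]])))
  scores <- matrix(scores, ncol = V)
  alpha <- softmaxRows(scores)
  fused <- matrix(0, nrow(alpha), ncol(emb[[1L]]))
  for (v in seq_len(V)) fused <- fused + alpha[, v] * emb[[v]]
  probs <- classifyNodes(fused, model@classifier)
  list(probs = probs, fused = fused, alpha = alpha, embeddings = emb,
       Tl = Tl, caches = caches)
}

# Analytic gradients of the mean masked cross-entropy w.r.t. every model
# parameter. Returns list(loss, grads) with grads mirroring the parameter
# structure: encoders[[v]][[l]], fusion$Wa, fusion$a, classifier$C/$b.
mvgnnGradients <- function(model, Xs, Anorms, y, mask, training = TRUE) {
  dropout <- if (training) model@config$dropout else 0
  fw <- mvgnnForwardCached(model, Xs, Anorms, training, dropout)
  n <- nrow(fw$probs); K <- ncol(fw$probs); V <- length(Xs)
  yi <- as.integer(y)
  loss <- maskedCrossEntropy(fw$probs, yi, mask)

  G <- matrix(0, n, K)
  G[mask, ] <- fw$probs[mask, , drop = FALSE]
  G[cbind(mask, yi[mask])] <- G[cbind(mask, yi[mask])] - 1
  G <- G / length(mask)

  Cw <- model@classifier$C
  gC <- crossprod(fw$fused, G)
  gb <- colSums(G)
  dF <- G %*% t(Cw)                                   # n x h3

  Wa <- model@fusion$Wa; a <- model@fusion$a
  alpha <- fw$alpha
  dAlpha <- vapply(seq_len(V), function(v)
    rowSums(dF * fw$embeddings[[v]]), numeric(n))     # n x V
  dAlpha <- matrix(dAlpha, ncol = V)
  dS <- alpha * (dAlpha - rowSums(alpha * dAlpha))    # softmax backward
  gWa <- matrix(0, nrow(Wa), ncol(Wa))
  ga <- numeric(length(a))
  dEmb <- vector("list", V)
  for (v in seq_len(V)) {
    Tm <- fw$Tl[[v]]
    dT <- dS[, v] %o% a                               # n x A
    ga <- ga + colSums(Tm * dS[, v])
    dPre <- dT * (1 - Tm^2)
    gWa <- gWa + crossprod(dPre, fw$embeddings[[v]])
    dEmb[[v]] <- alpha[, v] * dF + dPre %*% Wa
  }

  gEnc <- vector("list", V)
  for (v in seq_len(V)) {
    W <- model@encoders[[v]]
    ch <- fw$caches[[v]]
    M <- Anorms[[v]]
    dE <- dEmb[[v]]
    gW3 <- crossprod(ch$P2, dE)
    dD2 <- M %*% (dE %*% t(W[[3L]]))
    dH2 <- if (is.null(ch$B2)) dD2 else dD2 * ch$B2 / (1 - dropout)
    dZ2 <- dH2 * (ch$Z2 > 0)
    gW2 <- crossprod(ch$P1, dZ2)
    dD1 <- M %*% (dZ2 %*% t(W[[2L]]))
    dH1 <- if (is.null(ch$B1)) dD1 else dD1 * ch$B1 / (1 - dropout)
    dZ1 <- dH1 * (ch$Z1 > 0)
    gW1 <- crossprod(ch$P0, dZ1)
    gEnc[[v]] <- list(gW1, gW2, gW3)
  }
  list(loss = loss, forward = fw,
       grads = list(encoders = gEnc, fusion = list(Wa = gWa, a = ga),
                    classifier = list(C = gC, b = gb)))
}
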