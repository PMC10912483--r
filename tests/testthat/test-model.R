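randomNorm <- function(n, seed) {
  set.seed(seed)
  A <- matrix(runif(n * n), n, n); A <- (A + t(A)) / 2; diag(A) <- 0
  normalizeAdjacency(A)
}

test_that("a GCN layer matches dense brute-force evaluation", {
  # identity propagation
  H <- matrix(rnorm(12), 4, 3)
  expect_equal(gcnLayer(H, diag(4), diag(3), activate = FALSE), H)
  # random instances vs explicit product + elementwise max(0, .)
  for (seed in 1:30) {
    set.seed(seed)
    H <- matrix(rnorm(5 * 3), 5, 3)
    W <- matrix(rnorm(3 * 2), 3, 2)
    M <- randomNorm(5, seed + 500)
    out <- gcnLayer(H, M, W)
    expect_equal(out, pmax(M %*% H %*% W, 0), tolerance = 1e-12)
  }
  expect_error(gcnLayer(matrix(0, 4, 3), diag(4), matrix(0, 2, 2)),
               "conform")
  expect_error(gcnLayer(matrix(0, 3, 3), diag(4), matrix(0, 3, 2)),
               "conform")
})

test_that("propagation preserves constant features on a path graph", {
  A <- matrix(0, 3, 3); A[1, 2] <- A[2, 1] <- 1; A[2, 3] <- A[3, 2] <- 1
  M <- normalizeAdjacency(A)
  H <- matrix(1, 3, 2)
  out <- gcnLayer(H, M, diag(2), activate = FALSE)
  # oracle: explicit dense computation row by row
  expect_equal(out, M %*% H %*% diag(2), tolerance = 1e-15)
  # degree scaling makes rows unequal on the path, but within-row constant
  expect_equal(out[, 1], out[, 2])
})

test_that("the three-layer encoder composes gcnLayer and is deterministic", {
  set.seed(1)
  X <- matrix(rnorm(4 * 5), 4, 5)
  M <- randomNorm(4, 21)
  W <- list(matrix(rnorm(5 * 4), 5, 4), matrix(rnorm(4 * 3), 4, 3),
            matrix(rnorm(3 * 2), 3, 2))
  E <- encodeView(X, M, W)
  # composed oracle: three applications of the layer rule
  H1 <- pmax(M %*% X %*% W[[1]], 0)
  H2 <- pmax(M %*% H1 %*% W[[2]], 0)
  expect_equal(E, M %*% H2 %*% W[[3]], tolerance = 1e-12)
  # eval mode twice: bitwise identical
  expect_identical(E, encodeView(X, M, W))
  # zero final layer annihilates the embedding
  W0 <- W; W0[[3]] <- W0[[3]] * 0
  expect_true(all(encodeView(X, M, W0) == 0))
})

test_that("dropout acts only in training mode, with inverted scaling", {
  X <- matrix(1, 10, 4)
  W <- diag(4)
  set.seed(3)
  out <- gcnLayer(X, diag(10), W, activate = FALSE, dropout = 0.5,
                  training = TRUE)
  expect_true(all(out %in% c(0, 2)))   # kept entries scaled by 1/(1-p)
  out2 <- gcnLayer(X, diag(10), W, activate = FALSE, dropout = 0.5,
                   training = FALSE)
  expect_equal(out2, X)
})

test_that("attention weights are a valid simplex and reconstruct the fusion", {
  set.seed(7)
  fusion <- list(Wa = matrix(rnorm(3 * 4), 3, 4), a = rnorm(3))
  for (rep in 1:20) {
    emb <- lapply(1:3, function(v) matrix(rnorm(6 * 4), 6, 4))
    fz <- attentionFuse(emb, fusion)
    expect_equal(rowSums(fz$alpha), rep(1, 6), tolerance = 1e-9)
    expect_true(all(fz$alpha >= 0))
    # reconstruction oracle from the exported alphas
    recon <- matrix(0, 6, 4)
    for (v in 1:3) for (i in 1:6)
      recon[i, ] <- recon[i, ] + fz$alpha[i, v] * emb[[v]][i, ]
    expect_equal(fz$fused, recon, tolerance = 1e-12)
  }
  # identical embeddings: uniform weights
  same <- lapply(1:4, function(v) emb[[1]])
  expect_equal(attentionFuse(same, fusion)$alpha,
               matrix(0.25, 6, 4), tolerance = 1e-12)
  # single view: alpha == 1, fused == embedding
  one <- attentionFuse(emb[1], fusion)
  expect_equal(one$alpha, matrix(1, 6, 1))
  expect_equal(one$fused, emb[[1]])
  expect_error(attentionFuse(list(emb[[1]], emb[[1]][1:3, ]), fusion))
})

test_that("softmax classification is a proper, shift-invariant probability", {
  cls <- list(C = matrix(0, 3, 3), b = numeric(3))
  P <- classifyNodes(matrix(rnorm(15), 5, 3), cls)
  expect_equal(P, matrix(1 / 3, 5, 3), ignore_attr = TRUE)  # zero logits
  set.seed(11)
  cls$C <- matrix(rnorm(9), 3, 3); cls$b <- rnorm(3)
  Fm <- matrix(rnorm(15), 5, 3)
  P1 <- classifyNodes(Fm, cls)
  expect_equal(rowSums(P1), rep(1, 5), tolerance = 1e-12)
  # adding a constant to all logits of a row leaves probabilities unchanged
  logits <- Fm %*% cls$C + matrix(cls$b, 5, 3, byrow = TRUE)
  for (rep in 1:20) {
    set.seed(rep)
    shift <- rnorm(1)
    cls2 <- cls; cls2$b <- cls$b + shift
    expect_equal(classifyNodes(Fm, cls2), P1, tolerance = 1e-12)
    # argmax of probabilities equals argmax of logits
    expect_identical(max.col(P1, ties.method = "first"),
                     max.col(logits, ties.method = "first"))
  }
})

test_that("masked cross-entropy matches direct summation", {
  P <- rbind(c(1, 0, 0, 0), c(0.25, 0.25, 0.25, 0.25))
  y <- c(1L, 2L)
  expect_equal(maskedCrossEntropy(pmax(P, 1e-300), y, 1L), 0)
  expect_equal(maskedCrossEntropy(P, y, 2L), log(4))
  for (seed in 1:30) {
    set.seed(seed)
    P <- softmaxRowsOracle(matrix(rnorm(8 * 3), 8, 3))
    y <- sample(3, 8, TRUE)
    mask <- sort(sample(8, 4))
    direct <- 0
    for (l in mask) direct <- direct - log(P[l, y[l]])
    expect_equal(maskedCrossEntropy(P, y, mask, reduce = "sum"), direct,
                 tolerance = 1e-9)
    expect_equal(maskedCrossEntropy(P, y, mask), direct / 4,
                 tolerance = 1e-9)
  }
  expect_error(maskedCrossEntropy(P, y, integer(0)), "mask")
})

test_that("backprop gradients agree with finite differences", {
  set.seed(5)
  n <- 5
  Xs <- list(matrix(rnorm(n * 3), n, 3), matrix(rnorm(n * 2), n, 2))
  Ms <- list(randomNorm(n, 1), randomNorm(n, 2))
  y <- factor(c("A", "B", "A", "B", "A"))
  model <- initMVGNN(c(v1 = 3L, v2 = 2L), c("A", "B"),
                     hiddenDims = c(4L, 4L, 3L), attentionDim = 3L,
                     dropout = 0)
  mask <- c(1L, 2L, 4L)
  gr <- mvGCN:::mvgnnGradients(model, Xs, Ms, y, mask, training = FALSE)
  p <- mvGCN:::getParams(model)
  flat <- mvGCN:::flattenGrads(gr$grads)
  lossAt <- function(pp) {
    m2 <- mvGCN:::setParams(model, pp)
    maskedCrossEntropy(mvgnnForward(m2, Xs, Ms)$probs, y, mask)
  }
  h <- 1e-6
  for (k in names(p)) {
    idx <- seq_len(min(4, length(p[[k]])))
    for (i in idx) {
      pp <- p; pp[[k]][i] <- pp[[k]][i] + h
      up <- lossAt(pp)
      pp[[k]][i] <- pp[[k]][i] - 2 * h
      dn <- lossAt(pp)
      numeric_grad <- (up - dn) / (2 * h)
      denom <- max(abs(numeric_grad), abs(flat[[k]][i]), 1e-4)
      expect_lt(abs(numeric_grad - flat[[k]][i]) / denom, 1e-4)
    }
  }
})

test_that("forward pass is permutation-equivariant", {
  set.seed(9)
  n <- 7
  Xs <- list(matrix(rnorm(n * 4), n, 4), matrix(rnorm(n * 3), n, 3))
  Ms <- list(randomNorm(n, 31), randomNorm(n, 32))
  model <- initMVGNN(c(a = 4L, b = 3L), c("A", "B", "C"),
                     hiddenDims = c(5L, 4L, 3L), attentionDim = 3L)
  fw <- mvgnnForward(model, Xs, Ms)
  perm <- sample(n)
  fwP <- mvgnnForward(model, lapply(Xs, function(X) X[perm, ]),
                      lapply(Ms, function(M) M[perm, perm]))
  expect_equal(fwP$probs, fw$probs[perm, ], tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(fwP$alpha, fw$alpha[perm, ], tolerance = 1e-12)
  expect_equal(fwP$fused, fw$fused[perm, ], tolerance = 1e-12)
})

test_that("deep stacking over-smooths node embeddings relative to 3 layers", {
  # connected toy graph; propagation-only layers isolate the smoothing
  # effect of depth (W = I, no activation)
  set.seed(4)
  A <- matrix(0, 8, 8)
  for (i in 1:7) A[i, i + 1] <- A[i + 1, i] <- 1
  A[1, 8] <- A[8, 1] <- 1
  M <- normalizeAdjacency(A)
  H <- matrix(rnorm(8 * 4), 8, 4)
  prop <- function(H, times) {
    for (i in seq_len(times)) H <- gcnLayer(H, M, diag(4), activate = FALSE)
    H
  }
  nodeVariance <- function(H) mean(apply(H, 2, var))
  expect_lt(nodeVariance(prop(H, 6)), nodeVariance(prop(H, 3)))
})

test_that("model validity enforces layer chaining and class dimension", {
  model <- initMVGNN(c(v = 3L), c("A", "B"), hiddenDims = c(4L, 4L, 2L),
                     attentionDim = 2L)
  bad <- model
  bad@encoders[[1]][[2]] <- matrix(0, 7, 4)
  expect_error(validObject(bad), "chain")
  bad2 <- model
  bad2@classifier$C <- matrix(0, 2, 3)
  expect_error(validObject(bad2), "classes")
})
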