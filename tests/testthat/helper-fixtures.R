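# Shared fixture builders and independent oracles for the test suite.
# Oracles are deliberately written as naive double loops / direct formula
# evaluations, independent of the package's vectorized implementations.

makeView <- function(n = 5, d = 4, seed = 1, name = "mRNA",
                     nonneg = FALSE) {
  set.seed(seed)
  m <- matrix(rnorm(n * d), n, d,
              dimnames = list(sprintf("s%02d", seq_len(n)),
                              sprintf("%s_f%02d", name, seq_len(d))))
  if (nonneg) m <- m - min(m)
  OmicsView(m, name)
}

randomSymS <- function(n, seed) {
  set.seed(seed)
  X <- matrix(rnorm(n * 3), n, 3)
  cosineOracle(X)
}

# per-pair cosine similarity by direct dot products
cosineOracle <- function(X) {
  n <- nrow(X)
  S <- diag(n)
  for (i in seq_len(n)) for (j in seq_len(n)) if (i != j) {
    S[i, j] <- sum(X[i, ] * X[j, ]) /
      (sqrt(sum(X[i, ]^2)) * sqrt(sum(X[j, ]^2)))
  }
  S
}

# dense renormalized adjacency by the explicit definition
normAdjOracle <- function(A) {
  Ahat <- A + diag(nrow(A))
  D <- diag(1 / sqrt(rowSums(Ahat)))
  D %*% Ahat %*% D
}

# naive chi-square score of a single feature from class-wise sums
chi2Oracle <- function(x, y) {
  y <- as.factor(y)
  total <- sum(x)
  if (total == 0) return(0)
  sc <- 0
  for (cl in levels(y)) {
    O <- sum(x[y == cl])
    E <- mean(y == cl) * total
    sc <- sc + (O - E)^2 / E
  }
  sc
}

# discrete mutual information via entropies, using table()
miOracle <- function(xi, yi) {
  H <- function(t) { p <- t / sum(t); -sum(p[p > 0] * log(p[p > 0])) }
  H(table(xi)) + H(table(yi)) - H(table(xi, yi))
}

# row-wise softmax written independently of the package
softmaxRowsOracle <- function(L) {
  t(apply(L, 1, function(r) exp(r - max(r)) / sum(exp(r - max(r)))))
}

# pairwise-enumeration AUC
aucOracle <- function(scores, y) {
  pos <- scores[y == 1]; neg <- scores[y == 0]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# test-scale configuration: small hidden widths and a faster learning
# rate so full-batch Adam converges within a couple hundred epochs on
# cohorts of 50-300 samples
smallConfig <- function(seed = 1L) {
  cfg <- defaultConfig()
  cfg$model$hiddenDims <- c(16L, 16L, 8L)
  cfg$model$attentionDim <- 4L
  cfg$training$lr <- 1e-2
  cfg$training$maxEpochs <- 150L
  cfg$training$patience <- 40L
  cfg$training$seed <- as.integer(seed)
  cfg$graph$kAvgDegree <- 5
  cfg
}
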