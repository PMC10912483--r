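test_that("chi-square scores match the direct observed/expected formula", {
  # hand-checkable case: values (1,1,0,0) over classes (A,A,B,B)
  m <- matrix(c(1, 1, 0, 0), 4, 1,
              dimnames = list(paste0("s", 1:4), "f1"))
  y <- factor(c("A", "A", "B", "B"))
  names(y) <- rownames(m)
  r <- chi2Scores(OmicsView(m, "v"), y)
  # O_A = 2, O_B = 0, E_A = E_B = 1 -> (2-1)^2/1 + (0-1)^2/1 = 2
  expect_equal(r$scores, 2)

  # random instances against the per-feature oracle
  for (seed in 1:20) {
    v <- makeView(12, 6, seed = seed, nonneg = TRUE)
    set.seed(seed + 100)
    y <- factor(sample(c("A", "B", "C"), 12, replace = TRUE,
                       prob = c(.4, .4, .2)))
    while (nlevels(droplevels(y)) < 2) y <- factor(sample(c("A", "B"), 12, TRUE))
    names(y) <- sampleIDs(v)
    r <- chi2Scores(v, y)
    expected <- vapply(seq_len(6), function(j)
      chi2Oracle(omicsValues(v)[, j], y), numeric(1))
    expect_equal(r$scores, expected, tolerance = 1e-12)
  }
})

test_that("constant features score zero and negatives are rejected", {
  m <- cbind(f1 = rep(2.5, 6), f2 = c(1, 2, 3, 4, 5, 6))
  rownames(m) <- paste0("s", 1:6)
  y <- stats::setNames(factor(rep(c("A", "B"), 3)), rownames(m))
  r <- chi2Scores(OmicsView(m, "v"), y)
  expect_equal(r$scores[1], 0)
  m2 <- m; m2[1, 2] <- -1
  expect_error(chi2Scores(OmicsView(m2, "v"), y), "normalize")
})

test_that("chi-square scoring is invariant to sample order", {
  v <- makeView(15, 5, seed = 2, nonneg = TRUE)
  set.seed(5)
  y <- stats::setNames(factor(sample(c("A", "B"), 15, TRUE)), sampleIDs(v))
  r1 <- chi2Scores(v, y)
  perm <- sample(15)
  vp <- OmicsView(omicsValues(v)[perm, ], viewName(v))
  r2 <- chi2Scores(vp, y)
  expect_equal(r1$scores, r2$scores, tolerance = 1e-12)
})

test_that("selectTopK keeps the k best with ascending-index tie-break", {
  r <- mvGCN:::newFeatureRanking(c("a", "b", "c"), c(3, 1, 2))
  expect_identical(selectTopK(r, 2)$selected, c(1L, 3L))
  rt <- mvGCN:::newFeatureRanking(c("a", "b", "c"), c(1, 1, 1))
  expect_identical(selectTopK(rt, 2)$selected, c(1L, 2L))
  expect_identical(selectTopK(r, 10)$selected, c(1L, 3L, 2L))  # clamp
  expect_error(selectTopK(r, 0), "k")
})

test_that("min-max normalization maps each feature to [0,1]", {
  m <- cbind(a = c(2, 4, 6), b = c(5, 5, 5), c = c(0, 0.25, 1))
  rownames(m) <- paste0("s", 1:3)
  out <- omicsValues(minmaxNormalize(OmicsView(m, "v")))
  expect_equal(unname(out[, "a"]), c(0, 0.5, 1))
  expect_equal(unname(out[, "b"]), c(0, 0, 0))   # constant -> 0
  expect_equal(unname(out[, "c"]), c(0, 0.25, 1))  # already [0,1]: unchanged
  mNA <- m; mNA[2, 1] <- NA
  expect_error(minmaxNormalize(new("OmicsView", name = "v",
                                   values = mNA)))
})

test_that("first mRMR pick maximizes relevance; greedy matches brute force", {
  for (seed in 1:5) {
    set.seed(seed)
    n <- 20; d <- 5; bins <- 3
    m <- matrix(runif(n * d), n, d,
                dimnames = list(sprintf("s%02d", 1:n), paste0("f", 1:d)))
    y <- stats::setNames(factor(rep(c("A", "B"), length.out = n)[sample(n)]),
                         rownames(m))
    v <- OmicsView(m, "v")
    sel <- mrmrSelect(v, y, m = 3, bins = bins)$selected

    # independent brute force: discretize with the same binning contract,
    # evaluate the MID score of every candidate at every step via table()
    disc <- apply(m, 2, function(x) {
      br <- unique(quantile(x, probs = seq(0, 1, length.out = bins + 1),
                            names = FALSE))
      if (length(br) < 2) rep(1L, length(x))
      else .bincode(x, br, right = TRUE, include.lowest = TRUE)
    })
    yi <- as.integer(y)
    rel <- vapply(1:d, function(j) miOracle(disc[, j], yi), numeric(1))
    chosen <- integer(0)
    for (s in 1:3) {
      cand <- setdiff(1:d, chosen)
      score <- vapply(cand, function(j) {
        red <- if (length(chosen) == 0) 0
               else mean(vapply(chosen, function(g)
                 miOracle(disc[, j], disc[, g]), numeric(1)))
        rel[j] - red
      }, numeric(1))
      chosen <- c(chosen, cand[which.max(score)])
    }
    expect_identical(sel, chosen)
    expect_identical(sel[1], which.max(rel))  # empty redundancy term
  }
})

test_that("mRMR clamps m to the feature count with a warning", {
  v <- makeView(10, 4, seed = 9, nonneg = TRUE)
  y <- stats::setNames(factor(rep(c("A", "B"), 5)), sampleIDs(v))
  expect_warning(r <- mrmrSelect(v, y, m = 10), "clamp")
  expect_length(r$selected, 4L)
})

test_that("mRMR is invariant to sample order and column permutation", {
  v <- makeView(24, 6, seed = 4, nonneg = TRUE)
  set.seed(77)
  y <- stats::setNames(factor(sample(c("A", "B"), 24, TRUE)), sampleIDs(v))
  base <- mrmrSelect(v, y, m = 4)$selected
  perm <- sample(24)
  vp <- OmicsView(omicsValues(v)[perm, ], viewName(v))
  expect_identical(mrmrSelect(vp, y, m = 4)$selected, base)
  # column permutation: selection identifies the same features
  cperm <- c(3L, 1L, 6L, 2L, 5L, 4L)
  vc <- OmicsView(omicsValues(v)[, cperm], viewName(v))
  selc <- mrmrSelect(vc, y, m = 4)$selected
  expect_identical(cperm[selc], base)
})

test_that("the cascade returns min(m, k, d) features in pipeline order", {
  v <- makeView(30, 25, seed = 8)
  set.seed(12)
  y <- stats::setNames(factor(sample(c("A", "B"), 30, TRUE)), sampleIDs(v))
  out <- selectFeatures(v, y, kChi2 = 15, mMrmr = 6, bins = 4)
  expect_equal(ncol(omicsValues(out$view)), 6L)
  expect_length(out$chi2$selected, 15L)
  # selected features carry normalized values in [0, 1]
  expect_gte(min(omicsValues(out$view)), 0)
  expect_lte(max(omicsValues(out$view)), 1)
  # mMrmr beyond d: everything is kept
  out2 <- suppressWarnings(selectFeatures(v, y, kChi2 = 40, mMrmr = 40))
  expect_equal(ncol(omicsValues(out2$view)), 25L)
})

test_that("informative features outrank noise through the full cascade", {
  sim <- simulateCohort(200, c(0.5, 0.5), views = list(
    list(name = "v", nFeatures = 120, nInformative = 10, effectSize = 2)),
    seed = 31)
  v <- sim$views[[1]]
  truthIdx <- sim$truth$v$informative
  r <- chi2Scores(v, sim$labels)
  # informative chi2 scores stochastically dominate the noise scores
  pv <- wilcox.test(r$scores[truthIdx], r$scores[-truthIdx],
                    alternative = "greater")$p.value
  expect_lt(pv, 1e-6)
  out <- selectFeatures(v, sim$labels, kChi2 = 120, mMrmr = 20)
  picked <- featureIDs(v)[out$chi2$selected][out$mrmr$selected]
  hits <- sum(featureIDs(v)[truthIdx] %in% picked)
  expect_gte(hits, 8)
})
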