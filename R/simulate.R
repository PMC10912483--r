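#' Simulate an aligned multi-omics cohort
#'
#' Generates V omics views over the same samples with class-dependent
#' Gaussian signal. Labels are drawn from \code{classProportions}. In each
#' view, \code{nInformative} randomly chosen features carry class-dependent
#' mean shifts; all remaining features are pure noise
#' \eqn{N(0, noiseSd^2)}. For a fully discriminative view the C class
#' means of an informative feature are equally spaced
#' \eqn{(c - (C+1)/2) \cdot effectSize \cdot noiseSd} under a random
#' per-feature permutation of the class order, so adjacent classes are
#' separated by \code{effectSize} feature standard deviations. When a view
#' specifies \code{pairs = c(a, b)}, only that class pair is shifted
#' (\eqn{\pm effectSize/2}), which makes views complementary: different
#' views then separate different class pairs. Each view is finally shifted
#' by its global minimum so all values are non-negative (the chi-square
#' stage requires this), which preserves the covariance structure.
#'
#' @param nSamples Cohort size.
#' @param classProportions Vector of class proportions (normalized
#'   internally).
#' @param views List of per-view specifications, each a list with
#'   \code{name}, \code{nFeatures}, \code{nInformative},
#'   \code{effectSize}, optional \code{noiseSd} (default 1) and optional
#'   \code{pairs} (integer class pair).
#' @param seed Integer seed; the cohort is a deterministic function of the
#'   full specification and this seed.
#' @param classNames Optional class label strings.
#' @param heavyTail Use t(3) noise instead of Gaussian.
#' @return List with \code{views} (list of
#'   \code{\linkS4class{OmicsView}}), \code{labels} (named factor) and
#'   \code{truth} (per view: informative feature indices and the class
#'   mean matrix).
#' @examples
#' sim <- simulateCohort(60, c(0.5, 0.5),
#'   views = list(list(name = "mRNA", nFeatures = 30, nInformative = 5,
#'                     effectSize = 2)), seed = 7)
#' sim$views[[1]]
#' @export
simulateCohort <- function(nSamples, classProportions, views, seed = 1L,
                           classNames = NULL, heavyTail = FALSE) {
  props <- classProportions / sum(classProportions)
  if (any(props < 0) || abs(sum(props) - 1) > 1e-9)
    stop("classProportions must be a valid simplex vector")
  C <- length(props)
  if (C < 2L) stop("need at least 2 classes")
  if (is.null(classNames)) classNames <- paste0("C", seq_len(C))
  withSeed(seed, {
    yi <- sample.int(C, nSamples, replace = TRUE, prob = props)
    ids <- sprintf("s%04d", seq_len(nSamples))
    labels <- factor(classNames[yi], levels = classNames)
    names(labels) <- ids
    truth <- list()
    out <- lapply(views, function(vs) {
      d <- vs$nFeatures; ninf <- vs$nInformative
      if (ninf > d) stop("nInformative exceeds nFeatures")
      sdv <- if (is.null(vs$noiseSd)) 1 else vs$noiseSd
      e <- vs$effectSize
      if (e < 0) stop("effectSize must be >= 0")
      noise <- if (heavyTail) stats::rt(nSamples * d, df = 3) * sdv
               else stats::rnorm(nSamples * d, 0, sdv)
      vals <- matrix(noise, nSamples, d)
      inf <- sort(sample.int(d, ninf))
      mu <- matrix(0, C, ninf)
      if (ninf > 0) {
        if (is.null(vs$pairs)) {
          centers <- (seq_len(C) - (C + 1) / 2) * e * sdv
          for (f in seq_len(ninf)) mu[, f] <- centers[sample.int(C)]
        } else {
          pr <- as.integer(vs$pairs)
          if (length(pr) != 2L || any(pr < 1L | pr > C))
            stop("pairs must name two classes")
          mu[pr[1L], ] <- e * sdv / 2
          mu[pr[2L], ] <- -e * sdv / 2
        }
        vals[, inf] <- vals[, inf] + mu[yi, , drop = FALSE]
      }
      vals <- vals - min(vals)
      dimnames(vals) <- list(ids, sprintf("%s_f%04d", vs$name, seq_len(d)))
      truth[[vs$name]] <<- list(informative = inf, classMeans = mu)
      OmicsView(vals, vs$name)
    })
    list(views = out, labels = labels, truth = truth)
  })
}

#' Simulate a three-class cohort with complementary views
#'
#' Each of the three views discriminates exactly one class pair
#' (view 1: classes 1 vs 2; view 2: classes 2 vs 3; view 3: classes
#' 1 vs 3), so no single view supports perfect three-class separation
#' but their union does. This is the canonical design for testing that
#' multi-view fusion beats the best single view.
#'
#' @param nSamples Cohort size.
#' @param nFeatures,nInformative,effectSize,noiseSd Per-view settings
#'   (shared by all three views).
#' @param seed Integer seed.
#' @param classProportions Proportions for the 3 classes.
#' @return As \code{\link{simulateCohort}}.
#' @export
simulateComplementaryCohort <- function(nSamples, nFeatures = 100L,
                                        nInformative = 5L, effectSize = 1.5,
                                        noiseSd = 1, seed = 1L,
                                        classProportions = rep(1 / 3, 3)) {
  if (length(classProportions) != 3L) stop("the design has 3 classes")
  pairs <- list(c(1L, 2L), c(2L, 3L), c(1L, 3L))
  views <- lapply(1:3, function(v)
    list(name = paste0("view", v), nFeatures = nFeatures,
         nInformative = nInformative, effectSize = effectSize,
         noiseSd = noiseSd, pairs = pairs[[v]]))
  simulateCohort(nSamples, classProportions, views, seed = seed)
}
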