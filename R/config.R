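#' Default run configuration
#'
#' Returns the nested list of settings controlling the whole pipeline.
#' Defaults follow the study design: the chi-square stage keeps the top
#' 5000 features per view and the mRMR stage the top 500; the patient
#' graph targets an average degree of 5; the encoder has three graph
#' convolutional layers with two dropout layers (rate 0.5); training uses
#' Adam with early stopping monitored on a held-out validation split
#' (patience 100 epochs); evaluation uses stratified 5-fold
#' cross-validation.
#'
#' @return A named list with components \code{selection}, \code{graph},
#'   \code{model}, \code{training} and \code{cv}.
#' @examples
#' cfg <- defaultConfig()
#' cfg$selection$kChi2
#' @export
defaultConfig <- function() {
  list(
    selection = list(kChi2 = 5000L, mMrmr = 500L, bins = 5L),
    graph = list(kAvgDegree = 5),
    model = list(hiddenDims = c(400L, 400L, 200L), dropout = 0.5,
                 attentionDim = 64L),
    training = list(lr = 1e-3, weightDecay = 5e-4, maxEpochs = 500L,
                    patience = 100L, minDelta = 1e-4, seed = 1L),
    cv = list(nFolds = 5L, stratified = TRUE, valFraction = 0.2)
  )
}

#' Read a run configuration from YAML
#'
#' Values present in the file override the defaults; everything else is
#' taken from \code{\link{defaultConfig}}. The merged configuration is
#' validated before it is returned.
#'
#' @param path Path to a YAML file, or \code{NULL} for pure defaults.
#' @return A validated configuration list.
#' @export
readConfig <- function(path = NULL) {
  cfg <- defaultConfig()
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    for (sec in intersect(names(user), names(cfg)))
      cfg[[sec]][names(user[[sec]])] <- user[[sec]]
  }
  validateConfig(cfg)
}

#' @rdname readConfig
#' @param cfg A configuration list to validate.
#' @export
validateConfig <- function(cfg) {
  s <- cfg$selection
  if (!(s$kChi2 >= s$mMrmr && s$mMrmr >= 1))
    stop("selection: need kChi2 >= mMrmr >= 1")
  if (s$bins < 2) stop("selection: bins must be >= 2")
  m <- cfg$model
  if (!(m$dropout >= 0 && m$dropout < 1))
    stop("model: dropout must be in [0, 1)")
  if (length(m$hiddenDims) != 3L)
    stop("model: hiddenDims must have length 3 (three GCN layers)")
  if (cfg$training$patience < 1) stop("training: patience must be >= 1")
  if (cfg$cv$nFolds < 2) stop("cv: nFolds must be >= 2")
  cfg
}

# Evaluate expr with the RNG seeded to `seed`, restoring the caller's
# RNG state afterwards so library calls do not perturb user randomness.
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  set.seed(as.integer(seed))
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else rm(".Random.seed", envir = globalenv())
  })
  expr
}
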