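#' OmicsView: one omics measurement layer on a cohort
#'
#' An \code{OmicsView} holds a single omics data matrix (for example mRNA
#' expression, DNA methylation beta values, or copy-number estimates) with
#' rows as samples and columns as features. Sample and feature identifiers
#' are carried as the matrix dimnames and must be unique; missing values are
#' not allowed (the loader either rejects them or imputes, see
#' \code{\link{readOmicsView}}).
#'
#' @slot name Single string identifying the view (e.g. \code{"mRNA"}).
#' @slot values Numeric matrix, samples x features, with unique row and
#'   column names and no missing entries.
#'
#' @seealso \code{\link{readOmicsView}}, \code{\link{alignViews}},
#'   \code{\link{selectFeatures}}
#' @export
setClass("OmicsView",
  representation(name = "character", values = "matrix"))

setValidity("OmicsView", function(object) {
  msg <- character()
  v <- object@values
  if (length(object@name) != 1L || is.na(object@name) || !nzchar(object@name))
    msg <- c(msg, "'name' must be a single non-empty string")
  if (!is.numeric(v))
    msg <- c(msg, "'values' must be a numeric matrix")
  if (is.null(rownames(v)) || is.null(colnames(v)))
    msg <- c(msg, "'values' must have sample (row) and feature (column) names")
  if (!is.null(rownames(v)) && anyDuplicated(rownames(v)))
    msg <- c(msg, sprintf("duplicate sample ID: '%s'",
                          rownames(v)[duplicated(rownames(v))][1L]))
  if (!is.null(colnames(v)) && anyDuplicated(colnames(v)))
    msg <- c(msg, sprintf("duplicate feature ID: '%s'",
                          colnames(v)[duplicated(colnames(v))][1L]))
  if (is.numeric(v) && anyNA(v))
    msg <- c(msg, "'values' contains missing entries")
  if (length(msg)) msg else TRUE
})

#' Construct an OmicsView
#'
#' @param values Numeric matrix, samples x features, with dimnames.
#' @param name View identifier.
#' @return An \code{\linkS4class{OmicsView}}.
#' @examples
#' m <- matrix(rnorm(6), 3, 2,
#'             dimnames = list(paste0("s", 1:3), paste0("g", 1:2)))
#' OmicsView(m, "mRNA")
#' @export
OmicsView <- function(values, name = "view") {
  new("OmicsView", name = as.character(name), values = as.matrix(values))
}

#' PatientGraph: weighted patient similarity network for one omics view
#'
#' Nodes are patients; edge weights are cosine similarities between their
#' omics profiles that passed the threshold \code{epsilon}. The slot
#' \code{normalized} stores the renormalized propagation operator
#' \eqn{D^{-1/2} (A + I) D^{-1/2}} used by the graph convolutional layers.
#'
#' @slot sampleIDs Character vector of node (patient) identifiers.
#' @slot similarity Full cosine similarity matrix S (unit diagonal).
#' @slot adjacency Thresholded weighted adjacency A (zero diagonal).
#' @slot epsilon Similarity threshold actually applied.
#' @slot kTarget Requested average node degree.
#' @slot normalized Renormalized adjacency used for propagation.
#'
#' @seealso \code{\link{buildPatientGraph}}, \code{\link{realizedDegree}}
#' @export
setClass("PatientGraph",
  representation(sampleIDs = "character", similarity = "matrix",
                 adjacency = "matrix", epsilon = "numeric",
                 kTarget = "numeric", normalized = "matrix"))

setValidity("PatientGraph", function(object) {
  msg <- character()
  n <- length(object@sampleIDs)
  S <- object@similarity; A <- object@adjacency; N <- object@normalized
  for (nm in c("similarity", "adjacency", "normalized")) {
    M <- slot(object, nm)
    if (!all(dim(M) == c(n, n)))
      msg <- c(msg, sprintf("'%s' must be %d x %d", nm, n, n))
    else if (!all(is.finite(M)))
      msg <- c(msg, sprintf("'%s' has non-finite entries", nm))
    else if (max(abs(M - t(M))) > 1e-8)
      msg <- c(msg, sprintf("'%s' must be symmetric", nm))
  }
  if (all(dim(A) == c(n, n)) && any(diag(A) != 0))
    msg <- c(msg, "'adjacency' must have a zero diagonal")
  if (all(dim(A) == c(n, n)) && any(A < 0))
    msg <- c(msg, "'adjacency' must be non-negative")
  if (length(msg)) msg else TRUE
})

#' MVGNNModel: parameters of the multi-view GCN classifier
#'
#' Holds one three-layer GCN encoder per omics view, the shared attention
#' scorer used to fuse per-view node embeddings, and the softmax classifier
#' head. Create with \code{\link{initMVGNN}}; fit with
#' \code{\link{trainFold}} or \code{\link{crossValidate}}.
#'
#' @slot encoders List (one per view) of lists of 3 weight matrices.
#' @slot fusion List with projection matrix \code{Wa} (attention_dim x h3)
#'   and score vector \code{a} (attention_dim).
#' @slot classifier List with weight matrix \code{C} (h3 x n_classes) and
#'   bias vector \code{b}.
#' @slot viewNames Character vector naming the views, in encoder order.
#' @slot classNames Character vector of class labels.
#' @slot config The model sub-configuration used at initialisation.
#' @export
setClass("MVGNNModel",
  representation(encoders = "list", fusion = "list", classifier = "list",
                 viewNames = "character", classNames = "character",
                 config = "list"))

setValidity("MVGNNModel", function(object) {
  msg <- character()
  if (length(object@encoders) != length(object@viewNames))
    msg <- c(msg, "one encoder per view is required")
  for (v in seq_along(object@encoders)) {
    W <- object@encoders[[v]]
    if (length(W) != 3L)
      msg <- c(msg, "each view encoder must have exactly 3 layers")
    else {
      if (ncol(W[[1L]]) != nrow(W[[2L]]) || ncol(W[[2L]]) != nrow(W[[3L]]))
        msg <- c(msg, sprintf("encoder %d: layer shapes do not chain", v))
      if (!all(vapply(W, function(w) all(is.finite(w)), logical(1))))
        msg <- c(msg, sprintf("encoder %d: non-finite weights", v))
    }
  }
  if (!all(is.finite(object@fusion$Wa)) || !all(is.finite(object@fusion$a)))
    msg <- c(msg, "non-finite attention parameters")
  if (!all(is.finite(object@classifier$C)) ||
      !all(is.finite(object@classifier$b)))
    msg <- c(msg, "non-finite classifier parameters")
  if (ncol(object@classifier$C) != length(object@classNames))
    msg <- c(msg, "classifier output dimension must equal number of classes")
  if (length(msg)) msg else TRUE
})
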