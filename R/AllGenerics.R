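#' @rdname OmicsView-accessors
#' @export
setGeneric("viewName", function(x) standardGeneric("viewName"))

#' @rdname OmicsView-accessors
#' @export
setGeneric("sampleIDs", function(x) standardGeneric("sampleIDs"))

#' @rdname OmicsView-accessors
#' @export
setGeneric("featureIDs", function(x) standardGeneric("featureIDs"))

#' @rdname OmicsView-accessors
#' @export
setGeneric("omicsValues", function(x) standardGeneric("omicsValues"))

#' @rdname PatientGraph-accessors
#' @export
setGeneric("adjacency", function(x) standardGeneric("adjacency"))

#' @rdname PatientGraph-accessors
#' @export
setGeneric("similarity", function(x) standardGeneric("similarity"))

#' @rdname PatientGraph-accessors
#' @export
setGeneric("normalizedAdjacency", function(x)
  standardGeneric("normalizedAdjacency"))

#' @rdname PatientGraph-accessors
#' @export
setGeneric("realizedDegree", function(x) standardGeneric("realizedDegree"))

#' Accessors for OmicsView objects
#'
#' @param x An \code{\linkS4class{OmicsView}}.
#' @return \code{viewName}: the view identifier; \code{sampleIDs},
#'   \code{featureIDs}: character vectors; \code{omicsValues}: the
#'   samples x features numeric matrix.
#' @name OmicsView-accessors
NULL

#' @rdname OmicsView-accessors
#' @export
setMethod("viewName", "OmicsView", function(x) x@name)

#' @rdname OmicsView-accessors
#' @export
setMethod("sampleIDs", "OmicsView", function(x) rownames(x@values))

#' @rdname OmicsView-accessors
#' @export
setMethod("featureIDs", "OmicsView", function(x) colnames(x@values))

#' @rdname OmicsView-accessors
#' @export
setMethod("omicsValues", "OmicsView", function(x) x@values)

#' Accessors for PatientGraph objects
#'
#' @param x A \code{\linkS4class{PatientGraph}}.
#' @return \code{adjacency}, \code{similarity}, \code{normalizedAdjacency}:
#'   n x n numeric matrices; \code{sampleIDs}: node identifiers;
#'   \code{realizedDegree}: the achieved average number of edges per node,
#'   counting ordered pairs.
#' @name PatientGraph-accessors
NULL

#' @rdname PatientGraph-accessors
#' @export
setMethod("adjacency", "PatientGraph", function(x) x@adjacency)

#' @rdname PatientGraph-accessors
#' @export
setMethod("similarity", "PatientGraph", function(x) x@similarity)

#' @rdname PatientGraph-accessors
#' @export
setMethod("normalizedAdjacency", "PatientGraph", function(x) x@normalized)

#' @rdname PatientGraph-accessors
#' @export
setMethod("sampleIDs", "PatientGraph", function(x) x@sampleIDs)

#' @rdname PatientGraph-accessors
#' @export
setMethod("realizedDegree", "PatientGraph",
          function(x) sum(x@adjacency > 0) / nrow(x@adjacency))

setMethod("show", "OmicsView", function(object) {
  cat(sprintf("OmicsView '%s': %d samples x %d features\n", object@name,
              nrow(object@values), ncol(object@values)))
  cat(sprintf("  range [%.4g, %.4g]\n", min(object@values),
              max(object@values)))
})

setMethod("show", "PatientGraph", function(object) {
  n <- length(object@sampleIDs)
  cat(sprintf("PatientGraph: %d patients, epsilon = %.4f\n", n,
              object@epsilon))
  cat(sprintf("  target average degree %.2f, realized %.2f\n",
              object@kTarget, realizedDegree(object)))
})

setMethod("show", "MVGNNModel", function(object) {
  dims <- vapply(object@encoders, function(e) nrow(e[[1L]]), integer(1))
  cat(sprintf("MVGNNModel: %d view(s) [%s], %d classes\n",
              length(object@encoders),
              paste(object@viewNames, collapse = ", "),
              length(object@classNames)))
  cat(sprintf("  input dims: %s; hidden: %s; attention dim: %d\n",
              paste(dims, collapse = "/"),
              paste(vapply(object@encoders[[1L]], ncol, integer(1)),
                    collapse = "-"),
              nrow(object@fusion$Wa)))
})
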