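#' Read an omics matrix from delimited text
#'
#' Expects a header row of feature identifiers and a first column of sample
#' identifiers (the common export format for TCGA-style matrices). The
#' delimiter is sniffed from the first line unless given. By default any
#' missing value is an error; per-feature median imputation can be enabled
#' instead.
#'
#' @param path Path to a CSV/TSV file.
#' @param name View identifier to attach (defaults to the file base name).
#' @param sep Field delimiter; \code{NULL} to sniff between tab and comma.
#' @param transpose Set \code{TRUE} if the file is features x samples.
#' @param impute \code{"none"} (reject missing values) or \code{"median"}
#'   (per-feature median imputation).
#' @return An \code{\linkS4class{OmicsView}}.
#' @export
readOmicsView <- function(path, name = NULL, sep = NULL, transpose = FALSE,
                          impute = c("none", "median")) {
  impute <- match.arg(impute)
  if (!file.exists(path)) stop("file not found: ", path)
  first <- readLines(path, n = 1L)
  if (length(first) == 0L) stop("empty file: ", path)
  if (is.null(sep))
    sep <- if (grepl("\t", first, fixed = TRUE)) "\t" else ","
  df <- data.table::fread(path, sep = sep, header = TRUE,
                          data.table = FALSE, check.names = FALSE)
  if (nrow(df) == 0L) stop("no data rows in ", path)
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids))
    stop(sprintf("duplicate sample ID '%s' in %s",
                 ids[duplicated(ids)][1L], path))
  for (j in seq_along(df)[-1L])  # all-NA columns are read as logical
    if (is.logical(df[[j]])) df[[j]] <- as.numeric(df[[j]])
  numeric_ok <- vapply(df[-1L], is.numeric, logical(1))
  if (!all(numeric_ok)) {
    j <- which(!numeric_ok)[1L]
    col <- df[[j + 1L]]
    i <- which(is.na(suppressWarnings(as.numeric(col))) &
                 !col %in% c("NA", "", "NaN"))[1L]
    stop(sprintf("non-numeric value '%s' at row '%s', column '%s' in %s",
                 col[i], ids[i], colnames(df)[j + 1L], path))
  }
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- ids
  if (transpose) m <- t(m)
  if (anyNA(m)) {
    if (impute == "none") {
      ij <- which(is.na(m), arr.ind = TRUE)[1L, ]
      stop(sprintf(
        "missing value at sample '%s', feature '%s' in %s (set impute = 'median' to impute)",
        rownames(m)[ij[1L]], colnames(m)[ij[2L]], path))
    }
    for (j in which(colSums(is.na(m)) > 0L)) {
      med <- stats::median(m[, j], na.rm = TRUE)
      if (is.na(med)) med <- 0
      m[is.na(m[, j]), j] <- med
    }
  }
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  OmicsView(m, name)
}

#' Write an omics matrix as delimited text
#'
#' Inverse of \code{\link{readOmicsView}}: header row of feature IDs,
#' first column of sample IDs.
#'
#' @param view An \code{\linkS4class{OmicsView}}.
#' @param path Output path.
#' @param sep Field delimiter.
#' @export
writeOmicsView <- function(view, path, sep = "\t") {
  m <- omicsValues(view)
  df <- data.frame(sample_id = rownames(m), m, check.names = FALSE)
  data.table::fwrite(df, path, sep = sep, quote = FALSE)
  invisible(path)
}

#' Read class labels
#'
#' Reads a two-column delimited file (\code{sample_id,label}) into a named
#' factor. Class codes are assigned in the sorted order of the distinct
#' labels.
#'
#' @param path Path to a CSV/TSV label file.
#' @return A named factor of class labels.
#' @export
readLabels <- function(path) {
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first, fixed = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("label file needs columns sample_id,label")
  if (anyDuplicated(df[[1L]]))
    stop(sprintf("duplicate sample ID '%s' in %s",
                 df[[1L]][duplicated(df[[1L]])][1L], path))
  y <- factor(df[[2L]])
  if (nlevels(y) < 2L) stop("need at least 2 classes, found ", nlevels(y))
  names(y) <- df[[1L]]
  y
}

#' @rdname readLabels
#' @param labels Named factor of labels.
#' @export
writeLabels <- function(labels, path) {
  utils::write.table(
    data.frame(sample_id = names(labels), label = as.character(labels)),
    path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Align omics views and labels on their common samples
#'
#' Restricts every view and the label set to the intersection of their
#' sample IDs and puts all of them in the same deterministic (sorted) row
#' order. Idempotent: aligning aligned inputs changes nothing.
#'
#' @param views List of \code{\linkS4class{OmicsView}} objects.
#' @param labels Named factor of class labels.
#' @return List with components \code{views} (aligned list) and
#'   \code{labels} (aligned factor, empty levels dropped).
#' @export
alignViews <- function(views, labels) {
  if (length(views) < 1L) stop("need at least one view")
  idSets <- c(lapply(views, sampleIDs), list(names(labels)))
  common <- sort(Reduce(intersect, idSets))
  if (length(common) == 0L)
    stop("no samples are shared by all views and the label set")
  views <- lapply(views, function(v)
    OmicsView(omicsValues(v)[common, , drop = FALSE], viewName(v)))
  list(views = views, labels = droplevels(labels[common]))
}

#' Write / read a patient graph as sparse triplets
#'
#' The graph's weighted adjacency is written as a TSV of upper-triangle
#' edges (\code{i_id}, \code{j_id}, \code{weight}); a leading comment line
#' records the full node order so that isolated nodes survive the round
#' trip. \code{readGraph} reconstructs the symmetric adjacency exactly and
#' recomputes the renormalized propagation operator.
#'
#' @param graph A \code{\linkS4class{PatientGraph}}.
#' @param path Output (input) path.
#' @export
writeGraph <- function(graph, path) {
  A <- adjacency(graph)
  if (!all(is.finite(A))) stop("adjacency has non-finite weights")
  if (max(abs(A - t(A))) > 1e-12) stop("adjacency must be symmetric")
  ids <- sampleIDs(graph)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#samples\t%s", paste(ids, collapse = ",")), con)
  writeLines("i_id\tj_id\tweight", con)
  up <- which(upper.tri(A) & A != 0, arr.ind = TRUE)
  if (nrow(up))
    writeLines(sprintf("%s\t%s\t%.17g", ids[up[, 1L]], ids[up[, 2L]],
                       A[up]), con)
  invisible(path)
}

#' @rdname writeGraph
#' @export
readGraph <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0L || !startsWith(lines[1L], "#samples\t"))
    stop("not a graph triplet file: ", path)
  ids <- strsplit(sub("^#samples\t", "", lines[1L]), ",", fixed = TRUE)[[1L]]
  n <- length(ids)
  A <- matrix(0, n, n, dimnames = list(ids, ids))
  if (length(lines) > 2L) {
    parts <- strsplit(lines[-(1:2)], "\t", fixed = TRUE)
    i <- match(vapply(parts, `[[`, "", 1L), ids)
    j <- match(vapply(parts, `[[`, "", 2L), ids)
    w <- as.numeric(vapply(parts, `[[`, "", 3L))
    if (anyNA(i) || anyNA(j)) stop("edge references unknown sample ID")
    if (anyNA(w)) stop("non-numeric edge weight in ", path)
    A[cbind(i, j)] <- w
    A[cbind(j, i)] <- w
  }
  eps <- if (any(A > 0)) min(A[A > 0]) else 1
  new("PatientGraph", sampleIDs = ids, similarity = A + diag(n),
      adjacency = A, epsilon = eps, kTarget = sum(A > 0) / n,
      normalized = normalizeAdjacency(A))
}
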