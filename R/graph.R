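#' Cosine similarity between all patient pairs
#'
#' \eqn{S_{ij} = x_i \cdot x_j / (\|x_i\| \|x_j\|)} over the rows (samples)
#' of the view. All-zero profiles get similarity 0 to every other sample
#' and 1 to themselves, by convention.
#'
#' @param view An \code{\linkS4class{OmicsView}} or a numeric matrix
#'   (samples x features).
#' @return Symmetric n x n similarity matrix with unit diagonal.
#' @export
cosineSimilarityMatrix <- function(view) {
  X <- if (is(view, "OmicsView")) omicsValues(view) else as.matrix(view)
  if (anyNA(X)) stop("missing values in input")
  nrm <- sqrt(rowSums(X^2))
  S <- tcrossprod(X)
  denom <- outer(nrm, nrm)
  zero <- nrm == 0
  S <- ifelse(denom > 0, S / pmax(denom, .Machine$double.xmin), 0)
  S <- (S + t(S)) / 2                      # exact symmetry under fp noise
  S[S > 1] <- 1; S[S < -1] <- -1
  diag(S) <- 1
  if (any(zero)) {
    S[zero, ] <- 0; S[, zero] <- 0
    diag(S)[zero] <- 1
  }
  S
}

#' Similarity threshold achieving a target average degree
#'
#' Returns the threshold \eqn{\epsilon} such that keeping every ordered
#' pair with \eqn{S_{ij} \ge \epsilon} (diagonal excluded) preserves on
#' average at least \code{k} edges per node with the smallest possible
#' edge set: the \eqn{\lceil nk \rceil}-th largest off-diagonal similarity.
#'
#' @param S Symmetric similarity matrix.
#' @param k Target average degree, \eqn{0 < k \le n - 1}.
#' @return The threshold value.
#' @export
epsilonForTargetDegree <- function(S, k) {
  n <- nrow(S)
  if (k <= 0 || k > n - 1) stop("k must satisfy 0 < k <= n - 1")
  off <- S[row(S) != col(S)]
  sort(off, decreasing = TRUE)[ceiling(n * k)]
}

#' Threshold a similarity matrix into a weighted adjacency
#'
#' \eqn{A_{ij} = S_{ij}} when \eqn{i \ne j} and \eqn{S_{ij} \ge \epsilon},
#' else 0. Edges keep their similarity weights; the diagonal is zero.
#'
#' @param S Symmetric similarity matrix.
#' @param epsilon Threshold.
#' @return Weighted adjacency matrix.
#' @export
buildAdjacency <- function(S, epsilon) {
  if (max(abs(S - t(S))) > 1e-8) stop("S must be symmetric")
  A <- ifelse(S >= epsilon, S, 0)
  diag(A) <- 0
  (A + t(A)) / 2
}

#' Renormalized adjacency for graph convolution
#'
#' Computes \eqn{\tilde A = \hat D^{-1/2} (A + I) \hat D^{-1/2}} where
#' \eqn{\hat D} is the degree matrix of \eqn{A + I}. This is the
#' propagation operator of the GCN layers; its spectral radius is at most
#' 1, and an isolated node's row equals the corresponding identity row.
#'
#' @param A Symmetric, non-negative adjacency with zero diagonal.
#' @return The symmetric renormalized matrix.
#' @export
normalizeAdjacency <- function(A) {
  if (any(A < 0)) stop("adjacency must be non-negative")
  if (max(abs(A - t(A))) > 1e-8) stop("adjacency must be symmetric")
  Ahat <- A + diag(nrow(A))
  dmh <- 1 / sqrt(rowSums(Ahat))
  Ahat * outer(dmh, dmh)
}

#' Build the patient similarity network for one omics view
#'
#' Full pipeline for a view: cosine similarity between all patient
#' profiles, threshold chosen so the average node degree reaches
#' \code{k}, weighted thresholded adjacency, and its renormalized form.
#' A threshold that would be \eqn{\le 0} is rejected (negative-similarity
#' edges cannot enter the non-negative propagation operator); lower
#' \code{k} in that case.
#'
#' @param view An \code{\linkS4class{OmicsView}}.
#' @param k Target average degree (default 5).
#' @return A \code{\linkS4class{PatientGraph}}.
#' @examples
#' v <- OmicsView(matrix(runif(40), 8, 5,
#'        dimnames = list(paste0("s", 1:8), paste0("g", 1:5))), "mRNA")
#' g <- buildPatientGraph(v, k = 3)
#' realizedDegree(g)
#' @export
buildPatientGraph <- function(view, k = 5) {
  S <- cosineSimilarityMatrix(view)
  eps <- epsilonForTargetDegree(S, k)
  if (eps <= 0)
    stop(sprintf(
      "threshold for average degree %.3g is %.3g <= 0; use a smaller k",
      k, eps))
  A <- buildAdjacency(S, eps)
  new("PatientGraph", sampleIDs = sampleIDs(view), similarity = S,
      adjacency = A, epsilon = eps, kTarget = as.numeric(k),
      normalized = normalizeAdjacency(A))
}
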