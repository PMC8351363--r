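#' Construct a hypergraph from an incidence matrix and hyperedge weights
#'
#' A hypergraph G = (V, E, w) is held as its N x N_e 0/1 incidence matrix
#' H (H[v, e] = 1 iff vertex v belongs to hyperedge e), positive hyperedge
#' weights w, and the derived vertex degrees d(v) = row sums of H and
#' hyperedge degrees delta(e) = column sums of H. Every hyperedge must
#' contain at least 2 vertices and every vertex must belong to at least
#' one hyperedge.
#'
#' @param H 0/1 incidence matrix (vertices x hyperedges).
#' @param w positive hyperedge weight vector, length \code{ncol(H)}.
#' @return object of class \code{hypergraph} with elements \code{H},
#'   \code{w}, \code{dv}, \code{de}.
#' @export
hypergraph <- function(H, w) {
  if (!is.matrix(H) || !all(H == 0 | H == 1)) {
    stop("H must be a 0/1 incidence matrix")
  }
  if (length(w) != ncol(H)) stop("one weight per hyperedge required")
  if (any(w <= 0)) stop("hyperedge weights must be positive")
  dv <- rowSums(H)
  de <- colSums(H)
  if (any(de < 2)) stop("every hyperedge must contain at least 2 vertices")
  if (any(dv < 1)) stop("isolated vertex: d(v) = 0")
  structure(list(H = H, w = as.numeric(w), dv = dv, de = de),
            class = "hypergraph")
}

#' Build a kNN hypergraph from a kernel matrix
#'
#' One hyperedge per vertex: hyperedge j contains the center vertex v_j
#' plus its k most-similar other vertices under K (the center's
#' self-similarity is excluded from the neighbor search; ties are broken
#' toward the lower vertex index). The weight of hyperedge j is the sum
#' of the kernel values of its k neighbors to the center,
#' \eqn{w(e_j) = \sum_{i=1}^{k} K(v_i, v_j)}, and the weight vector is
#' then normalized to sum to 1. This normalization also guarantees the
#' hypergraph Laplacian below is positive semidefinite.
#'
#' @param K square symmetric kernel matrix over N vertices.
#' @param k neighbor count, \code{1 <= k <= N - 1}.
#' @return a \code{\link{hypergraph}} with N hyperedges, each of degree
#'   k + 1 (when similarities have no ties).
#' @export
knn_hypergraph <- function(K, k) {
  if (!is.matrix(K) || nrow(K) != ncol(K)) stop("K must be square")
  N <- nrow(K)
  if (k < 1 || k > N - 1) stop("k must lie in [1, N - 1]")
  H <- matrix(0, N, N)
  w <- numeric(N)
  for (j in seq_len(N)) {
    s <- K[, j]
    s[j] <- -Inf  # center excluded from its own neighbor search
    nb <- order(s, decreasing = TRUE)[seq_len(k)]  # stable: ties -> low index
    H[c(j, nb), j] <- 1
    w[j] <- sum(K[nb, j])
  }
  if (sum(w) <= 0) stop("hyperedge weights must have positive sum")
  # kernels with negative entries can yield non-positive edge weights;
  # floor them so the hypergraph invariant w > 0 holds
  w <- pmax(w, 1e-12 * max(w))
  hypergraph(H, w / sum(w))
}

#' Hypergraph Laplacian
#'
#' \deqn{L^h = I - \Theta, \qquad
#'   \Theta = D_v^{-1/2} H D_w D_e^{-1} H^T D_v^{-1/2}}
#' with D_v, D_e, D_w the diagonal matrices of vertex degrees, hyperedge
#' degrees, and hyperedge weights. With weights normalized to sum to at
#' most 1 (as \code{\link{knn_hypergraph}} produces), \eqn{L^h} is
#' positive semidefinite. When every hyperedge has degree 2 and unit
#' weight, \eqn{L^h} reduces to half the symmetric normalized graph
#' Laplacian of the induced graph.
#'
#' @param G a \code{\link{hypergraph}}.
#' @return symmetric N x N Laplacian matrix.
#' @export
hypergraph_laplacian <- function(G) {
  if (!inherits(G, "hypergraph")) stop("G must be a hypergraph")
  dvi <- 1 / sqrt(G$dv)
  B <- G$H * dvi  # D_v^{-1/2} H, recycled by row
  Theta <- B %*% (t(B) * (G$w / G$de))
  L <- diag(nrow(B)) - Theta
  (L + t(L)) / 2
}

#' Symmetric normalized graph Laplacian of a similarity matrix
#'
#' \eqn{L = D^{-1/2} (D - K) D^{-1/2}} with
#' \eqn{D(k, k) = \sum_l K(k, l)}; requires strictly positive row sums.
#' \code{form = "literal"} instead applies \eqn{D^{-1/2} (D - K) D^{1/2}}
#' (an asymmetric variant that appears in parts of the LapRLS literature;
#' it is not positive semidefinite and is provided for fidelity
#' experiments only).
#'
#' @param K square similarity matrix with positive row sums.
#' @param form \code{"symmetric"} (default) or \code{"literal"}.
#' @return N x N Laplacian matrix.
#' @export
graph_laplacian <- function(K, form = c("symmetric", "literal")) {
  form <- match.arg(form)
  if (!is.matrix(K) || nrow(K) != ncol(K)) stop("K must be square")
  d <- rowSums(K)
  if (any(d <= 0)) stop("zero or negative row sum in similarity matrix")
  Delta <- diag(d) - K
  if (form == "symmetric") {
    L <- Delta * outer(1 / sqrt(d), 1 / sqrt(d))
    (L + t(L)) / 2
  } else {
    Delta * outer(1 / sqrt(d), sqrt(d))
  }
}
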