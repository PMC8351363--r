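#' Gaussian interaction profile (GIP) kernel
#'
#' Similarity between two entities from their association profiles:
#' \deqn{K(i, j) = \exp(-\gamma \, ||y_i - y_j||^2)}
#' where \eqn{y_i} is row i of the association matrix (disease side) or
#' column i (gene side). Profiles are taken from the \emph{training}
#' network; in cross-validation the kernel must be rebuilt from each
#' fold's masked matrix.
#'
#' @param Y binary association matrix.
#' @param side \code{"disease"} (rows of Y) or \code{"gene"} (columns).
#' @param gamma kernel bandwidth, > 0; default 0.5.
#' @return symmetric kernel matrix with unit diagonal and entries in (0, 1].
#' @examples
#' Y <- matrix(c(1, 0, 0, 1), 2, 2)
#' gip_kernel(Y, "disease")
#' @export
gip_kernel <- function(Y, side = c("disease", "gene"), gamma = 0.5) {
  side <- match.arg(side)
  validate_association(Y)
  if (!is.numeric(gamma) || length(gamma) != 1L || gamma <= 0) {
    stop("gamma must be a positive scalar")
  }
  P <- if (side == "disease") Y else t(Y)
  rs <- rowSums(P^2)
  d2 <- outer(rs, rs, "+") - 2 * tcrossprod(P)
  d2[d2 < 0] <- 0
  K <- exp(-gamma * d2)
  K <- (K + t(K)) / 2
  diag(K) <- 1
  ids <- if (side == "disease") rownames(Y) else colnames(Y)
  dimnames(K) <- list(ids, ids)
  K
}

#' Construct a disease DAG for semantic similarity
#'
#' A directed acyclic graph of disease terms, edges pointing child ->
#' parent (e.g. a MeSH-style hierarchy). Acyclicity and referential
#' integrity are checked at construction.
#'
#' @param nodes character vector of term ids.
#' @param parent_edges data frame (or 2-column matrix) with columns
#'   \code{child}, \code{parent}.
#' @return object of class \code{disease_dag}.
#' @export
disease_dag <- function(nodes, parent_edges) {
  nodes <- as.character(nodes)
  if (anyDuplicated(nodes)) stop("duplicated DAG node ids")
  pe <- as.data.frame(parent_edges, stringsAsFactors = FALSE)
  if (nrow(pe) > 0L) {
    if (ncol(pe) < 2L) stop("parent_edges needs child and parent columns")
    names(pe)[1:2] <- c("child", "parent")
    pe$child <- as.character(pe$child)
    pe$parent <- as.character(pe$parent)
    miss <- setdiff(c(pe$child, pe$parent), nodes)
    if (length(miss)) stop("edge references unknown node(s): ",
                           paste(miss, collapse = ", "))
  } else {
    pe <- data.frame(child = character(0), parent = character(0))
  }
  dag <- structure(list(nodes = nodes, edges = pe[, c("child", "parent")]),
                   class = "disease_dag")
  assert_acyclic(dag)
  dag
}

# Kahn's algorithm over child -> parent edges; errors on a directed cycle.
assert_acyclic <- function(dag) {
  nodes <- dag$nodes
  edges <- dag$edges
  indeg <- table(factor(edges$parent, levels = nodes))
  indeg <- as.integer(indeg)
  names(indeg) <- nodes
  queue <- nodes[indeg == 0L]
  seen <- 0L
  while (length(queue)) {
    v <- queue[[1L]]
    queue <- queue[-1L]
    seen <- seen + 1L
    up <- edges$parent[edges$child == v]
    for (p in up) {
      indeg[[p]] <- indeg[[p]] - 1L
      if (indeg[[p]] == 0L) queue <- c(queue, p)
    }
  }
  if (seen != length(nodes)) stop("disease DAG contains a directed cycle")
  invisible(dag)
}

# All ancestors of d (following child -> parent edges), including d itself.
dag_ancestors <- function(dag, d) {
  anc <- character(0)
  frontier <- d
  while (length(frontier)) {
    anc <- c(anc, frontier)
    frontier <- unique(dag$edges$parent[dag$edges$child %in% frontier])
    frontier <- setdiff(frontier, anc)
  }
  anc
}

# Semantic contribution D_d(t) of each ancestor t of d:
# D_d(d) = 1; D_d(t) = max over children t' of t that are ancestors of d
# of delta * D_d(t'). Memoized recursion over the ancestor-induced sub-DAG.
semantic_scores <- function(dag, d, delta) {
  anc <- dag_ancestors(dag, d)
  sub <- dag$edges[dag$edges$child %in% anc & dag$edges$parent %in% anc, ,
                   drop = FALSE]
  memo <- new.env(parent = emptyenv())
  assign(d, 1, envir = memo)
  score <- function(t) {
    if (!is.null(v <- memo[[t]])) return(v)
    kids <- sub$child[sub$parent == t]
    v <- delta * max(vapply(kids, score, numeric(1)))
    assign(t, v, envir = memo)
    v
  }
  vapply(anc, score, numeric(1))
}

#' DAG-based disease semantic similarity kernel
#'
#' Each disease d is scored against its ancestor set T_d: the term d
#' itself contributes 1, and each ancestor t contributes
#' \eqn{\Delta \cdot \max_{t'} D_d(t')} over the children t' of t that are
#' themselves ancestors of d, with semantic contribution factor
#' \eqn{\Delta \in (0, 1]}. With \eqn{DV(d) = \sum_t D_d(t)}, the kernel is
#' \deqn{K(d_i, d_j) = \frac{\sum_{t \in T_i \cap T_j} (D_{d_i}(t) +
#'   D_{d_j}(t))}{DV(d_i) + DV(d_j)}}
#' so that \eqn{K(d, d) = 1} and diseases in disjoint DAG components have
#' similarity 0.
#'
#' @param dag a \code{\link{disease_dag}}.
#' @param targets disease ids to build the kernel over (must be DAG
#'   nodes); defaults to all nodes.
#' @param delta semantic contribution factor in (0, 1]; default 0.5.
#' @return symmetric kernel matrix over \code{targets} with unit diagonal.
#' @examples
#' dag <- disease_dag(c("p", "a", "b"),
#'                    data.frame(child = c("a", "b"), parent = c("p", "p")))
#' semantic_kernel(dag, c("a", "b"))  # siblings: K(a, b) = 1/3
#' @export
semantic_kernel <- function(dag, targets = dag$nodes, delta = 0.5) {
  if (!inherits(dag, "disease_dag")) stop("dag must be a disease_dag")
  if (!is.numeric(delta) || delta <= 0 || delta > 1) {
    stop("delta must lie in (0, 1]")
  }
  targets <- as.character(targets)
  unknown <- setdiff(targets, dag$nodes)
  if (length(unknown)) stop("unknown target id(s): ",
                            paste(unknown, collapse = ", "))
  scores <- lapply(targets, function(d) semantic_scores(dag, d, delta))
  names(scores) <- targets
  dv <- vapply(scores, sum, numeric(1))
  n <- length(targets)
  K <- matrix(0, n, n, dimnames = list(targets, targets))
  for (i in seq_len(n)) {
    for (j in i:n) {
      shared <- intersect(names(scores[[i]]), names(scores[[j]]))
      num <- if (length(shared)) {
        sum(scores[[i]][shared]) + sum(scores[[j]][shared])
      } else 0
      K[i, j] <- K[j, i] <- num / (dv[[i]] + dv[[j]])
    }
  }
  K
}

#' Cosine similarity kernel from per-entity feature vectors
#'
#' \eqn{K(i, j) = p_i \cdot p_j / (||p_i|| \, ||p_j||)}. An all-zero
#' feature vector has undefined cosine similarity; such entities are
#' assigned similarity 0 to every other entity and 1 to themselves, which
#' keeps the unit diagonal.
#'
#' @param features numeric N x p matrix of feature vectors, rownames as
#'   entity ids.
#' @return symmetric kernel matrix with unit diagonal.
#' @export
cosine_kernel <- function(features) {
  X <- as.matrix(features)
  if (nrow(X) < 1L || ncol(X) < 1L) stop("empty feature table")
  if (anyNA(X) || any(!is.finite(X))) stop("features must be finite")
  if (all(X == 0)) stop("at least one feature vector must be nonzero")
  nrm <- sqrt(rowSums(X^2))
  zero <- nrm == 0
  nrm[zero] <- 1
  K <- tcrossprod(X / nrm)
  K[zero, ] <- 0
  K[, zero] <- 0
  K <- (K + t(K)) / 2
  diag(K) <- 1
  ids <- rownames(X)
  if (!is.null(ids)) dimnames(K) <- list(ids, ids)
  K
}

#' Normalized Smith-Waterman similarity kernel
#'
#' Given raw pairwise alignment scores SW(i, j) with strictly positive
#' self-scores, returns
#' \eqn{K(i, j) = SW(i, j) / (\sqrt{SW(i, i)} \sqrt{SW(j, j)})},
#' symmetrized as \eqn{(K + K^T)/2} and with the diagonal set to 1.
#' The alignment itself is delegated to external tools; this function
#' only consumes their raw score matrix.
#'
#' @param raw square matrix of raw alignment scores (approximately
#'   symmetric, strictly positive diagonal).
#' @return symmetric kernel matrix with unit diagonal.
#' @export
normalized_sw_kernel <- function(raw) {
  raw <- as.matrix(raw)
  if (nrow(raw) != ncol(raw)) stop("raw score matrix must be square")
  d <- diag(raw)
  if (any(!is.finite(d)) || any(d <= 0)) {
    stop("raw self-scores must be strictly positive")
  }
  K <- raw / sqrt(outer(d, d))
  K <- (K + t(K)) / 2
  diag(K) <- 1
  K
}
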