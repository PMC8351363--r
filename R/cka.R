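#' Center a kernel matrix
#'
#' Double-centering \eqn{K^c = U_N K U_N} with
#' \eqn{U_N = I - (1/N) 1 1^T}; every row and column of the result sums
#' to zero, and the map is idempotent.
#'
#' @param K square kernel matrix.
#' @return centered kernel matrix.
#' @export
center_kernel <- function(K) {
  if (!is.matrix(K) || nrow(K) != ncol(K)) stop("K must be square")
  n <- nrow(K)
  rm_ <- rowMeans(K)
  cm_ <- colMeans(K)
  K - matrix(rm_, n, n) - matrix(cm_, n, n, byrow = TRUE) + mean(K)
}

#' Frobenius alignment (cosine similarity) between two kernel matrices
#'
#' \eqn{CA(K_1, K_2) = \langle K_1, K_2 \rangle_F /
#'   (||K_1||_F \, ||K_2||_F)}, in [-1, 1].
#'
#' @param K1,K2 same-shape square matrices with nonzero Frobenius norm.
#' @return alignment score.
#' @export
kernel_alignment <- function(K1, K2) {
  if (!all(dim(K1) == dim(K2))) stop("kernels must have the same shape")
  n1 <- sqrt(sum(K1^2))
  n2 <- sqrt(sum(K2^2))
  if (n1 == 0 || n2 == 0) stop("alignment undefined for zero-norm kernel")
  sum(K1 * K2) / (n1 * n2)
}

#' Ideal (label-space) kernel from training associations
#'
#' \eqn{K^d_{ideal} = Y Y^T} on the disease side and
#' \eqn{K^g_{ideal} = Y^T Y} on the gene side, built from the training
#' fold's association matrix only, so cross-validation stays leak-free.
#'
#' @param Y binary training association matrix.
#' @param side \code{"disease"} or \code{"gene"}.
#' @return symmetric positive semidefinite matrix.
#' @export
ideal_kernel <- function(Y, side = c("disease", "gene")) {
  side <- match.arg(side)
  validate_association(Y)
  if (side == "disease") tcrossprod(Y) else crossprod(Y)
}

# Exact solver for min_w w'Mw - 2 w'a  s.t.  w >= 0, sum(w) = 1.
# Enumerates active sets (support subsets): for each nonempty subset S the
# equality-constrained KKT system is solved; feasible candidates compete on
# objective value. Exact for the small kernel counts used here (k <= ~10).
qp_simplex <- function(M, a) {
  k <- nrow(M)
  M <- (M + t(M)) / 2 + diag(1e-12, k)  # guard against rank deficiency
  best_w <- NULL
  best_obj <- Inf
  for (code in seq_len(2^k - 1L)) {
    S <- which(bitwAnd(code, bitwShiftL(1L, seq_len(k) - 1L)) != 0L)
    kk <- length(S)
    KKT <- rbind(cbind(2 * M[S, S, drop = FALSE], rep(1, kk)),
                 c(rep(1, kk), 0))
    rhs <- c(2 * a[S], 1)
    sol <- tryCatch(solve(KKT, rhs),
                    error = function(e) drop(MASS::ginv(KKT) %*% rhs))
    w_s <- sol[seq_len(kk)]
    if (any(w_s < -1e-9)) next
    w <- numeric(k)
    w[S] <- pmax(w_s, 0)
    w <- w / sum(w)
    obj <- drop(crossprod(w, M %*% w)) - 2 * sum(w * a)
    if (obj < best_obj - 1e-15) {
      best_obj <- obj
      best_w <- w
    }
  }
  w <- best_w
  w[w < 1e-10] <- 0
  w <- w / sum(w)
  list(weights = w, objective = drop(crossprod(w, M %*% w)) - 2 * sum(w * a))
}

#' Solve centered-kernel-alignment weights for a kernel bundle
#'
#' Maximizing the alignment between the centered combined kernel
#' \eqn{\sum_i \omega_i K_i} and the ideal kernel over the simplex
#' \eqn{\omega \ge 0, \sum \omega_i = 1} reduces to the quadratic program
#' \deqn{\min_\omega \; \omega^T M \omega - 2 \omega^T a, \qquad
#'   M_{ij} = \langle K^c_i, K^c_j \rangle_F, \quad
#'   a_i = \langle K^c_i, K_{ideal} \rangle_F.}
#' Only the candidate kernels are centered; set
#' \code{center_ideal = TRUE} to center the ideal kernel as well.
#' The program is solved exactly by active-set enumeration; weights below
#' \code{1e-10} are snapped to zero and the vector renormalized.
#'
#' @param kernels list of same-shape square kernel matrices (one side).
#' @param ideal ideal kernel from \code{\link{ideal_kernel}}; must have
#'   nonzero Frobenius norm.
#' @param center_ideal also center the ideal kernel before computing the
#'   alignment vector; default \code{FALSE}.
#' @return list with \code{weights} (named like \code{kernels}) and the
#'   attained QP \code{objective}.
#' @export
cka_weights <- function(kernels, ideal, center_ideal = FALSE) {
  if (!is.list(kernels) || length(kernels) < 1L) {
    stop("kernels must be a non-empty list")
  }
  dims <- vapply(kernels, function(K) dim(K), integer(2))
  if (any(dims != nrow(ideal))) {
    stop("all kernels and the ideal kernel must share one shape")
  }
  if (sum(ideal^2) == 0) {
    stop("ideal kernel has zero norm (no training associations)")
  }
  tgt <- if (center_ideal) center_kernel(ideal) else ideal
  Kc <- lapply(kernels, center_kernel)
  k <- length(Kc)
  a <- vapply(Kc, function(K) sum(K * tgt), numeric(1))
  M <- matrix(0, k, k)
  for (i in seq_len(k)) {
    for (j in i:k) {
      M[i, j] <- M[j, i] <- sum(Kc[[i]] * Kc[[j]])
    }
  }
  sol <- qp_simplex(M, a)
  names(sol$weights) <- names(kernels)
  sol
}

#' Combine a kernel bundle with given weights
#'
#' \eqn{K^* = \sum_i \omega_i K_i} over the \emph{uncentered} member
#' kernels.
#'
#' @param kernels list of same-shape square kernel matrices.
#' @param weights nonnegative weights summing to 1 (within 1e-8).
#' @return combined kernel matrix.
#' @export
combine_kernels <- function(kernels, weights) {
  if (length(kernels) != length(weights)) {
    stop("one weight per kernel required")
  }
  if (any(weights < -1e-10) || abs(sum(weights) - 1) > 1e-8) {
    stop("weights must be nonnegative and sum to 1")
  }
  K <- 0
  for (i in seq_along(kernels)) K <- K + weights[[i]] * kernels[[i]]
  (K + t(K)) / 2
}

#' @rdname combine_kernels
#' @details \code{mean_combine} is the uniform-weight (mean weighted MKL)
#'   ablation: \eqn{\omega_i = 1/k}.
#' @export
mean_combine <- function(kernels) {
  k <- length(kernels)
  if (k < 1L) stop("kernels must be a non-empty list")
  combine_kernels(kernels, rep(1 / k, k))
}
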