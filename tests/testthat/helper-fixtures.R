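# Shared fixture builders and independent oracles for the test suite.

# Random symmetric PSD kernel with unit-ish diagonal, entries >= 0.
random_kernel <- function(n, nonneg = TRUE) {
  A <- matrix(rnorm(n * n), n, n)
  K <- crossprod(A) / n
  if (nonneg) K <- abs(K)
  K <- (K + t(K)) / 2
  diag(K) <- pmax(diag(K), 1)
  K / max(diag(K))
}

# Random binary association matrix with ids and at least one 1 and one 0.
random_assoc <- function(n, m, p = 0.4) {
  repeat {
    Y <- matrix(as.numeric(rbinom(n * m, 1, p)), n, m,
                dimnames = list(paste0("d", seq_len(n)),
                                paste0("g", seq_len(m))))
    if (any(Y == 1) && any(Y == 0)) return(Y)
  }
}

# Brute-force pairwise AUC oracle: mean over positive-negative pairs with
# half credit for ties.
auc_bruteforce <- function(scores, labels) {
  sp <- scores[labels == 1]
  sn <- scores[labels == 0]
  tot <- 0
  for (p in sp) {
    for (q in sn) {
      tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
    }
  }
  tot / (length(sp) * length(sn))
}

# Brute-force AUPR oracle: sweep distinct thresholds from high to low,
# recompute precision and recall from scratch at each, sum step areas.
aupr_bruteforce <- function(scores, labels) {
  P <- sum(labels == 1)
  th <- sort(unique(scores), decreasing = TRUE)
  area <- 0
  prev_rec <- 0
  for (t in th) {
    sel <- scores >= t
    prec <- sum(labels[sel] == 1) / sum(sel)
    rec <- sum(labels[sel] == 1) / P
    area <- area + (rec - prev_rec) * prec
    prev_rec <- rec
  }
  area
}

# Independent recursive evaluation of the DAG semantic similarity,
# written directly from the definition (no memoization, no shared code).
semantic_oracle <- function(nodes, edges, d1, d2, delta) {
  parents_of <- function(x) edges$parent[edges$child == x]
  anc <- function(d) {
    out <- d
    frontier <- d
    while (length(frontier)) {
      frontier <- setdiff(unique(unlist(lapply(frontier, parents_of))), out)
      out <- c(out, frontier)
    }
    out
  }
  contrib <- function(d, t, ancset) {
    if (t == d) return(1)
    kids <- edges$child[edges$parent == t]
    kids <- intersect(kids, ancset)
    delta * max(vapply(kids, function(k) contrib(d, k, ancset), numeric(1)))
  }
  a1 <- anc(d1)
  a2 <- anc(d2)
  D1 <- vapply(a1, function(t) contrib(d1, t, a1), numeric(1))
  D2 <- vapply(a2, function(t) contrib(d2, t, a2), numeric(1))
  shared <- intersect(a1, a2)
  num <- if (length(shared)) sum(D1[shared]) + sum(D2[shared]) else 0
  num / (sum(D1) + sum(D2))
}

# Exhaustive simplex-grid oracle for the CKA QP objective (k = 2 or 3).
cka_grid_oracle <- function(M, a, step = 1e-3) {
  k <- nrow(M)
  stopifnot(k %in% 2:3)
  g <- seq(0, 1, by = step)
  if (k == 2) {
    W <- cbind(g, 1 - g)
  } else {
    W <- expand.grid(w1 = g, w2 = g)
    W <- W[W$w1 + W$w2 <= 1 + 1e-12, ]
    W <- cbind(W$w1, W$w2, pmax(1 - W$w1 - W$w2, 0))
  }
  obj <- rowSums((W %*% M) * W) - 2 * drop(W %*% a)
  min(obj)
}

# Joint ridge least-squares oracle for the alternating solver with
# lambda = 0: minimizes ||K_d a_d + (K_g a_g)^T - 2Y||_F^2
# + beta(||a_d||^2 + ||a_g||^2) by one stacked normal-equations solve.
joint_ls_oracle <- function(Y, K_d, K_g, beta) {
  n <- nrow(Y)
  m <- ncol(Y)
  nc <- n * m
  cols <- matrix(0, nc, 2 * nc)
  for (j in seq_len(m)) {   # alpha_d columns: vec(K_d E_ij) = K_d[, i] in col j
    for (i in seq_len(n)) {
      E <- matrix(0, n, m)
      E[i, j] <- 1
      cols[, (j - 1L) * n + i] <- as.vector(K_d %*% E)
    }
  }
  for (j in seq_len(n)) {   # alpha_g columns
    for (i in seq_len(m)) {
      E <- matrix(0, m, n)
      E[i, j] <- 1
      cols[, nc + (j - 1L) * m + i] <- as.vector(t(K_g %*% E))
    }
  }
  x <- solve(crossprod(cols) + diag(beta, 2 * nc),
             crossprod(cols, as.vector(2 * Y)))
  list(alpha_d = matrix(x[seq_len(nc)], n, m),
       alpha_g = matrix(x[nc + seq_len(nc)], m, n))
}

# Tiny TSV writer for I/O tests.
write_lines_tmp <- function(lines) {
  f <- tempfile(fileext = ".tsv")
  writeLines(lines, f)
  f
}
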