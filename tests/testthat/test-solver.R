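test_that("objective value matches a term-by-term brute-force computation", {
  set.seed(31)
  Y <- random_assoc(4, 3)
  K_d <- random_kernel(4)
  K_g <- random_kernel(3)
  L_d <- graph_laplacian(K_d)
  L_g <- graph_laplacian(K_g)
  a_d <- matrix(rnorm(12), 4, 3)
  a_g <- matrix(rnorm(12), 3, 4)

  # zero coefficients: only the residual term remains
  z_d <- matrix(0, 4, 3)
  z_g <- matrix(0, 3, 4)
  expect_equal(dhrls_objective(z_d, z_g, Y * 0, K_d, K_g, beta = 1), 0)
  expect_equal(dhrls_objective(z_d, z_g, Y, K_d, K_g, beta = 1),
               4 * sum(Y^2))

  # element-loop oracle for every term
  R <- K_d %*% a_d + t(K_g %*% a_g) - 2 * Y
  res <- 0
  for (i in 1:4) for (j in 1:3) res <- res + R[i, j]^2
  tr_d <- sum(diag(t(a_d) %*% K_d %*% L_d %*% K_d %*% a_d))
  tr_g <- sum(diag(t(a_g) %*% K_g %*% L_g %*% K_g %*% a_g))
  beta <- 0.7
  expect_equal(
    dhrls_objective(a_d, a_g, Y, K_d, K_g, L_d, L_g, 0.3, 0.9, beta),
    res + 0.3 * tr_d + 0.9 * tr_g + beta * (sum(a_d^2) + sum(a_g^2)),
    tolerance = 1e-10)
})

test_that("block updates are stationary points of the objective", {
  set.seed(32)
  for (rep in 1:5) {
    n <- sample(3:6, 1); m <- sample(3:6, 1)
    Y <- random_assoc(n, m)
    K_d <- random_kernel(n); K_g <- random_kernel(m)
    L_d <- hypergraph_laplacian(knn_hypergraph(K_d, 2))
    L_g <- hypergraph_laplacian(knn_hypergraph(K_g, 2))
    a_g <- matrix(rnorm(m * n), m, n)
    ld <- 0.6; lg <- 0.4; beta <- 0.8
    a_d <- update_alpha_d(Y, K_d, K_g, a_g, L_d, ld, beta)
    grad <- 2 * K_d %*% (K_d %*% a_d + t(K_g %*% a_g) - 2 * Y) +
      2 * beta * a_d + 2 * ld * K_d %*% L_d %*% K_d %*% a_d
    expect_lt(max(abs(grad)), 1e-8)
    a_g2 <- update_alpha_g(Y, K_d, K_g, a_d, L_g, lg, beta)
    grad_g <- 2 * K_g %*% (K_g %*% a_g2 + t(K_d %*% a_d) - 2 * t(Y)) +
      2 * beta * a_g2 + 2 * lg * K_g %*% L_g %*% K_g %*% a_g2
    expect_lt(max(abs(grad_g)), 1e-8)
  }
})

test_that("a single ridge update solves the trivial identity-kernel case", {
  set.seed(33)
  Y <- random_assoc(4, 3)
  # K = I, lambda = 0, beta = 1, alpha_g = 0: (I + I) alpha = 2Y -> alpha = Y
  a_d <- update_alpha_d(Y, diag(4), diag(3), matrix(0, 3, 4),
                        NULL, 0, 1)
  expect_equal(a_d, unname(Y), tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("the scalar instance follows the hand-iterated recursion", {
  # 1x1, K = 1, Y = 1, lambda = 0, beta = 1: alpha <- (2 - alpha) / 2
  Y <- matrix(1, 1, 1, dimnames = list("d1", "g1"))
  K <- matrix(1, 1, 1)
  a_d <- update_alpha_d(Y, K, K, matrix(0, 1, 1), NULL, 0, 1)
  expect_equal(drop(a_d), 1)
  a_g <- update_alpha_g(Y, K, K, a_d, NULL, 0, 1)
  expect_equal(drop(a_g), 0.5)
  fit <- dhrls(Y, K, K, lambda_d = 0, lambda_g = 0, n_iter = 60)
  expect_equal(drop(fit$alpha_d), 2 / 3, tolerance = 1e-10)
  expect_equal(drop(fit$alpha_g), 2 / 3, tolerance = 1e-10)
  expect_equal(drop(predict(fit)), 2 / 3, tolerance = 1e-10)
})

test_that("alternating fit reaches the joint least-squares minimizer", {
  set.seed(34)
  for (rep in 1:5) {
    n <- sample(3:5, 1); m <- sample(3:4, 1)
    Y <- random_assoc(n, m)
    K_d <- random_kernel(n); K_g <- random_kernel(m)
    fit <- dhrls(Y, K_d, K_g, lambda_d = 0, lambda_g = 0, beta = 1,
                 n_iter = 500, tol = 1e-15, regularizer = "none")
    oracle <- joint_ls_oracle(Y, K_d, K_g, beta = 1)
    expect_equal(fit$alpha_d, oracle$alpha_d, tolerance = 1e-6)
    expect_equal(fit$alpha_g, oracle$alpha_g, tolerance = 1e-6)
  }
})

test_that("the objective trace never increases and fixed points behave", {
  set.seed(35)
  for (rep in 1:10) {
    n <- sample(3:7, 1); m <- sample(3:7, 1)
    Y <- random_assoc(n, m)
    fit <- dhrls(Y, random_kernel(n), random_kernel(m),
                 lambda_d = runif(1, 0, 2), lambda_g = runif(1, 0, 2),
                 knn_k = 2, n_iter = 8)
    expect_true(all(diff(fit$objective_trace) <= 1e-8))
  }
  # all-zero training matrix: the origin is the fixed point
  Y0 <- matrix(0, 3, 4, dimnames = list(paste0("d", 1:3), paste0("g", 1:4)))
  fit0 <- dhrls(Y0, diag(3), diag(4), lambda_d = 0, lambda_g = 0)
  expect_equal(fit0$alpha_d, matrix(0, 3, 4))
  expect_equal(unname(predict(fit0)), matrix(0, 3, 4))
})

test_that("system matrices are positive definite and one round is kernel ridge", {
  set.seed(36)
  n <- 5
  Y <- random_assoc(n, 4)
  K <- random_kernel(n)
  L <- hypergraph_laplacian(knn_hypergraph(K, 2))
  beta <- 0.9
  A <- K %*% K + diag(beta, n) + 1.3 * K %*% L %*% K
  ev <- eigen((A + t(A)) / 2, symmetric = TRUE, only.values = TRUE)$values
  expect_gte(min(ev), beta - 1e-8)

  # first half-step from alpha_g = 0 with lambda = 0 is the ridge solution
  fit <- dhrls(Y, K, random_kernel(4), lambda_d = 0, lambda_g = 0,
               beta = beta, n_iter = 1, regularizer = "none")
  ridge <- solve(K %*% K + diag(beta, n), 2 * K %*% Y)
  a1 <- update_alpha_d(Y, K, random_kernel(4), matrix(0, 4, n), NULL, 0, beta)
  expect_equal(a1, ridge, tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("hypergraph and graph regularization agree through the L/2 reduction", {
  set.seed(37)
  n <- 6; m <- 5
  Y <- random_assoc(n, m)
  K_d <- random_kernel(n); K_g <- random_kernel(m)
  # a degree-2 hypergraph Laplacian equals half a graph Laplacian, so
  # feeding L and L/2 with lambda and 2*lambda must give identical fits
  L_d <- hypergraph_laplacian(hypergraph(knn_hypergraph(K_d, 1)$H, rep(1, n)))
  L_g <- hypergraph_laplacian(hypergraph(knn_hypergraph(K_g, 1)$H, rep(1, m)))
  f1 <- dhrls(Y, K_d, K_g, lambda_d = 1, lambda_g = 0.5,
              laplacian_d = L_d, laplacian_g = L_g)
  f2 <- dhrls(Y, K_d, K_g, lambda_d = 0.5, lambda_g = 0.25,
              laplacian_d = 2 * L_d, laplacian_g = 2 * L_g)
  expect_equal(f1$alpha_d, f2$alpha_d, tolerance = 1e-8)
  expect_equal(predict(f1), predict(f2), tolerance = 1e-8)
})

test_that("LapRLS baseline: identity cases and the dense-inverse oracle", {
  set.seed(38)
  Y <- random_assoc(5, 4)
  K <- random_kernel(5)
  expect_equal(laprls(Y, K, lambda = 0), Y, tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_equal(laprls(Y, diag(5), lambda = 1), Y, tolerance = 1e-10,
               ignore_attr = TRUE)  # L of I is 0
  lam <- 0.7
  L <- graph_laplacian(K)
  oracle <- K %*% solve(K + lam * L %*% K) %*% Y
  expect_equal(laprls(Y, K, lam), oracle, tolerance = 1e-8,
               ignore_attr = TRUE)
  # gene side mirrors the transposed problem; dual averages both
  K_g <- random_kernel(4)
  Fg <- laprls(Y, K_g, lam, side = "gene")
  oracle_g <- t(K_g %*% solve(K_g + lam * graph_laplacian(K_g) %*% K_g) %*% t(Y))
  expect_equal(Fg, oracle_g, tolerance = 1e-8, ignore_attr = TRUE)
  expect_equal(laprls_dual(Y, K, K_g, lam, lam),
               (laprls(Y, K, lam) + Fg) / 2, tolerance = 1e-12)
})

test_that("predictions permute with the disease ordering", {
  set.seed(39)
  n <- 6; m <- 4
  Y <- random_assoc(n, m)
  K_d <- random_kernel(n); K_g <- random_kernel(m)
  p <- sample(n)
  f <- dhrls(Y, K_d, K_g, lambda_d = 0, lambda_g = 0)
  fp <- dhrls(Y[p, ], K_d[p, p], K_g, lambda_d = 0, lambda_g = 0)
  expect_equal(unname(predict(fp)), unname(predict(f)[p, ]),
               tolerance = 1e-10)
})
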