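test_that("AUC: separability extremes, the 3/4 example, and tie handling", {
  expect_equal(auc_score(c(3, 4, 1, 2), c(1, 1, 0, 0)), 1)
  expect_equal(auc_score(c(1, 2, 3, 4), c(1, 1, 0, 0)), 0)
  expect_equal(auc_score(c(0.9, 0.8, 0.7, 0.6), c(1, 0, 1, 0)), 3 / 4)
  expect_equal(auc_score(c(1, 1), c(1, 0)), 0.5)  # full tie = half credit
  expect_error(auc_score(c(1, 2), c(1, 1)), "both classes")
})

test_that("AUPR: the 5/6 example and rank invariance", {
  expect_equal(aupr_score(c(0.9, 0.8), c(1, 1)), 1)
  expect_equal(aupr_score(c(0.9, 0.8, 0.7, 0.6), c(1, 0, 1, 0)),
               5 / 6, tolerance = 1e-14)
  s <- c(0.2, 0.5, 0.1, 0.9, 0.4)
  l <- c(0, 1, 0, 1, 1)
  expect_equal(aupr_score(exp(3 * s), l), aupr_score(s, l),
               tolerance = 1e-12)
  expect_error(aupr_score(c(1, 2), c(0, 0)), "positive")
})

test_that("metrics agree with brute-force oracles, including heavy ties", {
  set.seed(41)
  for (rep in 1:50) {
    len <- sample(5:50, 1)
    scores <- sample(seq(0, 1, by = 0.1), len, replace = TRUE)
    labels <- rbinom(len, 1, 0.4)
    if (sum(labels) == 0 || sum(labels) == len) next
    expect_equal(auc_score(scores, labels), auc_bruteforce(scores, labels),
                 tolerance = 1e-12)
    expect_equal(aupr_score(scores, labels), aupr_bruteforce(scores, labels),
                 tolerance = 1e-12)
  }
})

test_that("CV1 folds partition the positives and mask them from training", {
  set.seed(42)
  Y <- random_assoc(10, 12, p = 0.35)
  fl <- cv_folds(Y, "CV1", n_folds = 5, seed = 7)
  ones <- which(Y == 1)
  held <- lapply(fl$folds, function(f) setdiff(which(Y == 1), which(f$train == 1)))
  # union of test positives = all positives, pairwise disjoint
  expect_setequal(unlist(held), ones)
  expect_equal(sum(lengths(held)), length(ones))
  for (f in fl$folds) {
    test_pos <- f$test_idx[f$test_labels == 1]
    expect_true(all(f$train[test_pos] == 0))        # no leakage
    expect_setequal(f$test_idx[f$test_labels == 0], which(Y == 0))
  }
  # reproducible: same seed, identical folds
  fl2 <- cv_folds(Y, "CV1", n_folds = 5, seed = 7)
  expect_identical(fl, fl2)
  expect_false(identical(fl, cv_folds(Y, "CV1", n_folds = 5, seed = 8)))
})

test_that("CV2 folds hold out whole disease rows (cold start)", {
  set.seed(43)
  Y <- random_assoc(10, 8, p = 0.5)
  fl <- cv_folds(Y, "CV2", n_folds = 10, seed = 3)
  rows_held <- lapply(fl$folds, function(f) which(rowSums(f$train) == 0 &
                                                    rowSums(Y) > 0))
  expect_equal(sum(lengths(rows_held)), 10)   # one disease per fold
  for (f in fl$folds) {
    held_rows <- unique(((f$test_idx - 1L) %% nrow(Y)) + 1L)
    expect_true(all(f$train[held_rows, ] == 0))
    expect_equal(length(f$test_idx), length(held_rows) * ncol(Y))
    expect_gt(sum(f$test_labels), 0)
    # the per-fold GIP kernel sees only the masked matrix: held-out rows
    # have empty profiles, hence identical kernel rows among themselves
    g <- gip_kernel(f$train, "disease")
    if (length(held_rows) > 1) {
      expect_equal(g[held_rows[1], held_rows[2]], 1)
    }
  }
  expect_error(cv_folds(Y, "CV2", n_folds = 11), "n_folds")
})

test_that("cv_evaluate runs the full pipeline reproducibly", {
  s <- synth_network(n = 24, m = 20, n_blocks = 2, seed = 5)
  r1 <- cv_evaluate(s$Y, "CV1", n_folds = 3, seed = 2,
                    disease_kernels = s$disease_kernels,
                    gene_kernels = s$gene_kernels,
                    knn_k = 4, n_iter = 4)
  expect_s3_class(r1, "cv_report")
  expect_true(all(r1$per_fold$auc >= 0 & r1$per_fold$auc <= 1))
  expect_true(all(r1$per_fold$aupr >= 0 & r1$per_fold$aupr <= 1))
  expect_equal(r1$mean_auc, mean(r1$per_fold$auc))
  expect_equal(r1$mean_aupr, mean(r1$per_fold$aupr))
  # kernel weights are reported per fold and live on the simplex
  w <- r1$weights[[1]]$disease
  expect_equal(sum(w), 1, tolerance = 1e-8)
  expect_named(w, c("SEM", "COS", "GIP"))

  r2 <- cv_evaluate(s$Y, "CV1", n_folds = 3, seed = 2,
                    disease_kernels = s$disease_kernels,
                    gene_kernels = s$gene_kernels,
                    knn_k = 4, n_iter = 4)
  expect_equal(r1$per_fold, r2$per_fold)

  # GIP-only run (no side kernels) also works, e.g. for benchmark networks
  r3 <- cv_evaluate(s$Y, "CV1", n_folds = 3, seed = 2, knn_k = 4, n_iter = 4)
  expect_named(r3$weights[[1]]$disease, "GIP")
  expect_equal(unname(r3$weights[[1]]$disease), 1)
})

test_that("grid search selects the highest mean AUPR row", {
  s <- synth_network(n = 20, m = 16, n_blocks = 2, seed = 9)
  grid <- data.frame(knn_k = c(2, 4), lambda_d = c(0.5, 1))
  gs <- grid_search(s$Y, grid, mode = "CV1", n_folds = 2, seed = 4,
                    disease_kernels = s$disease_kernels,
                    gene_kernels = s$gene_kernels, n_iter = 3)
  expect_equal(nrow(gs$table), 2)
  expect_equal(which.max(gs$table$mean_aupr),
               which(rownames(gs$table) == rownames(gs$best_params)))
  expect_equal(gs$best_report$mean_aupr, max(gs$table$mean_aupr))

  # size-1 grid returns that configuration
  gs1 <- grid_search(s$Y, data.frame(knn_k = 3), mode = "CV1", n_folds = 2,
                     seed = 4, disease_kernels = s$disease_kernels,
                     gene_kernels = s$gene_kernels, n_iter = 3)
  expect_equal(gs1$best_params$knn_k, 3)
  expect_error(grid_search(s$Y, data.frame()), "empty")
})

test_that("the default hyperparameter grid has the documented shape", {
  g <- default_param_grid()
  expect_length(g$knn_k, 10)
  expect_length(g$lambda_d, 11)
  expect_length(g$lambda_g, 11)
  expect_equal(g$beta, 1)
  expect_equal(range(g$n_iter), c(1, 15))
})
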