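#' Area under the ROC curve (Mann-Whitney form)
#'
#' The probability that a uniformly drawn positive outranks a uniformly
#' drawn negative, with ties receiving half credit; computed from the
#' rank-sum statistic.
#'
#' @param scores numeric prediction scores.
#' @param labels 0/1 labels; both classes must be present.
#' @return AUC in [0, 1].
#' @export
auc_score <- function(scores, labels) {
  check_labels(scores, labels)
  pos <- labels == 1
  P <- sum(pos)
  N <- sum(!pos)
  if (P == 0L || N == 0L) stop("AUC requires both classes")
  r <- rank(scores)  # average ranks -> half credit for ties
  (sum(r[pos]) - P * (P + 1) / 2) / (P * N)
}

#' Area under the precision-recall curve (average precision)
#'
#' Step-function PR area: scores are swept from high to low, equal
#' scores are processed as one threshold group, and the area is
#' \eqn{\sum_t (R_t - R_{t-1}) \, P_t} over thresholds t with precision
#' \eqn{P_t} and recall \eqn{R_t}. For untied scores this is the mean of
#' the precisions at each positive's rank. Invariant under strictly
#' monotone transformations of the scores.
#'
#' @inheritParams auc_score
#' @return AUPR in (0, 1].
#' @export
aupr_score <- function(scores, labels) {
  check_labels(scores, labels)
  P <- sum(labels == 1)
  if (P == 0L) stop("AUPR requires at least one positive")
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]
  l <- labels[o]
  grp <- cumsum(c(TRUE, s[-1L] != s[-length(s)]))
  tp <- cumsum(vapply(split(l, grp), sum, numeric(1)))
  nn <- cumsum(tabulate(grp))
  prec <- tp / nn
  rec <- tp / P
  sum(diff(c(0, rec)) * prec)
}

check_labels <- function(scores, labels) {
  if (length(scores) != length(labels)) stop("scores/labels length mismatch")
  if (!all(labels == 0 | labels == 1)) stop("labels must be 0/1")
  if (anyNA(scores)) stop("scores must not contain NA")
  invisible(NULL)
}

#' Cross-validation folds for bipartite link prediction
#'
#' Two protocols:
#' \describe{
#'   \item{CV1 (pair holdout)}{the observed 1-entries of Y are randomly
#'     partitioned into \code{n_folds} groups; each fold's training
#'     matrix zeroes its held-out 1s, and the fold is scored over those
#'     held-out positives plus \emph{all} zero cells of Y as ranking
#'     negatives.}
#'   \item{CV2 (disease holdout, cold start)}{the diseases (rows) are
#'     randomly partitioned; a fold's training matrix zeroes the held-out
#'     rows entirely and the fold is scored over every cell of those
#'     rows. A partition giving some fold no positive pair is redrawn.}
#' }
#' Folds are a deterministic function of \code{seed}; the caller's RNG
#' state is left untouched.
#'
#' @param Y binary association matrix.
#' @param mode \code{"CV1"} or \code{"CV2"}.
#' @param n_folds number of folds (default 10; CV2 requires
#'   \code{n_folds <= nrow(Y)}).
#' @param seed integer RNG seed.
#' @return object of class \code{cv_folds}: a list of folds, each with
#'   elements \code{train} (masked matrix), \code{test_idx} (linear cell
#'   indices), \code{test_labels}.
#' @export
cv_folds <- function(Y, mode = c("CV1", "CV2"), n_folds = 10, seed = 1) {
  mode <- match.arg(mode)
  validate_association(Y)
  if (n_folds < 2) stop("n_folds must be >= 2")
  n <- nrow(Y)
  if (mode == "CV2" && n_folds > n) {
    stop("CV2 requires n_folds <= number of diseases")
  }
  folds <- withr::with_seed(seed, {
    if (mode == "CV1") {
      ones <- which(Y == 1)
      zeros <- which(Y == 0)
      if (length(ones) < n_folds) stop("fewer positives than folds")
      perm <- sample(ones)
      fid <- rep_len(seq_len(n_folds), length(perm))
      lapply(seq_len(n_folds), function(f) {
        held <- perm[fid == f]
        train <- Y
        train[held] <- 0
        list(train = train,
             test_idx = c(held, zeros),
             test_labels = c(rep(1, length(held)), rep(0, length(zeros))))
      })
    } else {
      for (attempt in seq_len(100L)) {
        perm <- sample(n)
        fid <- rep_len(seq_len(n_folds), n)
        ok <- all(vapply(seq_len(n_folds), function(f) {
          sum(Y[perm[fid == f], , drop = FALSE]) > 0
        }, logical(1)))
        if (ok) break
      }
      if (!ok) stop("could not draw a CV2 partition with positives per fold")
      lapply(seq_len(n_folds), function(f) {
        rows <- perm[fid == f]
        train <- Y
        train[rows, ] <- 0
        idx <- as.vector(outer(rows, (seq_len(ncol(Y)) - 1L) * n, "+"))
        list(train = train, test_idx = idx, test_labels = Y[idx])
      })
    }
  })
  structure(list(folds = folds, mode = mode, n_folds = n_folds, seed = seed),
            class = "cv_folds")
}

# Per-fold kernel assembly: fixed side-information kernels plus kernels
# rebuilt from the fold's masked training matrix (GIP, ideal), then MKL.
fold_kernel <- function(Y_train, side, side_kernels, use_gip, gamma, mkl) {
  kl <- side_kernels
  if (use_gip) kl <- c(kl, list(GIP = gip_kernel(Y_train, side, gamma)))
  if (length(kl) == 0L) stop("no kernels available for side ", side)
  if (length(kl) == 1L) {
    w <- stats::setNames(1, names(kl))
    return(list(K = kl[[1L]], weights = w))
  }
  if (mkl == "cka") {
    sol <- cka_weights(kl, ideal_kernel(Y_train, side))
    list(K = combine_kernels(kl, sol$weights), weights = sol$weights)
  } else {
    k <- length(kl)
    w <- stats::setNames(rep(1 / k, k), names(kl))
    list(K = mean_combine(kl), weights = w)
  }
}

#' Cross-validated evaluation of DHRLS and its baselines
#'
#' Runs the full per-fold pipeline: mask the training matrix, rebuild
#' the GIP and ideal kernels from the masked matrix (leak-free, which
#' matters for cold-start CV2), solve the per-side kernel weights (CKA
#' or uniform), combine, fit, predict, and score the fold's test cells
#' (micro-averaged AUC and AUPR over all test cells).
#'
#' @param Y binary association matrix.
#' @param mode,n_folds,seed passed to \code{\link{cv_folds}} (ignored if
#'   \code{folds} is supplied).
#' @param disease_kernels,gene_kernels named lists of fixed
#'   side-information kernels (semantic, cosine, ...); these must not be
#'   derived from the held-out associations.
#' @param use_gip also build the per-fold GIP kernel on each side
#'   (default \code{TRUE}).
#' @param gamma_d,gamma_g GIP bandwidths (default 0.5).
#' @param mkl \code{"cka"} or \code{"mean"} kernel weighting.
#' @param method \code{"dhrls"} (hypergraph regularizer), \code{"dgrls"}
#'   (graph regularizer), \code{"ridge"} (no Laplacian), or
#'   \code{"laprls"} (single-side baseline averaged over sides).
#' @param lambda_d,lambda_g,beta,knn_k,n_iter solver hyperparameters;
#'   see \code{\link{dhrls}}.
#' @param folds optional precomputed \code{\link{cv_folds}}.
#' @return object of class \code{cv_report}: list with \code{per_fold}
#'   data frame (fold, auc, aupr), \code{mean_auc}, \code{mean_aupr},
#'   per-fold kernel \code{weights}, and the evaluated \code{params}.
#' @export
cv_evaluate <- function(Y, mode = c("CV1", "CV2"), n_folds = 10, seed = 1,
                        disease_kernels = list(), gene_kernels = list(),
                        use_gip = TRUE, gamma_d = 0.5, gamma_g = 0.5,
                        mkl = c("cka", "mean"),
                        method = c("dhrls", "dgrls", "ridge", "laprls"),
                        lambda_d = 1, lambda_g = 0.25, beta = 1,
                        knn_k = 10, n_iter = 10, folds = NULL) {
  mode <- match.arg(mode)
  mkl <- match.arg(mkl)
  method <- match.arg(method)
  if (is.null(folds)) folds <- cv_folds(Y, mode, n_folds, seed)
  if (!inherits(folds, "cv_folds")) stop("folds must come from cv_folds()")

  res <- lapply(seq_along(folds$folds), function(f) {
    fold <- folds$folds[[f]]
    Ytr <- fold$train
    kd <- fold_kernel(Ytr, "disease", disease_kernels, use_gip, gamma_d, mkl)
    kg <- fold_kernel(Ytr, "gene", gene_kernels, use_gip, gamma_g, mkl)
    F_ <- if (method == "laprls") {
      laprls_dual(Ytr, kd$K, kg$K, lambda_d, lambda_g)
    } else {
      reg <- switch(method, dhrls = "hypergraph", dgrls = "graph",
                    ridge = "none")
      ld <- if (method == "ridge") 0 else lambda_d
      lg <- if (method == "ridge") 0 else lambda_g
      fit <- dhrls(Ytr, kd$K, kg$K, lambda_d = ld, lambda_g = lg,
                   beta = beta, knn_k = knn_k, n_iter = n_iter,
                   regularizer = reg)
      predict(fit)
    }
    s <- F_[fold$test_idx]
    list(auc = auc_score(s, fold$test_labels),
         aupr = aupr_score(s, fold$test_labels),
         weights = list(disease = kd$weights, gene = kg$weights))
  })
  per_fold <- data.frame(
    fold = seq_along(res),
    auc = vapply(res, `[[`, numeric(1), "auc"),
    aupr = vapply(res, `[[`, numeric(1), "aupr")
  )
  structure(list(
    per_fold = per_fold,
    mean_auc = mean(per_fold$auc),
    mean_aupr = mean(per_fold$aupr),
    weights = lapply(res, `[[`, "weights"),
    params = list(mode = mode, n_folds = folds$n_folds, seed = folds$seed,
                  mkl = mkl, method = method, lambda_d = lambda_d,
                  lambda_g = lambda_g, beta = beta, knn_k = knn_k,
                  n_iter = n_iter, use_gip = use_gip)
  ), class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  p <- x$params
  cat(sprintf("%s %s (%d folds, seed %d, %s MKL): AUC %.4f, AUPR %.4f\n",
              toupper(p$method), p$mode, p$n_folds, p$seed, p$mkl,
              x$mean_auc, x$mean_aupr))
  print(x$per_fold, row.names = FALSE)
  invisible(x)
}

#' The default hyperparameter grid
#'
#' kNN neighbor counts 10, 20, ..., 100; \eqn{\lambda_d, \lambda_g \in
#' \{2^{-5}, ..., 2^0, ..., 2^5\}}; \eqn{\beta = 1}; iteration counts
#' 1..15.
#'
#' @return list with components \code{knn_k}, \code{lambda_d},
#'   \code{lambda_g}, \code{beta}, \code{n_iter}.
#' @export
default_param_grid <- function() {
  list(knn_k = seq(10, 100, by = 10),
       lambda_d = 2^(-5:5),
       lambda_g = 2^(-5:5),
       beta = 1,
       n_iter = 1:15)
}

#' Exhaustive grid search over solver hyperparameters
#'
#' Evaluates every row of \code{grid} with \code{\link{cv_evaluate}}
#' (sharing one fold split across configurations) and selects the row
#' with the highest mean AUPR; ties go to the earliest row.
#'
#' @param Y binary association matrix.
#' @param grid data frame whose columns are a subset of
#'   \code{knn_k}, \code{lambda_d}, \code{lambda_g}, \code{beta},
#'   \code{n_iter}; one evaluation per row.
#' @param ... further arguments passed to \code{\link{cv_evaluate}}
#'   (kernels, mode, seed, method, ...).
#' @return list with \code{best_params} (the selected grid row),
#'   \code{best_report}, and \code{table} (the grid with mean_auc and
#'   mean_aupr columns appended).
#' @export
grid_search <- function(Y, grid, ...) {
  grid <- as.data.frame(grid)
  if (nrow(grid) < 1L) stop("empty hyperparameter grid")
  fixed <- list(...)
  folds <- fixed$folds
  if (is.null(folds)) {
    folds <- cv_folds(Y,
                      mode = if (is.null(fixed$mode)) "CV1" else fixed$mode,
                      n_folds = if (is.null(fixed$n_folds)) 10 else fixed$n_folds,
                      seed = if (is.null(fixed$seed)) 1 else fixed$seed)
  }
  fixed$folds <- folds
  reports <- lapply(seq_len(nrow(grid)), function(i) {
    args <- c(list(Y = Y), fixed, as.list(grid[i, , drop = FALSE]))
    do.call(cv_evaluate, args)
  })
  tab <- cbind(grid,
               mean_auc = vapply(reports, `[[`, numeric(1), "mean_auc"),
               mean_aupr = vapply(reports, `[[`, numeric(1), "mean_aupr"))
  best <- which.max(tab$mean_aupr)
  list(best_params = grid[best, , drop = FALSE],
       best_report = reports[[best]],
       table = tab)
}
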