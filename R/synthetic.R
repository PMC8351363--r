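#' Generate a synthetic bipartite network with planted block structure
#'
#' Diseases and genes are assigned (evenly) to \code{n_blocks} matched
#' co-clusters; an association is drawn with probability
#' \code{density_in} when disease and gene share a block and
#' \code{density_out} otherwise, then each cell is flipped independently
#' with probability \code{flip_noise}. Side information mirrors what
#' real pipelines supply:
#' \itemize{
#'   \item per-side feature vectors (noisy block indicators), feeding
#'     \code{\link{cosine_kernel}};
#'   \item a disease DAG whose subtrees follow the blocks (one internal
#'     term per block under a common root), feeding
#'     \code{\link{semantic_kernel}};
#'   \item GIP kernels from the clean generated network (for
#'     cross-validation, rebuild GIP from each fold's training matrix
#'     instead).
#' }
#' All randomness flows from \code{seed}; the caller's RNG state is
#' untouched and the same seed reproduces the output bit-for-bit.
#'
#' @param n,m disease and gene counts (defaults 80/80).
#' @param n_blocks number of planted co-clusters (default 4).
#' @param density_in,density_out within/between-block association
#'   probabilities (defaults 0.85 / 0.05; requires
#'   \code{0 <= density_out < density_in <= 1}).
#' @param flip_noise label-flip probability in [0, 0.5) (default 0.02).
#' @param feature_dim side-feature dimension, >= \code{n_blocks}
#'   (default \code{n_blocks}); extra dimensions are pure noise.
#' @param feature_noise sd of Gaussian jitter on the block-indicator
#'   features (default 0.3).
#' @param seed integer RNG seed.
#' @return list with \code{Y}, block labels \code{blocks_d} /
#'   \code{blocks_g}, feature matrices \code{features_d} /
#'   \code{features_g}, the disease \code{dag}, leak-free side kernel
#'   lists \code{disease_kernels} (SEM, COS) and \code{gene_kernels}
#'   (COS), and full-network GIP kernels \code{gip_d}, \code{gip_g}.
#' @export
synth_network <- function(n = 80, m = 80, n_blocks = 4,
                          density_in = 0.85, density_out = 0.05,
                          flip_noise = 0.02, feature_dim = n_blocks,
                          feature_noise = 0.3, seed = 1) {
  if (!(density_out >= 0 && density_out < density_in && density_in <= 1)) {
    stop("need 0 <= density_out < density_in <= 1")
  }
  if (flip_noise < 0 || flip_noise >= 0.5) stop("flip_noise must be in [0, 0.5)")
  if (n_blocks < 1 || n_blocks > min(n, m)) stop("invalid n_blocks")
  if (feature_dim < n_blocks) stop("feature_dim must be >= n_blocks")

  withr::with_seed(seed, {
    blocks_d <- sort(rep_len(seq_len(n_blocks), n))
    blocks_g <- sort(rep_len(seq_len(n_blocks), m))
    prob <- ifelse(outer(blocks_d, blocks_g, "=="), density_in, density_out)
    Y <- matrix(stats::rbinom(n * m, 1, prob), n, m)
    if (flip_noise > 0) {
      flip <- matrix(stats::rbinom(n * m, 1, flip_noise), n, m)
      Y <- abs(Y - flip)
    }
    disease_ids <- sprintf("d%03d", seq_len(n))
    gene_ids <- sprintf("g%03d", seq_len(m))
    dimnames(Y) <- list(disease_ids, gene_ids)

    block_features <- function(blocks, k) {
      X <- diag(n_blocks)[blocks, , drop = FALSE]
      if (feature_dim > n_blocks) {
        X <- cbind(X, matrix(0, k, feature_dim - n_blocks))
      }
      X + matrix(stats::rnorm(k * feature_dim, sd = feature_noise),
                 k, feature_dim)
    }
    features_d <- block_features(blocks_d, n)
    features_g <- block_features(blocks_g, m)
    rownames(features_d) <- disease_ids
    rownames(features_g) <- gene_ids

    block_terms <- sprintf("blk%d", seq_len(n_blocks))
    dag <- disease_dag(
      nodes = c("root", block_terms, disease_ids),
      parent_edges = data.frame(
        child = c(block_terms, disease_ids),
        parent = c(rep("root", n_blocks), block_terms[blocks_d])
      )
    )

    list(
      Y = Y,
      blocks_d = blocks_d, blocks_g = blocks_g,
      features_d = features_d, features_g = features_g,
      dag = dag,
      disease_kernels = list(
        SEM = semantic_kernel(dag, disease_ids),
        COS = cosine_kernel(features_d)
      ),
      gene_kernels = list(COS = cosine_kernel(features_g)),
      gip_d = gip_kernel(Y, "disease"),
      gip_g = gip_kernel(Y, "gene"),
      seed = seed
    )
  })
}

#' Published benchmark bipartite network sizes
#'
#' Node and edge counts of six commonly used real-world bipartite
#' networks: drug-target style biological networks (GPC receptors,
#' enzymes, ion channels, drug-target), the Southern Women social
#' network (SW), and a country-organization affiliation network (CO).
#' Use \code{\link{network_stats_counts}} to derive link density and
#' average degrees.
#'
#' @return data frame with columns \code{network}, \code{n_left},
#'   \code{n_right}, \code{n_edges}.
#' @examples
#' b <- benchmark_networks()
#' network_stats_counts(b$n_left[5], b$n_right[5], b$n_edges[5])
#' @export
benchmark_networks <- function() {
  data.frame(
    network = c("GPC", "Enzymes", "Ionchannel", "Drug-target", "SW", "CO"),
    n_left = c(95L, 664L, 210L, 200L, 18L, 144L),
    n_right = c(223L, 445L, 204L, 150L, 14L, 151L),
    n_edges = c(635L, 2926L, 1476L, 454L, 89L, 12170L),
    stringsAsFactors = FALSE
  )
}

#' Small worked-example fixtures
#'
#' A bundle of tiny instances with hand-derivable expected values, used
#' in the documentation and test suite:
#' \describe{
#'   \item{scalar}{the 1 x 1 instance Y = 1, K_d = K_g = 1, lambda = 0,
#'     beta = 1. Alternating updates follow alpha <- (2 - alpha) / 2,
#'     whose fixed point is alpha_d = alpha_g = 2/3 and prediction
#'     F* = 2/3.}
#'   \item{sibling_dag}{three terms: parent p with children a, b. With
#'     contribution factor 0.5, DV(a) = DV(b) = 1.5 and the shared
#'     ancestor contributes 1.0, so the semantic similarity of the
#'     siblings is 1/3.}
#'   \item{als_instance}{a reproducible 4 x 3 association matrix with
#'     PSD kernels on both sides, for checking the alternating solver
#'     against a joint least-squares solution.}
#'   \item{benchmark_sizes}{the \code{\link{benchmark_networks}} table.}
#' }
#'
#' @param seed seed for the random 4 x 3 instance.
#' @return named list of fixtures.
#' @export
worked_examples <- function(seed = 42) {
  als <- withr::with_seed(seed, {
    n <- 4L
    m <- 3L
    Y <- matrix(stats::rbinom(n * m, 1, 0.5), n, m)
    Y[1, 1] <- 1  # keep at least one association
    Ad <- matrix(stats::rnorm(n * n), n, n)
    Ag <- matrix(stats::rnorm(m * m), m, m)
    list(Y = ensure_ids(Y),
         K_d = crossprod(Ad) / n + diag(n),
         K_g = crossprod(Ag) / m + diag(m),
         beta = 1)
  })
  list(
    scalar = list(
      Y = ensure_ids(matrix(1, 1, 1)),
      K = matrix(1, 1, 1),
      beta = 1,
      expected_alpha = 2 / 3,
      expected_F = 2 / 3
    ),
    sibling_dag = list(
      dag = disease_dag(c("p", "a", "b"),
                        data.frame(child = c("a", "b"),
                                   parent = c("p", "p"))),
      delta = 0.5,
      expected_similarity = 1 / 3
    ),
    als_instance = als,
    benchmark_sizes = benchmark_networks()
  )
}
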