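#' Validate a binary bipartite association matrix
#'
#' The association matrix \code{Y} encodes a bipartite network: rows are
#' left-side entities (diseases), columns are right-side entities (genes),
#' and \code{Y[i, j] == 1} iff disease i is associated with gene j.
#'
#' @param Y numeric matrix with entries in \{0, 1\} and unique dimnames.
#' @return \code{Y}, invisibly, after validation.
#' @keywords internal
validate_association <- function(Y) {
  if (!is.matrix(Y) || !is.numeric(Y)) {
    stop("association matrix must be a numeric matrix")
  }
  if (nrow(Y) < 1L || ncol(Y) < 1L) {
    stop("association matrix must be non-empty")
  }
  if (!all(Y == 0 | Y == 1)) {
    stop("association matrix entries must be exactly 0 or 1")
  }
  rn <- rownames(Y)
  cn <- colnames(Y)
  if (!is.null(rn) && anyDuplicated(rn)) stop("duplicated row (disease) ids")
  if (!is.null(cn) && anyDuplicated(cn)) stop("duplicated column (gene) ids")
  invisible(Y)
}

# Attach default ids where a matrix arrives without dimnames.
ensure_ids <- function(Y, row_prefix = "d", col_prefix = "g") {
  if (is.null(rownames(Y))) rownames(Y) <- paste0(row_prefix, seq_len(nrow(Y)))
  if (is.null(colnames(Y))) colnames(Y) <- paste0(col_prefix, seq_len(ncol(Y)))
  Y
}

detect_sep <- function(line) if (grepl("\t", line, fixed = TRUE)) "\t" else ","

#' Read a bipartite association matrix from a text file
#'
#' Two dialects are supported. An \emph{edge list} has one association per
#' line: \code{disease<TAB>gene} with an optional third 0/1 column; absent
#' pairs are 0 and duplicate edges collapse to a single 1. A \emph{dense}
#' table has a header row of gene ids and a first column of disease ids,
#' with 0/1 cells. The separator (tab or comma) is auto-detected, and lines
#' starting with \code{#} are ignored.
#'
#' With \code{format = "auto"}, files whose rows carry more than three
#' fields are read as dense tables, otherwise as edge lists; three-column
#' dense tables (two genes) must be requested explicitly.
#'
#' @param path path to a TSV/CSV file.
#' @param format one of \code{"auto"}, \code{"edgelist"}, \code{"dense"}.
#' @return a binary association matrix with disease row ids and gene
#'   column ids.
#' @examples
#' f <- tempfile()
#' writeLines(c("d1\tg1", "d1\tg2", "d2\tg2"), f)
#' read_associations(f)
#' @export
read_associations <- function(path, format = c("auto", "edgelist", "dense")) {
  format <- match.arg(format)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines)]
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty association input: ", path)
  sep <- detect_sep(lines[[1L]])
  fields <- strsplit(lines, sep, fixed = TRUE)
  if (format == "auto") {
    format <- if (max(lengths(fields)) > 3L) "dense" else "edgelist"
  }
  if (format == "edgelist") {
    nf <- lengths(fields)
    if (any(nf < 2L | nf > 3L)) {
      stop("edge list lines must have 2 or 3 fields")
    }
    d <- vapply(fields, function(x) trimws(x[[1L]]), character(1))
    g <- vapply(fields, function(x) trimws(x[[2L]]), character(1))
    val <- rep(1, length(d))
    has3 <- nf == 3L
    if (any(has3)) {
      v <- suppressWarnings(as.numeric(vapply(fields[has3],
                                              function(x) x[[3L]], character(1))))
      if (anyNA(v) || !all(v %in% c(0, 1))) {
        stop("third edge-list column must be 0 or 1")
      }
      val[has3] <- v
    }
    row_ids <- unique(d)
    col_ids <- unique(g)
    Y <- matrix(0, length(row_ids), length(col_ids),
                dimnames = list(row_ids, col_ids))
    keep <- val == 1
    Y[cbind(match(d[keep], row_ids), match(g[keep], col_ids))] <- 1
  } else {
    tab <- utils::read.table(text = lines, header = TRUE, sep = sep,
                             row.names = 1, check.names = FALSE,
                             stringsAsFactors = FALSE)
    Y <- as.matrix(tab)
    storage.mode(Y) <- "double"
    if (anyNA(Y) || !all(Y == 0 | Y == 1)) {
      stop("dense association table must contain only 0/1 values")
    }
  }
  validate_association(Y)
  Y
}

#' Write a bipartite association matrix to a text file
#'
#' @param Y binary association matrix with dimnames.
#' @param path output path.
#' @param format \code{"dense"} (header ids, tab-separated) or
#'   \code{"edgelist"} (one \code{disease<TAB>gene} line per association).
#' @return \code{path}, invisibly.
#' @export
write_associations <- function(Y, path, format = c("dense", "edgelist")) {
  format <- match.arg(format)
  Y <- ensure_ids(Y)
  validate_association(Y)
  if (format == "dense") {
    utils::write.table(Y, path, sep = "\t", quote = FALSE,
                       col.names = NA, row.names = TRUE)
  } else {
    idx <- which(Y == 1, arr.ind = TRUE)
    df <- data.frame(disease_id = rownames(Y)[idx[, 1L]],
                     gene_id = colnames(Y)[idx[, 2L]])
    df <- df[order(df$disease_id, df$gene_id), , drop = FALSE]
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       col.names = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Descriptive statistics of a bipartite network
#'
#' Computes, for a network with \code{n_left} left nodes, \code{n_right}
#' right nodes and \code{n_edges} links: the link density
#' LD = E / (V * W), the average degree AD = E / (V + W), and the
#' per-side average degrees LAD = E / V and RAD = E / W.
#'
#' @param n_left,n_right,n_edges node and edge counts.
#' @return one-row data frame with columns \code{n_left}, \code{n_right},
#'   \code{n_edges}, \code{link_density}, \code{avg_degree},
#'   \code{left_avg_degree}, \code{right_avg_degree}.
#' @examples
#' network_stats_counts(18, 14, 89)
#' @export
network_stats_counts <- function(n_left, n_right, n_edges) {
  if (n_left < 1L || n_right < 1L) stop("network must have nodes on both sides")
  if (n_edges < 0L) stop("negative edge count")
  data.frame(
    n_left = n_left,
    n_right = n_right,
    n_edges = n_edges,
    link_density = n_edges / (n_left * n_right),
    avg_degree = n_edges / (n_left + n_right),
    left_avg_degree = n_edges / n_left,
    right_avg_degree = n_edges / n_right
  )
}

#' @rdname network_stats_counts
#' @param Y binary association matrix.
#' @export
network_stats <- function(Y) {
  validate_association(Y)
  network_stats_counts(nrow(Y), ncol(Y), sum(Y))
}

#' Write a prediction score matrix as a ranked long-format table
#'
#' Emits a three-column TSV (\code{disease_id}, \code{gene_id},
#' \code{score}) sorted by descending score; ties are broken
#' lexicographically by (disease id, gene id) so output is deterministic.
#'
#' @param F numeric score matrix with the same dimnames as the association
#'   matrix it was predicted for.
#' @param path output path.
#' @return the written data frame, invisibly.
#' @export
write_predictions <- function(F, path) {
  if (!is.matrix(F) || !is.numeric(F)) stop("F must be a numeric matrix")
  F <- ensure_ids(F)
  df <- data.frame(
    disease_id = rep(rownames(F), times = ncol(F)),
    gene_id = rep(colnames(F), each = nrow(F)),
    score = as.vector(F),
    stringsAsFactors = FALSE
  )
  df <- df[order(-df$score, df$disease_id, df$gene_id), , drop = FALSE]
  rownames(df) <- NULL
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}

#' Read/write a square kernel (similarity) matrix
#'
#' Dense TSV/CSV with a header row and first column of entity ids.
#' On read the matrix is checked to be square and symmetric (tolerance
#' \code{1e-10} relative to its largest entry) with finite, nonnegative
#' diagonal.
#'
#' @param path file path.
#' @return numeric kernel matrix with entity ids as dimnames.
#' @export
read_kernel_matrix <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty kernel input: ", path)
  sep <- detect_sep(lines[[1L]])
  tab <- utils::read.table(text = lines, header = TRUE, sep = sep,
                           row.names = 1, check.names = FALSE)
  K <- as.matrix(tab)
  storage.mode(K) <- "double"
  validate_kernel(K)
  K
}

#' @rdname read_kernel_matrix
#' @param K kernel matrix with dimnames.
#' @export
write_kernel_matrix <- function(K, path) {
  validate_kernel(K)
  utils::write.table(K, path, sep = "\t", quote = FALSE,
                     col.names = NA, row.names = TRUE)
  invisible(path)
}

#' @keywords internal
validate_kernel <- function(K, tol = 1e-10) {
  if (!is.matrix(K) || !is.numeric(K)) stop("kernel must be a numeric matrix")
  if (nrow(K) != ncol(K)) stop("kernel matrix must be square")
  if (anyNA(K) || any(!is.finite(K))) stop("kernel entries must be finite")
  scale <- max(1, max(abs(K)))
  if (max(abs(K - t(K))) > tol * scale) stop("kernel matrix must be symmetric")
  if (any(diag(K) < 0)) stop("kernel diagonal must be nonnegative")
  invisible(K)
}
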