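#' Gaussian similarity kernel between patients
#'
#' Computes the pairwise similarity matrix
#' \deqn{X_{ij} = \exp(-\lVert S_i - S_j \rVert^2 / 2)}
#' over the rows of a feature matrix. The result is symmetric with unit
#' diagonal and entries in (0, 1]. Because the squared Euclidean norm is
#' scale-sensitive, features should normally be standardized first (see
#' [split_train_test()]).
#'
#' @param features n x d numeric matrix (rows = patients).
#' @return n x n similarity matrix of class `kernel_matrix`.
#' @export
compute_kernel <- function(features) {
  features <- as.matrix(features)
  if (any(!is.finite(features)))
    stop("features must be finite to compute similarities")
  sq <- rowSums(features^2)
  d2 <- outer(sq, sq, "+") - 2 * tcrossprod(features)
  d2[d2 < 0] <- 0 # numerical negatives from cancellation
  X <- exp(-d2 / 2)
  X <- (X + t(X)) / 2
  diag(X) <- 1
  class(X) <- c("kernel_matrix", class(X))
  X
}

#' Symmetric normalization of a binary adjacency matrix
#'
#' Adds self-loops and applies the symmetric degree normalization
#' \deqn{\hat{A} = \tilde{D}^{-1/2} (A + I) \tilde{D}^{-1/2},}
#' where \eqn{\tilde{D}} is the diagonal degree matrix of \eqn{A + I}. This is
#' the propagation operator used by every GCN layer.
#'
#' @param A Symmetric binary adjacency matrix (zero diagonal); dense or
#'   `Matrix` sparse.
#' @return A sparse symmetric `dgCMatrix` with nonnegative entries and
#'   spectral radius at most 1.
#' @export
normalize_adjacency <- function(A) {
  A <- methods::as(methods::as(Matrix::Matrix(A, sparse = TRUE),
                               "generalMatrix"), "CsparseMatrix")
  if (nrow(A) != ncol(A)) stop("adjacency must be square")
  if (!Matrix::isSymmetric(A)) stop("adjacency must be symmetric")
  if (any(Matrix::diag(A) != 0)) stop("adjacency must have a zero diagonal")
  A_tilde <- A + Matrix::Diagonal(nrow(A))
  d_inv_sqrt <- 1 / sqrt(Matrix::rowSums(A_tilde))
  A_hat <- Matrix::Diagonal(x = d_inv_sqrt) %*% A_tilde %*%
    Matrix::Diagonal(x = d_inv_sqrt)
  methods::as(A_hat, "CsparseMatrix")
}

#' Build the undirected top-k patient similarity graph
#'
#' For every patient the `k` most similar other patients (largest kernel
#' values, ties broken toward the smaller patient index) are nominated as
#' neighbours; the edge set is the symmetric union of the nominations, so each
#' node ends with degree at least `k` or more. The normalized propagation
#' operator (see [normalize_adjacency()]) is computed alongside.
#'
#' @param X Similarity matrix from [compute_kernel()] (any symmetric matrix
#'   works).
#' @param k Neighbours nominated per patient, `1 <= k <= n - 1`.
#' @return An object of class `similarity_graph`: list with sparse binary
#'   adjacency `A`, normalized operator `A_hat`, neighbour count `k`, and
#'   `degree` (per node, self-loop excluded).
#' @export
build_topk_graph <- function(X, k = 10L) {
  X <- unclass(as.matrix(X))
  n <- nrow(X)
  if (k < 1L || k >= n)
    stop("k must satisfy 1 <= k <= n - 1 (n = ", n, ")")
  k <- as.integer(k)
  ei <- integer(n * k); ej <- integer(n * k)
  for (i in seq_len(n)) {
    sim <- X[i, ]
    sim[i] <- -Inf
    # order(): descending similarity, ascending index on ties
    nb <- order(-sim, seq_len(n))[seq_len(k)]
    ei[((i - 1L) * k + 1L):(i * k)] <- i
    ej[((i - 1L) * k + 1L):(i * k)] <- nb
  }
  A <- Matrix::sparseMatrix(i = c(ei, ej), j = c(ej, ei), x = 1,
                            dims = c(n, n), use.last.ij = TRUE)
  A@x[] <- 1 # union of nominations: binary edges
  A <- methods::as(A, "CsparseMatrix")
  structure(list(
    A = A,
    A_hat = normalize_adjacency(A),
    k = k,
    degree = Matrix::rowSums(A)
  ), class = "similarity_graph")
}

#' @export
print.similarity_graph <- function(x, ...) {
  n <- nrow(x$A)
  cat(sprintf("similarity_graph: %d nodes, k = %d, %d undirected edges, degree %d-%d\n",
              n, x$k, as.integer(Matrix::nnzero(x$A) / 2),
              as.integer(min(x$degree)), as.integer(max(x$degree))))
  invisible(x)
}

#' Write a similarity graph as an edge list
#'
#' Emits a TSV with columns `patient_id_a`, `patient_id_b`, `similarity`
#' (one row per undirected edge, a < b by index).
#'
#' @param graph A [build_topk_graph()] result.
#' @param X The kernel matrix the graph was built from.
#' @param patient_ids Node identifiers.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(graph, X, patient_ids, path) {
  tri <- Matrix::which(Matrix::triu(graph$A, 1) != 0, arr.ind = TRUE)
  df <- data.frame(patient_id_a = patient_ids[tri[, 1]],
                   patient_id_b = patient_ids[tri[, 2]],
                   similarity = as.matrix(X)[tri])
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
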