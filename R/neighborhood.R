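# k-nearest-neighbor graphs over a similarity matrix and the graph
# Laplacians that express the neighborhood-smoothness penalty
#   sum_{i,mu} a_{i,mu} ||u_i - u_mu||^2  =  tr(U' L U),
#   L = (D + Dt) - (A + A'),  D_ii = sum_mu a_{i,mu},  Dt_mm = sum_i a_{i,mu}.
# A keeps only each row's top-K similarities, so it is not symmetric in
# general; the Laplacian symmetrizes it.

#' Per-row k-nearest-neighbor index lists
#'
#' For each row `i` of a square similarity matrix, the `min(K, m - 1)`
#' indices `mu != i` with the largest similarity `s[i, mu]`. Ties are broken
#' by ascending index so graphs are deterministic; zero similarities are
#' eligible neighbors (they contribute nothing to the penalty but keep the
#' neighborhood size constant).
#'
#' @param S square numeric similarity matrix (rows are read as is; no
#'   symmetrization is applied).
#' @param K nonnegative integer neighborhood size.
#' @return list of integer vectors, one per row, each sorted by descending
#'   similarity (ties ascending index).
#' @export
knn_indices <- function(S, K) {
  S <- as.matrix(S)
  m <- nrow(S)
  if (m != ncol(S)) stop_validation("similarity matrix must be square, got %d x %d", m, ncol(S))
  if (length(K) != 1 || is.na(K) || K < 0 || K != round(K)) {
    stop_validation("K must be a single nonnegative integer")
  }
  k_eff <- min(K, m - 1L)
  lapply(seq_len(m), function(i) {
    cand <- setdiff(seq_len(m), i)
    if (k_eff == 0L) return(integer(0))
    ord <- cand[order(-S[i, cand], cand)]
    ord[seq_len(k_eff)]
  })
}

#' Build a k-nearest-neighbor adjacency matrix
#'
#' Sparse-in-spirit adjacency with `a[i, mu] = s[i, mu]` when `mu` is among
#' the `K1` nearest neighbors of `i` and 0 otherwise. The diagonal is zero
#' (self is never a neighbor) and the matrix need not be symmetric.
#'
#' @param S square similarity matrix.
#' @param K1 neighborhood size used during training regularization.
#' @return an object of class `neighbor_graph` with fields `A` (the
#'   adjacency matrix), `K1` and `neighbor_sets`.
#' @export
build_adjacency <- function(S, K1) {
  S <- as.matrix(S)
  nbrs <- knn_indices(S, K1)
  m <- nrow(S)
  A <- matrix(0, m, m, dimnames = dimnames(S))
  for (i in seq_len(m)) {
    A[i, nbrs[[i]]] <- S[i, nbrs[[i]]]
  }
  structure(list(A = A, K1 = K1, neighbor_sets = nbrs), class = "neighbor_graph")
}

#' Graph Laplacian of a k-nearest-neighbor adjacency
#'
#' `L = (D + Dt) - (A + A')` where `D` holds row sums and `Dt` column sums
#' of the (possibly asymmetric) adjacency. `L` is symmetric, annihilates
#' constant vectors and is positive semidefinite, and satisfies
#' `tr(U' L U) = sum_{i,mu} a[i,mu] ||u_i - u_mu||^2`.
#'
#' @param graph a `neighbor_graph` from [build_adjacency()], or a plain
#'   square adjacency matrix.
#' @return an object of class `laplacian_pair` with fields `L`,
#'   `row_degree`, `col_degree`.
#' @export
build_laplacian <- function(graph) {
  A <- if (inherits(graph, "neighbor_graph")) graph$A else as.matrix(graph)
  if (nrow(A) != ncol(A)) stop_validation("adjacency must be square")
  d_row <- rowSums(A)
  d_col <- colSums(A)
  L <- diag(d_row + d_col, nrow = nrow(A)) - (A + t(A))
  dimnames(L) <- dimnames(A)
  structure(list(L = L, row_degree = d_row, col_degree = d_col),
            class = "laplacian_pair")
}
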