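# Heat-kernel k-nearest-neighbour affinity over final-layer dictionary
# atoms, its graph Laplacian, and the neighbourhood-smoothness penalty
# Tr(B' L B) that couples similar atoms' code usage.

#' Build the k-NN heat-kernel affinity graph over dictionary atoms
#'
#' Edges connect each atom to its `k` nearest neighbours by Euclidean
#' distance (self excluded); the directed k-NN mask is symmetrised by OR, so
#' an edge exists if either endpoint selects the other. Edge weights are
#' `exp(-||d_i - d_j||^2 / sigma)`. With `sigma = "auto"` the bandwidth is
#' the median of squared k-NN distances (floored at 1e-12).
#'
#' @param D dictionary whose columns are the final-layer atoms (K >= 2).
#' @param k neighbour count, `1 <= k < K`.
#' @param sigma positive bandwidth, or `"auto"` for the median heuristic.
#' @return an object of class `dd_atom_graph` with elements `E` (symmetric
#'   K x K affinity, zero diagonal), `k`, `sigma`.
#' @export
build_atom_graph <- function(D, k = 5L, sigma = "auto") {
  D <- as.matrix(D)
  K <- ncol(D)
  if (K < 2L) abort("at least 2 atoms are required to build a graph")
  k <- as.integer(k)
  if (k < 1L || k >= K) abort("`k` must satisfy 1 <= k < K")
  sq <- colSums(D^2)
  d2 <- outer(sq, sq, "+") - 2 * crossprod(D)
  d2[d2 < 0] <- 0
  diag(d2) <- Inf
  # directed mask: row i, col j TRUE iff atom i is one of the k nearest of j
  mask <- matrix(FALSE, K, K)
  for (j in seq_len(K)) {
    nn <- order(d2[, j], seq_len(K))[seq_len(k)] # ties toward lower index
    mask[nn, j] <- TRUE
  }
  mask <- mask | t(mask)
  if (identical(sigma, "auto")) {
    sigma <- max(median(d2[mask]), 1e-12)
  }
  if (!is.numeric(sigma) || sigma <= 0) abort("`sigma` must be positive or 'auto'")
  E <- exp(-d2 / sigma) * mask
  diag(E) <- 0
  structure(list(E = E, k = k, sigma = sigma), class = "dd_atom_graph")
}

#' Graph Laplacian of an atom graph
#'
#' `L = diag(row sums of E) - E`; symmetric, rows summing to zero, positive
#' semidefinite for the symmetric non-negative affinities produced by
#' [build_atom_graph()].
#'
#' @param g a `dd_atom_graph`, or a symmetric affinity matrix.
#' @return the K x K Laplacian matrix.
#' @export
graph_laplacian <- function(g) {
  E <- if (inherits(g, "dd_atom_graph")) g$E else as.matrix(g)
  if (max(abs(E - t(E))) > 1e-9) abort("affinity matrix must be symmetric")
  diag(rowSums(E)) - E
}

#' Neighbourhood-smoothness penalty on final-layer codes
#'
#' `Tr(B' L B)`, which for a symmetric affinity equals
#' `0.5 * sum_ij E_ij ||row_i(B) - row_j(B)||^2`: atoms joined in the graph
#' are pushed toward similar usage patterns across samples.
#'
#' @param B code matrix, K_M rows.
#' @param L Laplacian from [graph_laplacian()].
#' @return non-negative scalar.
#' @export
graph_penalty <- function(B, L) {
  B <- as.matrix(B)
  if (nrow(B) != nrow(L)) abort("nrow(B) must match the Laplacian dimension")
  sum(B * (L %*% B))
}

#' Gradient of the smoothness penalty
#'
#' `2 L B` (valid for symmetric `L`).
#'
#' @inheritParams graph_penalty
#' @return matrix with the shape of `B`.
#' @export
graph_penalty_grad <- function(B, L) {
  B <- as.matrix(B)
  if (nrow(B) != nrow(L)) abort("nrow(B) must match the Laplacian dimension")
  2 * (L %*% B)
}
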