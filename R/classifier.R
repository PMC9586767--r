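# Softmax head over final-layer codes plus the label-consistency term
# B ~ S H pulling each code toward a learned per-class prototype.

#' Softmax class probabilities for a code vector or code matrix
#'
#' `g_c = exp(theta_c' b) / sum_u exp(theta_u' b)` computed in the max-shifted
#' numerically stable form.
#'
#' @param theta C x K_M parameter matrix (one row per class).
#' @param b length-K_M code vector, or K_M x N code matrix.
#' @return length-C probability vector, or C x N matrix with unit column sums.
#' @export
softmax_prob <- function(theta, b) {
  theta <- as.matrix(theta)
  B <- as.matrix(b)
  if (nrow(B) != ncol(theta)) abort("code length must equal ncol(theta)")
  logits <- theta %*% B
  m <- apply(logits, 2, max)
  ex <- exp(sweep(logits, 2, m))
  G <- sweep(ex, 2, colSums(ex), "/")
  if (is.null(dim(b)) || ncol(B) == 1L) as.numeric(G) else G
}

#' Mean softmax cross-entropy over samples
#'
#' @param theta C x K_M parameters.
#' @param B codes K_M x N.
#' @param H one-hot C x N label matrix (see [label_matrix()]).
#' @return scalar mean negative log-likelihood.
#' @export
softmax_loss <- function(theta, B, H) {
  B <- as.matrix(B); H <- as.matrix(H)
  if (ncol(B) != ncol(H)) abort("B and H must have the same number of columns")
  logits <- theta %*% B
  m <- apply(logits, 2, max)
  lse <- m + log(colSums(exp(sweep(logits, 2, m))))
  -mean(colSums(H * logits) - lse)
}

#' Gradient of the softmax loss
#'
#' `d/dtheta = (1/N) (G - H) B'` and `d/dB = (1/N) theta' (G - H)` where `G`
#' holds the predicted probabilities.
#'
#' @inheritParams softmax_loss
#' @return list with `dtheta` and `dB`.
#' @export
softmax_grad <- function(theta, B, H) {
  B <- as.matrix(B); H <- as.matrix(H)
  N <- ncol(B)
  G <- softmax_prob(theta, B)
  G <- matrix(G, nrow = nrow(as.matrix(theta)))
  R <- (G - H) / N
  list(dtheta = R %*% t(B), dB = crossprod(as.matrix(theta), R))
}

#' Label-consistency penalty and gradients
#'
#' `lambda_lc * ||B - S H||_F^2`, pulling every sample's code toward its
#' class's prototype column of `S`.
#'
#' @param B codes K_M x N.
#' @param S prototype matrix K_M x C.
#' @param H one-hot C x N labels.
#' @param lambda_lc non-negative weight.
#' @return list with `loss`, `dB` and `dS`.
#' @export
label_consistency_loss <- function(B, S, H, lambda_lc) {
  B <- as.matrix(B); S <- as.matrix(S); H <- as.matrix(H)
  if (lambda_lc == 0) {
    zero <- array(0, dim = dim(B))
    return(list(loss = 0, dB = zero, dS = array(0, dim = dim(S))))
  }
  Rm <- B - S %*% H
  list(loss = lambda_lc * frob2(Rm),
       dB = 2 * lambda_lc * Rm,
       dS = -2 * lambda_lc * Rm %*% t(H))
}

#' Closed-form prototype update
#'
#' Minimises `||B - S H||_F^2` in `S`: each present class's prototype becomes
#' the mean code of its samples (`S = B H' (H H')^{-1}`). Columns of absent
#' classes are left at their previous value.
#'
#' @param B codes K_M x N.
#' @param H one-hot C x N labels.
#' @param S_old previous prototypes (kept for absent classes); defaults to
#'   zeros.
#' @return updated K_M x C prototype matrix.
#' @export
update_prototypes <- function(B, H, S_old = NULL) {
  B <- as.matrix(B); H <- as.matrix(H)
  C <- nrow(H)
  S <- if (is.null(S_old)) matrix(0, nrow(B), C) else as.matrix(S_old)
  counts <- rowSums(H)
  BHt <- B %*% t(H)
  for (cc in which(counts > 0)) S[, cc] <- BHt[, cc] / counts[cc]
  S
}
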