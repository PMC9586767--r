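# The multilayer dictionary model Z ~ D1 f(D2 f(... DM B_M)), with the
# activation f applied strictly BETWEEN dictionary applications, plus its
# reconstruction loss and chain-rule gradients.

#' Apply an elementwise activation
#'
#' @param kind one of `"relu"`, `"sigmoid"`, `"tanh"`, `"identity"`.
#' @param X numeric array.
#' @return array of the same shape. `activation_deriv` returns the
#'   elementwise derivative, with `relu`'s derivative at 0 defined as 0.
#' @export
activation_apply <- function(kind, X) {
  switch(kind,
    relu = pmax(X, 0),
    sigmoid = 1 / (1 + exp(-X)),
    tanh = tanh(X),
    identity = X,
    abort(sprintf("unknown activation '%s'", kind))
  )
}

#' @rdname activation_apply
#' @export
activation_deriv <- function(kind, X) {
  switch(kind,
    relu = (X > 0) * 1,
    sigmoid = {
      s <- 1 / (1 + exp(-X))
      s * (1 - s)
    },
    tanh = 1 - tanh(X)^2,
    identity = X * 0 + 1,
    abort(sprintf("unknown activation '%s'", kind))
  )
}

#' Construct a dictionary layer stack
#'
#' @param dictionaries list of matrices D_1 ... D_M; `ncol(D_m)` must equal
#'   `nrow(D_{m+1})` and every column must satisfy the unit-ball atom norm.
#' @param activation activation applied between layers (never after the last
#'   multiply), default `"relu"`.
#' @return an object of class `dd_stack`.
#' @export
layer_stack <- function(dictionaries, activation = "relu") {
  if (!length(dictionaries)) abort("at least one dictionary required")
  dictionaries <- lapply(dictionaries, as.matrix)
  for (m in seq_along(dictionaries)) {
    D <- dictionaries[[m]]
    check_finite(D, sprintf("dictionary %d", m))
    if (m > 1 && nrow(D) != ncol(dictionaries[[m - 1]])) {
      abort(sprintf("layer %d: nrow(D_%d)=%d does not chain with ncol(D_%d)=%d",
                    m, m, nrow(D), m - 1, ncol(dictionaries[[m - 1]])))
    }
    if (any(colSums(D^2) > 1 + 1e-9)) {
      abort(sprintf("layer %d violates the unit-ball atom norm", m))
    }
  }
  structure(list(dictionaries = dictionaries, activation = activation,
                 n_layers = length(dictionaries)),
            class = "dd_stack")
}

#' @export
print.dd_stack <- function(x, ...) {
  dims <- vapply(x$dictionaries, function(D) paste(dim(D), collapse = "x"), "")
  cat(sprintf("<dd_stack> %d layer(s), activation '%s'\n", x$n_layers, x$activation))
  cat("  ", paste(dims, collapse = " -> "), "\n")
  invisible(x)
}

#' Decode final-layer codes through the stack
#'
#' Computes `D1 f(D2 f(... f(DM B)))`. For a single layer this is simply
#' `D1 B`: the activation sits strictly between dictionary applications.
#'
#' @param stack a `dd_stack`.
#' @param B final-layer code matrix (K_M rows) or vector.
#' @return reconstructed feature matrix, `nrow(D1)` rows.
#' @export
decode_stack <- function(stack, B) {
  B <- as.matrix(B)
  M <- stack$n_layers
  if (nrow(B) != ncol(stack$dictionaries[[M]])) {
    abort(sprintf("layer %d: B has %d rows, expected %d",
                  M, nrow(B), ncol(stack$dictionaries[[M]])))
  }
  X <- stack$dictionaries[[M]] %*% B
  for (m in rev(seq_len(M - 1))) {
    X <- stack$dictionaries[[m]] %*% activation_apply(stack$activation, X)
  }
  X
}

#' Multilayer reconstruction loss
#'
#' `||Z - decode(stack, B)||_F^2 + lambda1 * ||B||_1` — the data-fidelity
#' term plus the l1 code penalty used during joint training.
#'
#' @param stack a `dd_stack`.
#' @param B final-layer codes.
#' @param Z observed feature matrix.
#' @param lambda1 l1 weight on `B` (0 for pure fidelity).
#' @return scalar loss.
#' @export
reconstruction_loss <- function(stack, B, Z, lambda1 = 0) {
  frob2(Z - decode_stack(stack, B)) + lambda1 * sum(abs(B))
}

#' Gradients of the reconstruction fidelity through the stack
#'
#' Backpropagates the residual `-2 (Z - Zhat)` through the alternating linear
#' maps and elementwise activation derivatives, returning the gradient of
#' `||Z - decode(stack, B)||_F^2` with respect to every dictionary and to the
#' final-layer codes.
#'
#' @param stack a `dd_stack`.
#' @param B final-layer codes, K_M x N.
#' @param Z observed features, c x N.
#' @return list with `dD` (list of per-layer gradient matrices) and `dB`.
#' @export
grad_stack <- function(stack, B, Z) {
  B <- as.matrix(B); Z <- as.matrix(Z)
  M <- stack$n_layers
  Ds <- stack$dictionaries
  act <- stack$activation
  # forward pass: A[[m]] = D_m %*% X_{m+1}, X_m = f(A[[m]]) for m >= 2
  A <- vector("list", M)
  X <- vector("list", M + 1L) # X[[m+1]] feeds layer m; X[[M+1]] = B
  X[[M + 1L]] <- B
  for (m in rev(seq_len(M))) {
    A[[m]] <- Ds[[m]] %*% X[[m + 1L]]
    X[[m]] <- if (m > 1) activation_apply(act, A[[m]]) else A[[m]]
  }
  R <- -2 * (Z - A[[1L]])
  dD <- vector("list", M)
  G <- R
  for (m in seq_len(M)) {
    Gpre <- if (m == 1L) G else G * activation_deriv(act, A[[m]])
    dD[[m]] <- Gpre %*% t(X[[m + 1L]])
    G <- crossprod(Ds[[m]], Gpre)
  }
  list(dD = dD, dB = G)
}
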