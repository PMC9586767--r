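#' @keywords internal
"_PACKAGE"

#' @importFrom rlang abort warn %||%
#' @importFrom stats rnorm runif sd median setNames
#' @importFrom utils packageVersion head tail
NULL

# Evaluate `code` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is untouched.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(code)
}

soft_threshold <- function(x, t) {
  sign(x) * pmax(abs(x) - t, 0)
}

frob2 <- function(X) sum(X * X)

# Largest singular value of A via power iteration on t(A) %*% A.
spectral_norm <- function(A, max_iter = 100, tol = 1e-10) {
  G <- crossprod(A)
  n <- ncol(G)
  if (n == 0L) return(0)
  v <- rep(1 / sqrt(n), n)
  lam <- 0
  for (i in seq_len(max_iter)) {
    w <- G %*% v
    nw <- sqrt(sum(w * w))
    if (nw < 1e-300) return(0)
    v_new <- as.vector(w / nw)
    lam_new <- nw
    if (abs(lam_new - lam) < tol * max(1, lam_new)) {
      lam <- lam_new
      break
    }
    v <- v_new
    lam <- lam_new
  }
  sqrt(lam)
}

check_finite <- function(x, what) {
  if (!all(is.finite(x))) {
    abort(sprintf("`%s` must contain only finite values", what))
  }
  invisible(x)
}

# One-hot C x N label matrix from 0-based integer labels.
#' Build a one-hot label matrix
#'
#' Converts 0-based integer class labels into the C x N indicator matrix used
#' by the softmax head and the label-consistency term (column i carries a
#' single 1 in the row of sample i's class).
#'
#' @param labels integer vector of 0-based class labels.
#' @param n_classes number of classes C; defaults to `max(labels) + 1`.
#' @return a C x N matrix of 0/1 indicators.
#' @export
label_matrix <- function(labels, n_classes = NULL) {
  labels <- as.integer(labels)
  if (any(is.na(labels)) || any(labels < 0L)) {
    abort("`labels` must be non-negative integers (0-based class indices)")
  }
  C <- n_classes %||% (max(labels) + 1L)
  if (any(labels >= C)) abort("label outside 0..C-1")
  H <- matrix(0, C, length(labels))
  H[cbind(labels + 1L, seq_along(labels))] <- 1
  H
}
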