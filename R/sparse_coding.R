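# Single-layer dictionary-learning primitives: atom normalisation, greedy
# (OMP) and l1 (FISTA) sparse encoders, K-SVD sweeps, and the per-class
# K-SVD initialisation used for layer 1.

#' Project dictionary atoms onto the unit l2 ball
#'
#' Every dictionary atom (column) is constrained to `||d||_2^2 <= 1`. Columns
#' with norm greater than 1 are rescaled to unit norm; columns already inside
#' the ball, including all-zero columns, are left untouched.
#'
#' @param D numeric matrix, one atom per column.
#' @return matrix of the same shape with every column norm at most 1.
#' @export
normalize_atoms <- function(D) {
  D <- as.matrix(D)
  check_finite(D, "D")
  nrm <- sqrt(colSums(D^2))
  scale_by <- ifelse(nrm > 1, 1 / nrm, 1)
  D * rep(scale_by, each = nrow(D))
}

#' Greedy sparse coding by orthogonal matching pursuit
#'
#' Selects atoms one at a time by maximal absolute correlation with the
#' current residual (ties broken toward the lowest atom index), refitting all
#' selected coefficients by least squares after each selection. Stops after
#' `s` atoms or when the residual norm falls below 1e-12.
#'
#' @param D dictionary, p x K matrix.
#' @param z signal of length p.
#' @param s maximum number of nonzero coefficients; must satisfy
#'   `s <= min(p, K)`.
#' @return length-K coefficient vector with at most `s` nonzeros.
#' @export
encode_omp <- function(D, z, s) {
  D <- as.matrix(D)
  z <- as.numeric(z)
  p <- nrow(D)
  K <- ncol(D)
  if (length(z) != p) abort(sprintf("`z` has length %d but dictionary has %d rows", length(z), p))
  s <- as.integer(s)
  if (s < 1L || s > K || s > p) abort("`s` must satisfy 1 <= s <= min(p, K)")
  b <- numeric(K)
  support <- integer(0)
  r <- z
  for (step in seq_len(s)) {
    if (sqrt(sum(r^2)) < 1e-12) break
    corr <- abs(crossprod(D, r))
    corr[support] <- -Inf
    j <- which.max(corr) # which.max returns the first (lowest-index) maximum
    support <- c(support, j)
    Ds <- D[, support, drop = FALSE]
    coef <- qr.coef(qr(Ds), z)
    coef[is.na(coef)] <- 0
    r <- z - Ds %*% coef
  }
  if (length(support)) b[support] <- coef
  b
}

#' l1-penalised sparse coding by accelerated proximal gradient (FISTA)
#'
#' Solves `min_b 0.5 * ||z - D b||_2^2 + lambda1 * ||b||_1` with the step size
#' `1 / ||D'D||_2` (spectral norm via power iteration) and Nesterov momentum.
#' Iterates until the objective decrease drops below `tol` or `max_iter`
#' iterations; if the latter is hit first the result carries
#' `attr(, "converged") = FALSE` rather than raising an error.
#'
#' @param D dictionary, p x K matrix.
#' @param z signal of length p.
#' @param lambda1 non-negative l1 weight.
#' @param tol objective-decrease stopping tolerance.
#' @param max_iter iteration cap.
#' @param b0 optional warm start (length K).
#' @return length-K coefficient vector with attributes `converged` (logical)
#'   and `objective` (final objective value).
#' @export
encode_l1 <- function(D, z, lambda1, tol = 1e-10, max_iter = 2000L, b0 = NULL) {
  D <- as.matrix(D)
  z <- as.numeric(z)
  if (length(z) != nrow(D)) abort("`z` length must equal nrow(D)")
  if (lambda1 < 0) abort("`lambda1` must be >= 0")
  K <- ncol(D)
  L <- spectral_norm(D)^2
  if (L < 1e-300) {
    out <- numeric(K)
    attr(out, "converged") <- TRUE
    attr(out, "objective") <- 0.5 * sum(z^2)
    return(out)
  }
  step <- 1 / L
  obj <- function(b) 0.5 * sum((z - D %*% b)^2) + lambda1 * sum(abs(b))
  b <- if (is.null(b0)) numeric(K) else as.numeric(b0)
  y <- b
  tk <- 1
  f_prev <- obj(b)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    grad <- as.vector(crossprod(D, D %*% y - z))
    b_new <- soft_threshold(y - step * grad, step * lambda1)
    # Monotone (restarted) FISTA: fall back to the plain ISTA step if the
    # momentum step overshoots, so the objective trace is non-increasing.
    if (obj(b_new) > f_prev) {
      grad_b <- as.vector(crossprod(D, D %*% b - z))
      b_new <- soft_threshold(b - step * grad_b, step * lambda1)
      tk <- 1
    }
    t_new <- (1 + sqrt(1 + 4 * tk^2)) / 2
    y <- b_new + ((tk - 1) / t_new) * (b_new - b)
    b <- b_new
    tk <- t_new
    f_new <- obj(b)
    if (f_prev - f_new < tol && f_new <= f_prev + 1e-15) {
      converged <- TRUE
      f_prev <- f_new
      break
    }
    f_prev <- f_new
  }
  if (!converged) warn("encode_l1 reached max_iter without meeting `tol`")
  out <- as.numeric(b)
  attr(out, "converged") <- converged
  attr(out, "objective") <- f_prev
  out
}

#' One K-SVD sweep over all atoms
#'
#' Classic K-SVD: each atom and the nonzero entries of its code row are
#' jointly replaced by the leading singular pair of the residual restricted
#' to the columns that use the atom. Atoms used by no column are re-seeded
#' from the currently worst-reconstructed training column (normalised), each
#' replacement drawing a distinct column. The Frobenius reconstruction error
#' `||Z - D B||_F` never increases over the sweep.
#'
#' @param D dictionary p x K.
#' @param Z data p x N (columns are samples).
#' @param B codes K x N.
#' @return list with updated `D` and `B`.
#' @export
ksvd_sweep <- function(D, Z, B) {
  D <- as.matrix(D); Z <- as.matrix(Z); B <- as.matrix(B)
  if (nrow(D) != nrow(Z) || ncol(D) != nrow(B) || ncol(Z) != ncol(B)) {
    abort("inconsistent shapes among D, Z, B")
  }
  if (frob2(Z) == 0) return(list(D = D, B = B))
  used_cols <- integer(0)
  for (k in seq_len(ncol(D))) {
    idx <- which(B[k, ] != 0)
    if (length(idx) == 0L) {
      # re-seed dead atom from the worst-reconstructed column
      res <- colSums((Z - D %*% B)^2)
      res[used_cols] <- -Inf
      j <- which.max(res)
      used_cols <- c(used_cols, j)
      d_new <- Z[, j]
      nj <- sqrt(sum(d_new^2))
      if (nj > 0) d_new <- d_new / nj
      D[, k] <- d_new
      next
    }
    Ek <- Z[, idx, drop = FALSE] - D[, -k, drop = FALSE] %*% B[-k, idx, drop = FALSE]
    sv <- svd(Ek, nu = 1, nv = 1)
    u <- sv$u[, 1]
    # deterministic sign: largest-magnitude entry of the atom is positive
    sgn <- sign(u[which.max(abs(u))])
    if (sgn == 0) sgn <- 1
    D[, k] <- sgn * u
    B[k, idx] <- sgn * sv$d[1] * sv$v[, 1]
  }
  list(D = D, B = B)
}

#' Learn a single-layer dictionary by K-SVD
#'
#' Initialises atoms uniformly on the unit sphere (seeded), then alternates
#' OMP sparse coding with [ksvd_sweep()] for `sweeps` rounds. Deterministic
#' given `seed`.
#'
#' @param Z data matrix p x N (columns are samples).
#' @param n_atoms dictionary size K.
#' @param s OMP nonzero budget per sample.
#' @param sweeps alternation rounds.
#' @param seed RNG seed.
#' @param D0 optional initial dictionary (defaults to seeded random atoms).
#' @return list with the learned `D` (p x K) and codes `B` (K x N).
#' @export
ksvd_learn <- function(Z, n_atoms, s, sweeps = 15L, seed = 0L, D0 = NULL) {
  Z <- as.matrix(Z)
  p <- nrow(Z)
  n_atoms <- as.integer(n_atoms)
  s <- max(1L, min(as.integer(s), n_atoms, p))
  D <- if (is.null(D0)) {
    # standard K-SVD initialisation: atoms seeded from random data columns
    # (unit-normalised), topped up from the unit sphere if samples run out
    with_seed(seed, {
      n_data <- min(n_atoms, ncol(Z))
      cols <- sample(ncol(Z), n_data)
      M <- Z[, cols, drop = FALSE] +
        1e-8 * matrix(rnorm(p * n_data), p, n_data) # break exact duplicates
      if (n_atoms > n_data) {
        M <- cbind(M, matrix(rnorm(p * (n_atoms - n_data)), p, n_atoms - n_data))
      }
      nrm <- sqrt(colSums(M^2))
      nrm[nrm == 0] <- 1
      M / rep(nrm, each = p)
    })
  } else {
    normalize_atoms(D0)
  }
  B <- matrix(0, n_atoms, ncol(Z))
  for (sw in seq_len(sweeps)) {
    B <- vapply(seq_len(ncol(Z)), function(i) encode_omp(D, Z[, i], s),
                numeric(n_atoms))
    B <- matrix(B, nrow = n_atoms)
    upd <- ksvd_sweep(D, Z, B)
    D <- upd$D
    B <- upd$B
    if (sw < sweeps) D <- purge_duplicate_atoms(D, Z, B)
  }
  list(D = D, B = B)
}

# Standard K-SVD housekeeping: near-duplicate atoms (|cosine| > 0.99) are
# replaced by the currently worst-reconstructed training column, so the
# dictionary does not collapse onto repeated directions.
purge_duplicate_atoms <- function(D, Z, B, cos_thresh = 0.99) {
  G <- abs(crossprod(D))
  diag(G) <- 0
  res <- colSums((Z - D %*% B)^2)
  used <- integer(0)
  for (k in seq_len(ncol(D))) {
    if (any(G[k, seq_len(k - 1)] > cos_thresh)) {
      res[used] <- -Inf
      j <- which.max(res)
      used <- c(used, j)
      v <- Z[, j]
      nv <- sqrt(sum(v^2))
      if (nv > 0) D[, k] <- v / nv
    }
  }
  D
}

#' Per-class K-SVD dictionary initialisation
#'
#' Runs K-SVD independently on each class's samples and concatenates the
#' per-class sub-dictionaries in class-index order, so the initial dictionary
#' holds contiguous class blocks. If a class has fewer samples than
#' `atoms_per_class` its block is shrunk to the class size (with a warning).
#'
#' @param Z feature matrix p x N.
#' @param labels integer 0-based class labels, length N.
#' @param atoms_per_class atoms allocated to each class.
#' @param s nonzero budget for the OMP coding phase; default
#'   `ceiling(atoms_per_class / 10)`.
#' @param sweeps K-SVD sweeps per class.
#' @param seed RNG seed (per-class streams derived deterministically).
#' @return dictionary matrix p x (C * atoms_per_class), with attribute
#'   `class_of_atom` giving the 0-based class owning each atom.
#' @export
ksvd_init_per_class <- function(Z, labels, atoms_per_class, s = NULL,
                                sweeps = 10L, seed = 0L) {
  Z <- as.matrix(Z)
  if (is.null(labels)) abort("`labels` are required for per-class initialisation")
  labels <- as.integer(labels)
  if (length(labels) != ncol(Z)) abort("one label per column of Z required")
  classes <- sort(unique(labels))
  blocks <- vector("list", length(classes))
  owners <- integer(0)
  for (ci in seq_along(classes)) {
    idx <- which(labels == classes[ci])
    Kc <- atoms_per_class
    if (length(idx) < Kc) {
      warn(sprintf("class %d has %d samples < %d atoms; block reduced",
                   classes[ci], length(idx), Kc))
      Kc <- length(idx)
    }
    sc <- if (is.null(s)) max(1L, ceiling(Kc / 10)) else s
    fit <- ksvd_learn(Z[, idx, drop = FALSE], Kc, sc, sweeps = sweeps,
                      seed = seed + ci)
    blocks[[ci]] <- fit$D
    owners <- c(owners, rep(classes[ci], Kc))
  }
  D <- do.call(cbind, blocks)
  D <- normalize_atoms(D)
  attr(D, "class_of_atom") <- owners
  D
}

#' Match learned atoms to reference atoms
#'
#' Pairs learned and reference atoms one-to-one by maximising total absolute
#' cosine similarity (Hungarian assignment) and reports the fraction of
#' reference atoms matched above a cosine threshold. Used to quantify
#' dictionary recovery on planted data.
#'
#' @param D_hat learned dictionary.
#' @param D_ref reference dictionary with the same atom dimension.
#' @param threshold absolute-cosine cutoff counting a match.
#' @return list with `recovery` (fraction matched), `cosines` (per reference
#'   atom, after assignment) and `assignment` (index into `D_hat` columns).
#' @export
match_atoms <- function(D_hat, D_ref, threshold = 0.95) {
  unit <- function(M) {
    n <- sqrt(colSums(M^2))
    n[n == 0] <- 1
    M / rep(n, each = nrow(M))
  }
  A <- abs(crossprod(unit(as.matrix(D_ref)), unit(as.matrix(D_hat))))
  if (ncol(A) < nrow(A)) abort("D_hat must have at least as many atoms as D_ref")
  sol <- clue::solve_LSAP(A, maximum = TRUE)
  cosines <- A[cbind(seq_len(nrow(A)), sol)]
  list(recovery = mean(cosines >= threshold),
       cosines = cosines,
       assignment = as.integer(sol))
}
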