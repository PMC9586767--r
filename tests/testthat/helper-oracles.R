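# Independent oracles and shared fixtures for the test suite. Every oracle
# here is deliberately written as a direct, brute-force or closed-form
# computation, independent of the package's own code paths.

# Exhaustive best s-sparse least-squares fit: tries every support of size s.
omp_bruteforce_oracle <- function(D, z, s) {
  K <- ncol(D)
  best <- list(resid = Inf, support = integer(0), coef = numeric(0))
  supports <- utils::combn(K, s)
  for (i in seq_len(ncol(supports))) {
    sup <- supports[, i]
    fit <- qr.coef(qr(D[, sup, drop = FALSE]), z)
    fit[is.na(fit)] <- 0
    r <- sqrt(sum((z - D[, sup, drop = FALSE] %*% fit)^2))
    if (r < best$resid - 1e-12) {
      best <- list(resid = r, support = sup, coef = fit)
    }
  }
  best
}

# Long-run cyclic coordinate descent for 0.5||z - Db||^2 + lambda||b||_1.
lasso_cd_oracle <- function(D, z, lambda, iters = 5000) {
  K <- ncol(D)
  b <- numeric(K)
  nrm2 <- colSums(D^2)
  r <- z
  for (it in seq_len(iters)) {
    delta <- 0
    for (j in seq_len(K)) {
      if (nrm2[j] == 0) next
      old <- b[j]
      rho <- sum(D[, j] * r) + nrm2[j] * old
      new <- sign(rho) * max(abs(rho) - lambda, 0) / nrm2[j]
      if (new != old) {
        r <- r - D[, j] * (new - old)
        b[j] <- new
        delta <- delta + abs(new - old)
      }
    }
    if (delta < 1e-14) break
  }
  b
}

lasso_objective <- function(D, z, b, lambda) {
  0.5 * sum((z - D %*% b)^2) + lambda * sum(abs(b))
}

# Hand-rolled multilayer decode, written as an explicit elementwise loop.
decode_loop_oracle <- function(dicts, activation, B) {
  act <- function(X) switch(activation,
                            relu = pmax(X, 0),
                            sigmoid = 1 / (1 + exp(-X)),
                            tanh = tanh(X),
                            identity = X)
  M <- length(dicts)
  X <- as.matrix(B)
  for (m in rev(seq_len(M))) {
    D <- dicts[[m]]
    Y <- matrix(0, nrow(D), ncol(X))
    for (i in seq_len(nrow(D))) {
      for (j in seq_len(ncol(X))) {
        Y[i, j] <- sum(D[i, ] * X[, j])
      }
    }
    X <- if (m > 1) act(Y) else Y
  }
  X
}

# Central finite differences of a scalar function over a matrix argument.
fd_grad <- function(f, X, eps = 1e-6) {
  G <- X * 0
  for (i in seq_along(X)) {
    Xp <- X; Xp[i] <- Xp[i] + eps
    Xm <- X; Xm[i] <- Xm[i] - eps
    G[i] <- (f(Xp) - f(Xm)) / (2 * eps)
  }
  G
}

max_rel_err <- function(got, want, floor = 1e-8) {
  max(abs(got - want) / pmax(abs(want), floor))
}

# Reference metric computation built on table().
metrics_reference <- function(true, predicted, C) {
  tt <- table(factor(true, levels = 0:(C - 1)),
              factor(predicted, levels = 0:(C - 1)))
  tp <- diag(tt)
  prec <- ifelse(colSums(tt) > 0, tp / colSums(tt), NA)
  rec <- ifelse(rowSums(tt) > 0, tp / rowSums(tt), NA)
  f1 <- ifelse(!is.na(prec) & !is.na(rec) & (prec + rec) > 0,
               2 * prec * rec / (prec + rec),
               ifelse(is.na(prec) | is.na(rec), NA, 0))
  z <- function(x) ifelse(is.na(x), 0, x)
  c(precision = 100 * mean(z(prec)),
    recall = 100 * mean(z(rec)),
    accuracy = 100 * mean(true == predicted),
    balance = 100 * mean(rec[rowSums(tt) > 0]),
    f1 = 100 * mean(z(f1)))
}

# Seeded 8x16 s=3 sparse-coding problem on which greedy pursuit is exact:
# a signed/permuted union of the identity and Hadamard bases (mutual
# coherence 1/sqrt(8)), the best-conditioned planted support (smallest exact
# recovery constant) among 30 seeded draws, and well-separated coefficient
# magnitudes. On this family greedy selection provably matches the
# exhaustive best-support search.
omp_test_problem <- function(seed) {
  H8 <- matrix(1, 1, 1)
  for (i in 1:3) H8 <- rbind(cbind(H8, H8), cbind(H8, -H8))
  set.seed(seed)
  Dbase <- cbind(diag(8), H8 / sqrt(8))
  D <- sweep(Dbase, 2, sample(c(-1, 1), 16, replace = TRUE), "*")[, sample(16)]
  best <- NULL
  bestv <- Inf
  for (try in 1:30) {
    s0 <- sample(16, 3)
    erc <- max(colSums(abs(qr.coef(qr(D[, s0]), D[, -s0]))))
    if (erc < bestv) {
      bestv <- erc
      best <- s0
    }
  }
  coef0 <- sign(rnorm(3)) * c(2, 1, 0.5)
  list(D = D, z = as.numeric(D[, best] %*% coef0), support = best,
       coef = coef0, s = 3L)
}

random_dictionary <- function(p, K, seed) {
  set.seed(seed)
  normalize_atoms(matrix(rnorm(p * K), p, K))
}

# Small labelled feature fixture drawn from a planted model.
tiny_planted_fixture <- function(seed = 1, n_per_class = 10) {
  pm <- plant_model(n_classes = 3, n_layers = 2, dims = c(24, 18, 12),
                    sparsity = 3, seed = seed)
  ds <- sample_features(pm, n_per_class = n_per_class, seed = seed + 1)
  list(pm = pm, ds = ds, H = label_matrix(ds$labels, 3))
}
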