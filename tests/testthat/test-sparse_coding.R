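test_that("normalize_atoms rescales only columns outside the unit ball", {
  D <- cbind(c(3, 4), c(0.3, 0.4), c(0, 0))
  out <- normalize_atoms(D)
  expect_equal(out[, 1], c(0.6, 0.8))
  expect_equal(out[, 2], c(0.3, 0.4)) # already inside, untouched
  expect_equal(out[, 3], c(0, 0))
  expect_identical(normalize_atoms(diag(2)), diag(2))
  set.seed(42)
  M <- matrix(rnorm(40), 5, 8)
  out <- normalize_atoms(M)
  expect_equal(sqrt(colSums(out^2)), pmin(1, sqrt(colSums(M^2))))
  expect_error(normalize_atoms(matrix(c(1, NaN), 1, 2)), "finite")
})

test_that("encode_omp solves trivial and tie-break cases", {
  expect_equal(encode_omp(diag(2), c(0.5, 0), 1), c(0.5, 0))
  D <- cbind(c(1, 0), c(0, 1), c(1, 1) / sqrt(2))
  b <- encode_omp(D, c(1, 1), 1)
  expect_equal(which(b != 0), 3L)
  expect_equal(b[3], sqrt(2))
  expect_error(encode_omp(diag(3), c(1, 1), 1), "length")
})

test_that("encode_omp matches exhaustive support search on seeded problems", {
  # low-coherence instances with well-separated planted coefficients, the
  # regime where greedy pursuit is exact (see helper-oracles.R)
  for (seed in 1:10) {
    prob <- omp_test_problem(seed)
    b <- encode_omp(prob$D, prob$z, prob$s)
    oracle <- omp_bruteforce_oracle(prob$D, prob$z, prob$s)
    resid <- sqrt(sum((prob$z - prob$D %*% b)^2))
    expect_lt(abs(resid - oracle$resid), 1e-10)
    expect_setequal(which(b != 0), oracle$support)
  }
})

test_that("encode_omp with s = K and full-rank D is the least-squares solution", {
  D <- random_dictionary(10, 6, 3)
  set.seed(4)
  z <- rnorm(10)
  b <- encode_omp(D, z, 6)
  expect_equal(as.numeric(b), as.numeric(qr.coef(qr(D), z)), tolerance = 1e-10)
})

test_that("encode_l1 closed forms and oracle agreement hold", {
  D <- random_dictionary(6, 6, 7)
  set.seed(8)
  z <- rnorm(6)
  big <- max(abs(crossprod(D, z))) * 1.01
  expect_equal(as.numeric(encode_l1(D, z, big)), rep(0, 6))
  # orthonormal dictionary: exact soft threshold
  Q <- qr.Q(qr(matrix(rnorm(36), 6, 6)))
  bq <- encode_l1(Q, z, 0.2, tol = 1e-14, max_iter = 5000)
  expect_equal(as.numeric(bq),
               as.numeric(sign(crossprod(Q, z)) *
                            pmax(abs(crossprod(Q, z)) - 0.2, 0)),
               tolerance = 1e-8)
  # seeded 10x20 problem vs coordinate descent oracle
  D2 <- random_dictionary(10, 20, 9)
  set.seed(10)
  z2 <- rnorm(10)
  b2 <- encode_l1(D2, z2, 0.1, tol = 1e-14, max_iter = 20000)
  b_cd <- lasso_cd_oracle(D2, z2, 0.1)
  expect_lt(abs(lasso_objective(D2, z2, b2, 0.1) -
                  lasso_objective(D2, z2, b_cd, 0.1)), 1e-8)
})

test_that("ksvd_sweep never increases the reconstruction error", {
  set.seed(11)
  D <- random_dictionary(10, 15, 11)
  Z <- matrix(rnorm(10 * 40), 10, 40)
  B <- vapply(1:40, function(i) encode_omp(D, Z[, i], 3), numeric(15))
  err0 <- norm(Z - D %*% B, "F")
  up <- ksvd_sweep(D, Z, B)
  err1 <- norm(Z - up$D %*% up$B, "F")
  expect_lte(err1, err0 + 1e-10)
})

test_that("ksvd_sweep single-atom update equals the rank-1 SVD of the residual", {
  set.seed(12)
  D <- random_dictionary(6, 1, 12)
  Z <- matrix(rnorm(6 * 5), 6, 5)
  B <- matrix(rnorm(5), 1, 5)
  up <- ksvd_sweep(D, Z, B)
  sv <- svd(Z, nu = 1, nv = 1) # with one atom the restricted residual is Z
  expect_equal(abs(as.numeric(up$D)), abs(sv$u[, 1]), tolerance = 1e-10)
  expect_equal(abs(as.numeric(up$B)), abs(sv$d[1] * sv$v[, 1]), tolerance = 1e-10)
})

test_that("ksvd_sweep reseeds all atoms from data columns when B is zero", {
  set.seed(13)
  D <- random_dictionary(5, 3, 13)
  Z <- matrix(rnorm(5 * 8), 5, 8)
  up <- ksvd_sweep(D, Z, matrix(0, 3, 8))
  unit_cols <- apply(Z, 2, function(v) v / sqrt(sum(v^2)))
  for (k in 1:3) {
    match_any <- apply(unit_cols, 2, function(u) max(abs(u - up$D[, k])) < 1e-12)
    expect_true(any(match_any))
  }
  # all-zero data leaves the dictionary untouched
  same <- ksvd_sweep(D, matrix(0, 5, 8), matrix(0, 3, 8))
  expect_identical(same$D, D)
})

test_that("K-SVD converges to machine precision from a coherent start on exact data", {
  pm <- plant_model(n_classes = 2, n_layers = 1, dims = c(20, 12),
                    sparsity = 3, orthonormal = TRUE, seed = 14)
  ds <- sample_features(pm, n_per_class = 60, seed = 15, snr_db = Inf)
  set.seed(99)
  D0 <- normalize_atoms(pm$stack$dictionaries[[1]] +
                          2e-4 * matrix(rnorm(240), 20, 12))
  fit <- ksvd_learn(ds$values, 12, 3, sweeps = 30, seed = 16, D0 = D0)
  err <- norm(ds$values - fit$D %*% fit$B, "F") / norm(ds$values, "F")
  expect_lt(err, 1e-6)
})

test_that("per-class K-SVD init is deterministic, block-structured, and recovers planted atoms", {
  pm <- plant_model(n_classes = 3, n_layers = 1, dims = c(20, 12),
                    sparsity = 2, orthonormal = TRUE, seed = 17)
  ds <- sample_features(pm, n_per_class = 200, seed = 18, snr_db = 40)
  D1 <- ksvd_init_per_class(ds$values, ds$labels, 4, s = 2, sweeps = 30, seed = 19)
  D2 <- ksvd_init_per_class(ds$values, ds$labels, 4, s = 2, sweeps = 30, seed = 19)
  expect_identical(D1, D2)
  expect_equal(ncol(D1), 12)
  expect_equal(attr(D1, "class_of_atom"), rep(0:2, each = 4))
  mt <- match_atoms(D1, pm$stack$dictionaries[[1]], threshold = 0.99)
  expect_gte(mt$recovery, 0.9)
  expect_error(ksvd_init_per_class(ds$values, NULL, 4), "labels")
})

test_that("returned dictionaries always satisfy the atom-norm invariant", {
  fx <- tiny_planted_fixture(20)
  D <- ksvd_init_per_class(fx$ds$values, fx$ds$labels, 4, sweeps = 3, seed = 21)
  expect_true(all(colSums(D^2) <= 1 + 1e-9))
  fit <- ksvd_learn(fx$ds$values, 10, 2, sweeps = 3, seed = 22)
  up <- ksvd_sweep(fit$D, fx$ds$values, fit$B)
  expect_true(all(colSums(up$D^2) <= 1 + 1e-9))
})
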