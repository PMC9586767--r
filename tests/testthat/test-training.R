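test_that("total_objective components are bookkept exactly", {
  fx <- tiny_planted_fixture(80)
  cfg <- dd_config(n_layers = 2, n_atoms = c(12, 9), epochs = 0,
                   init_sweeps = 2, seed = 80)
  model <- init_model(fx$ds, cfg = cfg)
  obj <- total_objective(model, fx$ds$values, fx$H)
  expect_equal(sum(obj$components), obj$total, tolerance = 1e-12)
  # independent recomputation from the five formulas
  manual <- sum((fx$ds$values - decode_stack(model$stack, model$B))^2) +
    cfg$lambda1 * sum(abs(model$B)) +
    cfg$lambda2 * sum(model$B * (model$laplacian %*% model$B)) +
    cfg$lambda3 * softmax_loss(model$theta, model$B, fx$H) +
    cfg$lambda_lc * sum((model$B - model$S %*% fx$H)^2)
  expect_equal(obj$total, manual, tolerance = 1e-10)
})

test_that("zero penalties and perfect reconstruction give a zero objective", {
  pm <- plant_model(n_classes = 2, n_layers = 1, dims = c(10, 6), sparsity = 2,
                    seed = 81)
  ds <- sample_features(pm, n_per_class = 5, seed = 82, snr_db = Inf)
  cfg <- dd_config(n_layers = 1, n_atoms = 6L, lambda1 = 0, lambda2 = 0,
                   lambda3 = 0, lambda_lc = 0, epochs = 0, seed = 81)
  model <- init_model(ds, cfg = cfg)
  # plug in the exact planted factorization
  model$stack$dictionaries[[1]] <- pm$stack$dictionaries[[1]]
  model$B <- ds$true_codes
  expect_equal(total_objective(model, ds$values, label_matrix(ds$labels))$total, 0,
               tolerance = 1e-20)
})

test_that("init_model is deterministic and satisfies every type invariant", {
  fx <- tiny_planted_fixture(83)
  cfg <- dd_config(n_layers = 2, n_atoms = c(12, 9), epochs = 0,
                   init_sweeps = 3, seed = 83)
  m1 <- init_model(fx$ds, cfg = cfg)
  m2 <- init_model(fx$ds, cfg = cfg)
  expect_identical(m1$stack$dictionaries, m2$stack$dictionaries)
  expect_identical(m1$B, m2$B)
  for (D in m1$stack$dictionaries) {
    expect_true(all(colSums(D^2) <= 1 + 1e-9))
  }
  expect_true(isSymmetric(m1$graph$E))
  expect_lt(max(abs(rowSums(m1$laplacian))), 1e-9)
  expect_equal(dim(m1$theta), c(3L, 9L))
  expect_equal(nrow(m1$trace), 0L)
})

test_that("layer-wise init reconstructs planted two-layer data at zero noise", {
  # linear planted stack: per-class data is exactly rank 4, so the staged
  # K-SVD factorization is well-posed and the initial decode should capture
  # at least 90% of the signal energy
  pm <- plant_model(n_classes = 3, n_layers = 2, dims = c(24, 18, 12),
                    sparsity = 3, activation = "identity", seed = 84)
  ds <- sample_features(pm, n_per_class = 20, seed = 85, snr_db = Inf)
  cfg <- dd_config(n_layers = 2, n_atoms = c(12, 12), activation = "identity",
                   epochs = 0, init_sweeps = 30, init_sparsity = 6L, seed = 84)
  model <- init_model(ds, cfg = cfg)
  fid <- sum((ds$values - decode_stack(model$stack, model$B))^2)
  expect_lte(fid, 0.10 * sum(ds$values^2))
})

test_that("full-batch training is monotone and epochs=0 returns the initial model", {
  fx <- tiny_planted_fixture(86)
  cfg <- dd_config(n_layers = 2, n_atoms = c(12, 9), epochs = 25,
                   init_sweeps = 3, graph_refresh = 8, seed = 86)
  model <- dd_train(fx$ds, cfg = cfg)
  expect_true(all(diff(model$trace$total) <= 1e-8))
  expect_gt(nrow(model$trace), 0)
  cfg0 <- cfg
  cfg0$epochs <- 0L
  m0 <- dd_train(fx$ds, cfg = cfg0)
  mi <- init_model(fx$ds, cfg = cfg0)
  expect_identical(m0$B, mi$B)
  expect_identical(m0$stack$dictionaries, mi$stack$dictionaries)
})

test_that("joint training reaches high training accuracy on separable planted codes", {
  fx <- tiny_planted_fixture(87, n_per_class = 15)
  cfg <- dd_config(n_layers = 2, n_atoms = c(12, 9), epochs = 200,
                   init_sweeps = 5, seed = 87)
  model <- dd_train(fx$ds, cfg = cfg)
  G <- softmax_prob(model$theta, model$B)
  train_acc <- mean((apply(G, 2, which.max) - 1L) == fx$ds$labels)
  expect_gte(train_acc, 0.98)
})

test_that("with no penalties and one identity layer training solves the rank-K factorization", {
  set.seed(88)
  Z <- matrix(rnorm(10 * 30), 10, 30)
  labels <- rep(0:1, 15)
  cfg <- dd_config(n_layers = 1, n_atoms = 4L, activation = "identity",
                   lambda1 = 0, lambda2 = 0, lambda3 = 0, lambda_lc = 0,
                   epochs = 300, init_sweeps = 5, seed = 88)
  model <- dd_train(Z, label_matrix(labels), cfg = cfg)
  fid <- sum((Z - decode_stack(model$stack, model$B))^2)
  # Eckart-Young: the optimum over rank-4 factorizations is the tail
  # singular-value energy
  opt <- sum(svd(Z)$d[-(1:4)]^2)
  expect_lte(fid, 1.1 * opt + 1e-8)
  expect_gte(fid, opt - 1e-8)
})

test_that("stochastic mode runs and records a trace", {
  fx <- tiny_planted_fixture(89)
  cfg <- dd_config(n_layers = 1, n_atoms = 12L, epochs = 5,
                   batch_mode = "stochastic", batch_size = 10,
                   init_sweeps = 2, seed = 89)
  model <- dd_train(fx$ds, cfg = cfg)
  expect_equal(nrow(model$trace), 5)
  expect_true(all(is.finite(model$trace$total)))
})

test_that("make_folds yields exact per-class 70/30 splits on balanced data", {
  labels <- rep(0:1, each = 50)
  plan <- make_folds(labels, n_folds = 5, train_fraction = 0.70, seed = 1)
  for (f in plan$folds) {
    expect_length(f$train, 70)
    expect_length(f$test, 30)
    expect_length(intersect(f$train, f$test), 0)
    for (cl in 0:1) {
      expect_equal(sum(labels[f$train] == cl), 35)
      expect_equal(sum(labels[f$test] == cl), 15)
    }
  }
  # fold blocks rotate: each sample appears in at least one test set
  expect_setequal(unlist(lapply(plan$folds, `[[`, "test")), 1:100)
})

test_that("folds are stratified, deterministic, and warn on tiny classes", {
  labels <- rep(0:1, each = 10)
  plan <- make_folds(labels, n_folds = 5, seed = 3)
  for (f in plan$folds) {
    expect_true(all(0:1 %in% labels[f$test]))
    expect_true(all(0:1 %in% labels[f$train]))
  }
  expect_identical(make_folds(labels, 5, seed = 3), plan)
  expect_false(identical(make_folds(labels, 5, seed = 4), plan))
  expect_warning(make_folds(c(rep(0L, 20), 1L, 1L), n_folds = 5, seed = 5),
                 "fewer samples than folds")
})

test_that("grid search returns grid members with small-lambda tie-breaking", {
  fx <- tiny_planted_fixture(90, n_per_class = 8)
  cfg <- dd_config(n_layers = 1, n_atoms = 9L, epochs = 2, init_sweeps = 2,
                   grid = c(0.1, 1), seed = 90)
  folds <- make_folds(fx$ds$labels, n_folds = 2, seed = 90)
  res <- grid_search_lambda(fx$ds, cfg = cfg, folds = folds)
  expect_true(all(res$best %in% cfg$grid))
  expect_equal(nrow(res$table), 2 * 2) # triples x folds
  # single-candidate grid returns that candidate
  cfg1 <- cfg
  cfg1$grid <- 0.5
  res1 <- grid_search_lambda(fx$ds, cfg = cfg1, folds = folds)
  expect_equal(unname(res1$best), c(0.5, 0.5, 0.5))
})

test_that("repeat_and_average stacks runs and appends exact mean rows", {
  run_stub <- function(seed) {
    tibble::tibble(split = c("Training", "Testing"),
                   accuracy = c(90 + seed, 80 + seed))
  }
  rep1 <- repeat_and_average(run_stub, repeats = 1, seed = 5)
  expect_equal(nrow(rep1), 4) # 2 data rows + one average row per split
  avg1 <- rep1[rep1$`repeat` == "average", ]
  dat1 <- rep1[rep1$`repeat` == "1", ]
  expect_equal(avg1$accuracy[match(dat1$split, avg1$split)], dat1$accuracy)
  rep3 <- repeat_and_average(run_stub, repeats = 3, seed = 0)
  avg_test <- rep3$accuracy[rep3$`repeat` == "average" & rep3$split == "Testing"]
  expect_equal(avg_test, mean(80 + 0:2), tolerance = 1e-12)
  # constant-metric runs show zero deviation
  rep_const <- repeat_and_average(function(s) {
    tibble::tibble(split = "Testing", accuracy = 42)
  }, repeats = 4, seed = 1)
  expect_equal(sd(rep_const$accuracy), 0)
})

test_that("training aborts with a diagnostic on divergence", {
  fx <- tiny_planted_fixture(91)
  cfg <- dd_config(n_layers = 1, n_atoms = 12L, epochs = 30,
                   batch_mode = "stochastic", learning_rate = 50,
                   init_sweeps = 2, seed = 91)
  expect_error(dd_train(fx$ds, cfg = cfg), "diverged")
})
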