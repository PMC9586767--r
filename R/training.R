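# Joint training: the combined objective (reconstruction + l1 sparsity +
# atom-graph smoothness + softmax loss + label consistency), its alternating
# block optimisation with backtracking line searches, the per-class K-SVD
# initialisation, stratified fold plans, the lambda grid search, and the
# repeated-run averaging protocol.

#' Training configuration
#'
#' @param n_layers stack depth M.
#' @param n_atoms integer vector of atoms per layer (length `n_layers`);
#'   `NULL` derives a default chain from the data at fit time.
#' @param activation between-layer activation (default `"relu"`).
#' @param lambda1 l1 sparsity weight on the final-layer codes.
#' @param lambda2 atom-graph smoothness weight.
#' @param lambda3 softmax-loss weight.
#' @param lambda_lc label-consistency weight.
#' @param knn_k neighbour count for the atom graph.
#' @param sigma heat-kernel bandwidth or `"auto"`.
#' @param learning_rate fixed step size for `batch_mode = "stochastic"`.
#' @param epochs training epochs.
#' @param batch_mode `"full"` (backtracking line searches, monotone
#'   objective) or `"stochastic"` (mini-batch, fixed rate).
#' @param batch_size mini-batch size for stochastic mode.
#' @param graph_refresh rebuild the atom graph every this many epochs.
#' @param init_sweeps K-SVD sweeps during initialisation.
#' @param init_sparsity OMP nonzero budget at initialisation; default
#'   `ceiling(K_1 / 10)`.
#' @param early_stop_tol,early_stop_patience stop when the objective drop
#'   stays below `early_stop_tol` for `early_stop_patience` epochs.
#' @param grid candidate lambda values for [grid_search_lambda()].
#' @param seed RNG seed governing every stochastic choice.
#' @return an object of class `dd_config`.
#' @export
dd_config <- function(n_layers = 3L, n_atoms = NULL, activation = "relu",
                      lambda1 = 0.1, lambda2 = 0.1, lambda3 = 1,
                      lambda_lc = 0.1, knn_k = 5L, sigma = "auto",
                      learning_rate = 1e-2, epochs = 300L,
                      batch_mode = c("full", "stochastic"), batch_size = 32L,
                      graph_refresh = 10L, init_sweeps = 10L,
                      init_sparsity = NULL,
                      early_stop_tol = 1e-7, early_stop_patience = 10L,
                      grid = c(0.001, 0.01, 0.1, 1, 10, 100), seed = 0L) {
  batch_mode <- match.arg(batch_mode)
  lams <- c(lambda1, lambda2, lambda3, lambda_lc)
  if (any(lams < 0)) abort("lambda weights must be >= 0")
  if (epochs < 0) abort("`epochs` must be >= 0")
  structure(list(n_layers = as.integer(n_layers), n_atoms = n_atoms,
                 activation = activation, lambda1 = lambda1,
                 lambda2 = lambda2, lambda3 = lambda3, lambda_lc = lambda_lc,
                 knn_k = as.integer(knn_k), sigma = sigma,
                 learning_rate = learning_rate, epochs = as.integer(epochs),
                 batch_mode = batch_mode, batch_size = as.integer(batch_size),
                 graph_refresh = as.integer(graph_refresh),
                 init_sweeps = as.integer(init_sweeps),
                 init_sparsity = init_sparsity,
                 early_stop_tol = early_stop_tol,
                 early_stop_patience = as.integer(early_stop_patience),
                 grid = grid, seed = as.integer(seed)),
            class = "dd_config")
}

# Accept either a plain matrix + H, or a dd_features object.
resolve_inputs <- function(Z, H) {
  classes <- NULL
  if (inherits(Z, "dd_features")) {
    classes <- Z$classes
    if (is.null(H)) {
      if (is.null(Z$labels)) abort("features carry no labels")
      H <- label_matrix(Z$labels, length(classes))
    }
    Z <- Z$values
  }
  if (is.null(H)) abort("labels (H) are required")
  Z <- as.matrix(Z); H <- as.matrix(H)
  if (ncol(Z) != ncol(H)) abort("Z and H must have the same number of columns")
  if (is.null(classes)) classes <- sprintf("class_%d", seq_len(nrow(H)) - 1L)
  list(Z = Z, H = H, classes = classes)
}

default_atom_chain <- function(p, C, M) {
  K1 <- max(8L * C, 24L)
  K1 <- min(K1, p)
  Ks <- integer(M)
  Ks[1] <- (K1 %/% C) * C
  if (M > 1) for (m in 2:M) Ks[m] <- max(C * 2L, ceiling(Ks[m - 1] * 0.75))
  Ks
}

#' Combined training objective and its components
#'
#' `J = ||Z - decode||_F^2 + lambda1 ||B||_1 + lambda2 Tr(B' L B) +
#'  lambda3 * softmax loss + lambda_lc ||B - S H||_F^2`.
#'
#' @param model a `dd_model`.
#' @param Z feature matrix.
#' @param H one-hot labels.
#' @param B final-layer codes; defaults to the codes stored in the model.
#' @return list with `total` and named `components`.
#' @export
total_objective <- function(model, Z, H, B = model$B) {
  cfg <- model$config
  fid <- frob2(Z - decode_stack(model$stack, B))
  comp <- c(
    fidelity = fid,
    sparsity = cfg$lambda1 * sum(abs(B)),
    graph = cfg$lambda2 * graph_penalty(B, model$laplacian),
    classifier = cfg$lambda3 * softmax_loss(model$theta, B, H),
    label_consistency = label_consistency_loss(B, model$S, H, cfg$lambda_lc)$loss
  )
  list(total = sum(comp), components = comp)
}

#' Initialise a model by layer-wise K-SVD
#'
#' Layer 1 comes from per-class K-SVD on the data (per-class blocks
#' concatenated in class order); each deeper layer from K-SVD on the previous
#' layer's codes (the activation is ignored at initialisation). The softmax
#' parameters start at zero, prototypes at the class-mean codes, and the atom
#' graph is built from the last dictionary. Deterministic given the seed.
#'
#' @param Z feature matrix (or `dd_features`).
#' @param H one-hot labels (optional when `Z` is a labelled `dd_features`).
#' @param cfg a [dd_config()].
#' @return an untrained `dd_model` (empty trace).
#' @export
init_model <- function(Z, H = NULL, cfg = dd_config()) {
  inp <- resolve_inputs(Z, H)
  Z <- inp$Z; H <- inp$H
  C <- nrow(H)
  M <- cfg$n_layers
  labels <- max.col(t(H)) - 1L
  Ks <- cfg$n_atoms %||% default_atom_chain(nrow(Z), C, M)
  if (length(Ks) != M) abort("`n_atoms` must have one entry per layer")
  apc <- max(1L, Ks[1] %/% C)
  s1 <- cfg$init_sparsity %||% max(1L, ceiling(Ks[1] / 10))
  D1 <- ksvd_init_per_class(Z, labels, apc, s = s1, sweeps = cfg$init_sweeps,
                            seed = cfg$seed)
  dicts <- list(normalize_atoms(D1))
  Bm <- vapply(seq_len(ncol(Z)),
               function(i) encode_omp(D1, Z[, i], min(s1, ncol(D1), nrow(D1))),
               numeric(ncol(D1)))
  Bm <- matrix(Bm, nrow = ncol(D1))
  if (M > 1) {
    for (m in 2:M) {
      Km <- Ks[m]
      avail <- min(nrow(Bm), ncol(Bm))
      if (Km > avail) {
        warn(sprintf("layer %d: %d atoms exceed available rank %d; clipped", m, Km, avail))
        Km <- avail
      }
      sm <- cfg$init_sparsity %||% max(1L, ceiling(Km / 10))
      fit <- ksvd_learn(Bm, Km, min(sm, Km, nrow(Bm)), sweeps = cfg$init_sweeps,
                        seed = cfg$seed + 100L * m)
      dicts[[m]] <- normalize_atoms(fit$D)
      Bm <- fit$B
    }
  }
  stack <- layer_stack(dicts, activation = cfg$activation)
  K_M <- ncol(dicts[[M]])
  graph <- build_atom_graph(dicts[[M]], k = min(cfg$knn_k, K_M - 1L),
                            sigma = cfg$sigma)
  model <- structure(list(stack = stack,
                          theta = matrix(0, C, K_M),
                          S = update_prototypes(Bm, H),
                          graph = graph,
                          laplacian = graph_laplacian(graph),
                          B = Bm,
                          prior = rowMeans(Bm),
                          config = cfg,
                          classes = inp$classes,
                          trace = empty_trace()),
                     class = "dd_model")
  model
}

empty_trace <- function() {
  tibble::tibble(epoch = integer(), fidelity = numeric(), sparsity = numeric(),
                 graph = numeric(), classifier = numeric(),
                 label_consistency = numeric(), total = numeric())
}

# Smooth part of the objective in B (everything except the l1 term).
smooth_parts_B <- function(model, Z, H, B) {
  cfg <- model$config
  fid <- frob2(Z - decode_stack(model$stack, B))
  fid + cfg$lambda2 * graph_penalty(B, model$laplacian) +
    cfg$lambda3 * softmax_loss(model$theta, B, H) +
    label_consistency_loss(B, model$S, H, cfg$lambda_lc)$loss
}

smooth_grad_B <- function(model, Z, H, B) {
  cfg <- model$config
  g <- grad_stack(model$stack, B, Z)$dB
  if (cfg$lambda2 > 0) g <- g + cfg$lambda2 * graph_penalty_grad(B, model$laplacian)
  if (cfg$lambda3 > 0) g <- g + cfg$lambda3 * softmax_grad(model$theta, B, H)$dB
  if (cfg$lambda_lc > 0) g <- g + label_consistency_loss(B, model$S, H, cfg$lambda_lc)$dB
  g
}

# One proximal-gradient step on B with backtracking; returns updated B and
# the accepted step size. Guarantees the composite objective in B does not
# increase.
prox_step_B <- function(model, Z, H, B, t0) {
  cfg <- model$config
  f0 <- smooth_parts_B(model, Z, H, B)
  g <- smooth_grad_B(model, Z, H, B)
  t <- t0
  for (i in 1:40) {
    Bn <- soft_threshold(B - t * g, t * cfg$lambda1)
    dB <- Bn - B
    f1 <- smooth_parts_B(model, Z, H, Bn)
    if (f1 <= f0 + sum(g * dB) + frob2(dB) / (2 * t) + 1e-12) {
      return(list(B = Bn, t = t))
    }
    t <- t / 2
  }
  list(B = B, t = t0)
}

#' Train the full model
#'
#' Alternating block updates per epoch: (a) final-layer codes by proximal
#' gradient with l1 shrinkage; (b) every dictionary by a chain-rule gradient
#' step followed by atom normalisation; (c) softmax parameters by gradient
#' step and prototypes by their closed form; (d) a periodic atom-graph
#' rebuild. In `"full"` batch mode every step is accepted through a
#' backtracking line search and a rebuilt graph is adopted only when it does
#' not increase the objective, so the recorded objective trace is
#' non-increasing. `"stochastic"` mode uses fixed-rate mini-batch steps.
#'
#' @inheritParams init_model
#' @return a trained `dd_model` with a per-epoch objective trace.
#' @export
dd_train <- function(Z, H = NULL, cfg = dd_config()) {
  inp <- resolve_inputs(Z, H)
  model <- init_model(inp$Z, inp$H, cfg)
  if (cfg$epochs == 0L) return(model)
  Z <- inp$Z; H <- inp$H
  J0 <- total_objective(model, Z, H)$total
  t_B <- 1 / max(spectral_norm(model$stack$dictionaries[[1]])^2, 1e-8)
  t_D <- 0.1
  t_T <- 1
  flat <- 0L
  J_prev <- J0
  trace <- vector("list", cfg$epochs)
  rng_state <- NULL
  for (epoch in seq_len(cfg$epochs)) {
    # (d) monotone-safe graph refresh
    if (cfg$lambda2 > 0 && epoch > 1L && (epoch - 1L) %% cfg$graph_refresh == 0L) {
      model <- refresh_graph(model, Z, H)
    }
    if (cfg$batch_mode == "full") {
      # (a) code step (a few inner prox iterations)
      for (it in 1:3) {
        st <- prox_step_B(model, Z, H, model$B, t_B)
        model$B <- st$B
        t_B <- st$t * 1.5
      }
      # (b) dictionary steps
      upd <- update_dictionaries(model, Z, t_D)
      model <- upd$model
      t_D <- upd$t
      # (c) classifier + prototypes
      if (model$config$lambda3 > 0) {
        upd <- update_theta(model, H, t_T)
        model <- upd$model
        t_T <- upd$t
      }
      if (model$config$lambda_lc > 0) {
        model$S <- update_prototypes(model$B, H, model$S)
      }
    } else {
      model <- stochastic_epoch(model, Z, H, epoch)
    }
    obj <- total_objective(model, Z, H)
    trace[[epoch]] <- tibble::tibble(epoch = epoch,
                                     fidelity = obj$components[["fidelity"]],
                                     sparsity = obj$components[["sparsity"]],
                                     graph = obj$components[["graph"]],
                                     classifier = obj$components[["classifier"]],
                                     label_consistency = obj$components[["label_consistency"]],
                                     total = obj$total)
    if (!is.finite(obj$total) || obj$total > 1e3 * max(J0, 1e-12)) {
      abort(sprintf("training diverged at epoch %d (J = %.3g, initial %.3g)",
                    epoch, obj$total, J0))
    }
    flat <- if (J_prev - obj$total < cfg$early_stop_tol) flat + 1L else 0L
    J_prev <- obj$total
    if (flat >= cfg$early_stop_patience) {
      trace <- trace[seq_len(epoch)]
      break
    }
  }
  model$trace <- dplyr::bind_rows(trace)
  model$prior <- rowMeans(model$B)
  model
}

refresh_graph <- function(model, Z, H) {
  D_M <- model$stack$dictionaries[[model$stack$n_layers]]
  K_M <- ncol(D_M)
  g_new <- build_atom_graph(D_M, k = min(model$config$knn_k, K_M - 1L),
                            sigma = model$config$sigma)
  L_new <- graph_laplacian(g_new)
  old_pen <- graph_penalty(model$B, model$laplacian)
  new_pen <- graph_penalty(model$B, L_new)
  if (model$config$batch_mode != "full" ||
      model$config$lambda2 * (new_pen - old_pen) <= 1e-12) {
    model$graph <- g_new
    model$laplacian <- L_new
  }
  model
}

update_dictionaries <- function(model, Z, t0) {
  M <- model$stack$n_layers
  t <- t0
  for (m in seq_len(M)) {
    gD <- grad_stack(model$stack, model$B, Z)$dD[[m]]
    f0 <- frob2(Z - decode_stack(model$stack, model$B))
    accepted <- FALSE
    tm <- t
    for (i in 1:30) {
      cand <- model$stack
      cand$dictionaries[[m]] <- normalize_atoms(cand$dictionaries[[m]] - tm * gD)
      f1 <- frob2(Z - decode_stack(cand, model$B))
      if (f1 <= f0 + 1e-12) {
        model$stack <- cand
        accepted <- TRUE
        break
      }
      tm <- tm / 2
    }
    if (accepted) t <- tm * 1.5
  }
  list(model = model, t = t)
}

update_theta <- function(model, H, t0) {
  g <- softmax_grad(model$theta, model$B, H)$dtheta
  f0 <- softmax_loss(model$theta, model$B, H)
  t <- t0
  for (i in 1:30) {
    theta_new <- model$theta - t * g
    if (softmax_loss(theta_new, model$B, H) <= f0 + 1e-12) {
      model$theta <- theta_new
      return(list(model = model, t = t * 1.5))
    }
    t <- t / 2
  }
  list(model = model, t = t0)
}

stochastic_epoch <- function(model, Z, H, epoch) {
  cfg <- model$config
  N <- ncol(Z)
  idx <- with_seed(cfg$seed + epoch, sample.int(N))
  batches <- split(idx, ceiling(seq_along(idx) / cfg$batch_size))
  lr <- cfg$learning_rate
  for (b in batches) {
    Zb <- Z[, b, drop = FALSE]
    Hb <- H[, b, drop = FALSE]
    Bb <- model$B[, b, drop = FALSE]
    g <- smooth_grad_B(model, Zb, Hb, Bb)
    model$B[, b] <- soft_threshold(Bb - lr * g, lr * cfg$lambda1)
    gD <- grad_stack(model$stack, model$B[, b, drop = FALSE], Zb)$dD
    for (m in seq_len(model$stack$n_layers)) {
      model$stack$dictionaries[[m]] <-
        normalize_atoms(model$stack$dictionaries[[m]] - lr * gD[[m]])
    }
    if (cfg$lambda3 > 0) {
      gT <- softmax_grad(model$theta, model$B[, b, drop = FALSE], Hb)$dtheta
      model$theta <- model$theta - lr * cfg$lambda3 * gT
    }
  }
  if (cfg$lambda_lc > 0) model$S <- update_prototypes(model$B, H, model$S)
  model
}

#' @export
print.dd_model <- function(x, ...) {
  cat(sprintf("<dd_model> %d layer(s), %d classes, %d training samples\n",
              x$stack$n_layers, length(x$classes), ncol(x$B)))
  if (nrow(x$trace)) {
    cat(sprintf("  trained %d epochs, final objective %.4g\n",
                max(x$trace$epoch), x$trace$total[nrow(x$trace)]))
  } else {
    cat("  initialised only (no training epochs)\n")
  }
  invisible(x)
}

#' Stratified fold plan with per-class train fraction
#'
#' Samples are first partitioned per class into `n_folds` disjoint,
#' rotating blocks. For fold i, the training set draws
#' `ceiling(train_fraction * n_class)` samples per class from outside block
#' i; everything else (block i plus the undrawn remainder) is the fold's
#' test set, so each fold honours the train fraction exactly per class.
#' Classes smaller than `n_folds` are kept whole in the rotation, with a
#' warning.
#'
#' @param labels 0-based integer class labels.
#' @param n_folds number of folds (>= 2).
#' @param train_fraction per-class training fraction (default 0.70).
#' @param seed RNG seed; identical seeds give identical plans.
#' @return object of class `dd_folds`: list of `folds` (each with `train`
#'   and `test` index vectors), plus the plan parameters.
#' @export
make_folds <- function(labels, n_folds = 5L, train_fraction = 0.70, seed = 0L) {
  labels <- as.integer(labels)
  n_folds <- as.integer(n_folds)
  if (n_folds < 2L) abort("`n_folds` must be >= 2")
  if (train_fraction <= 0 || train_fraction >= 1) abort("`train_fraction` must be in (0, 1)")
  classes <- sort(unique(labels))
  small <- classes[table(factor(labels, levels = classes)) < n_folds]
  if (length(small)) {
    warn(sprintf("class(es) %s have fewer samples than folds; kept whole in rotation",
                 paste(small, collapse = ", ")))
  }
  plan <- with_seed(seed, {
    blocks <- lapply(classes, function(cl) {
      idx <- sample(which(labels == cl))
      split(idx, rep_len(seq_len(n_folds), length(idx)))
    })
    folds <- vector("list", n_folds)
    for (f in seq_len(n_folds)) {
      train <- integer(0)
      test <- integer(0)
      for (ci in seq_along(classes)) {
        cl_idx <- which(labels == classes[ci])
        blk <- blocks[[ci]][[as.character(f)]] %||% integer(0)
        comp <- setdiff(cl_idx, blk)
        n_train <- min(ceiling(train_fraction * length(cl_idx)), length(comp))
        tr <- if (n_train > 0) sample(comp, n_train) else integer(0)
        train <- c(train, tr)
        test <- c(test, setdiff(cl_idx, tr))
      }
      folds[[f]] <- list(train = sort(train), test = sort(test))
    }
    folds
  })
  structure(list(folds = plan, n_folds = n_folds,
                 train_fraction = train_fraction, seed = as.integer(seed)),
            class = "dd_folds")
}

#' Cross-validated grid search over the lambda weights
#'
#' Evaluates mean cross-validation accuracy for candidate
#' `(lambda1, lambda2, lambda3)` triples drawn from `cfg$grid` and returns
#' the best triple. `pairing` controls the candidate set: `"diagonal"` ties
#' all three weights, `"tied"` enumerates the three pairwise-tied families,
#' `"full"` the whole cube. Ties in mean accuracy break toward smaller
#' lambdas (lexicographically).
#'
#' @param Z feature matrix (or labelled `dd_features`).
#' @param H one-hot labels (optional for `dd_features`).
#' @param cfg a [dd_config()]; its `epochs` bound the per-fold fits.
#' @param folds a [make_folds()] plan; default fivefold on the labels.
#' @param pairing `"diagonal"`, `"tied"` or `"full"`.
#' @return list with `best` (named lambda triple) and `table` (tibble, one
#'   row per evaluated triple x fold).
#' @export
grid_search_lambda <- function(Z, H = NULL, cfg = dd_config(), folds = NULL,
                               pairing = c("diagonal", "tied", "full")) {
  pairing <- match.arg(pairing)
  inp <- resolve_inputs(Z, H)
  labels <- max.col(t(inp$H)) - 1L
  if (is.null(folds)) folds <- make_folds(labels, 5L, 0.70, cfg$seed)
  g <- cfg$grid
  if (!length(g)) abort("`cfg$grid` must be non-empty")
  cube <- expand.grid(lambda1 = g, lambda2 = g, lambda3 = g)
  cand <- switch(pairing,
    diagonal = data.frame(lambda1 = g, lambda2 = g, lambda3 = g),
    tied = unique(cube[cube$lambda1 == cube$lambda2 |
                         cube$lambda2 == cube$lambda3 |
                         cube$lambda1 == cube$lambda3, ]),
    full = cube
  )
  rows <- list()
  for (i in seq_len(nrow(cand))) {
    cfg_i <- cfg
    cfg_i$lambda1 <- cand$lambda1[i]
    cfg_i$lambda2 <- cand$lambda2[i]
    cfg_i$lambda3 <- cand$lambda3[i]
    for (f in seq_along(folds$folds)) {
      tr <- folds$folds[[f]]$train
      te <- folds$folds[[f]]$test
      model <- dd_train(inp$Z[, tr, drop = FALSE],
                        inp$H[, tr, drop = FALSE], cfg_i)
      model$classes <- inp$classes
      pred <- predict(model, inp$Z[, te, drop = FALSE])
      acc <- mean(pred$pred_index == labels[te])
      rows[[length(rows) + 1L]] <-
        tibble::tibble(lambda1 = cand$lambda1[i], lambda2 = cand$lambda2[i],
                       lambda3 = cand$lambda3[i], fold = f, accuracy = acc)
    }
  }
  table <- dplyr::bind_rows(rows)
  means <- dplyr::summarise(
    dplyr::group_by(table, .data$lambda1, .data$lambda2, .data$lambda3),
    mean_accuracy = mean(.data$accuracy), .groups = "drop")
  means <- dplyr::arrange(means, dplyr::desc(.data$mean_accuracy),
                          .data$lambda1, .data$lambda2, .data$lambda3)
  best <- c(lambda1 = means$lambda1[1], lambda2 = means$lambda2[1],
            lambda3 = means$lambda3[1])
  list(best = best, table = table, means = means)
}

#' Repeat an experiment and append average rows
#'
#' Runs `run(seed_i)` for `repeats` derived seeds; each run must return a
#' data frame with a `split` column (e.g. `Training` / `Testing`) plus
#' numeric metric columns. The result stacks all runs with a `repeat`
#' column and appends one arithmetic-average row per split.
#'
#' @param run function taking a seed and returning a metrics data frame.
#' @param repeats number of repetitions (>= 1).
#' @param seed base seed; run i uses `seed + i - 1`.
#' @return tibble of per-repeat rows plus `repeat = "average"` rows.
#' @export
repeat_and_average <- function(run, repeats = 10L, seed = 0L) {
  if (repeats < 1L) abort("`repeats` must be >= 1")
  rows <- lapply(seq_len(repeats), function(i) {
    out <- tibble::as_tibble(run(seed + i - 1L))
    if (!"split" %in% names(out)) abort("`run` must return a `split` column")
    dplyr::mutate(out, `repeat` = as.character(i), .before = 1)
  })
  all <- dplyr::bind_rows(rows)
  num_cols <- names(all)[vapply(all, is.numeric, TRUE)]
  avg <- dplyr::summarise(dplyr::group_by(all, .data$split),
                          dplyr::across(dplyr::all_of(num_cols), mean),
                          .groups = "drop")
  avg <- dplyr::mutate(avg, `repeat` = "average", .before = 1)
  dplyr::bind_rows(all, avg)
}
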