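# Test-time encoding with an optional code prior, prediction through the
# softmax head, and the evaluation suite (row-normalised confusion matrix,
# macro precision/recall/F1, accuracy and balanced accuracy).

#' Encode a test sample through a trained stack
#'
#' Minimises `||y - decode(stack, b)||^2 + lambda1 ||b||_1 +
#' prior_weight ||b - P||^2` by proximal gradient with backtracking.
#' The start point is the prior `P` when the prior is active; otherwise the
#' solver warm-starts from the convex l1 fit against the linearised stack
#' (the product of the dictionaries with no activation), since the all-zero
#' vector is a stationary point of the ReLU objective and would never move.
#' Deterministic.
#'
#' @param model a `dd_model`.
#' @param y feature vector of length `nrow(D_1)`.
#' @param prior optional list with `P` (length K_M) and `weight` (>= 0);
#'   default uses the model's stored mean training code with weight 0
#'   (prior off).
#' @param max_iter,tol iteration cap and objective-decrease tolerance.
#' @return length-K_M code with attribute `converged`.
#' @export
encode_test <- function(model, y, prior = NULL, max_iter = 200L, tol = 1e-9) {
  y <- as.numeric(y)
  stack <- model$stack
  if (length(y) != nrow(stack$dictionaries[[1]])) {
    abort("`y` length must match the first dictionary's rows")
  }
  lambda1 <- model$config$lambda1
  P <- prior$P %||% model$prior
  w <- prior$weight %||% 0
  K_M <- ncol(stack$dictionaries[[stack$n_layers]])
  b <- if (w > 0) {
    as.numeric(P)
  } else {
    D_eff <- Reduce(`%*%`, stack$dictionaries)
    as.numeric(encode_l1(D_eff, y, lambda1, tol = 1e-8, max_iter = 200L))
  }
  smooth_f <- function(b) {
    frob2(y - decode_stack(stack, b)) + w * sum((b - P)^2)
  }
  smooth_g <- function(b) {
    g <- as.numeric(grad_stack(stack, matrix(b, ncol = 1), matrix(y, ncol = 1))$dB)
    if (w > 0) g <- g + 2 * w * (b - P)
    g
  }
  t <- 1 / max(spectral_norm(stack$dictionaries[[1]])^2, 1e-8)
  f_prev <- smooth_f(b) + lambda1 * sum(abs(b))
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    f0 <- smooth_f(b)
    g <- smooth_g(b)
    accepted <- FALSE
    for (ls in 1:30) {
      bn <- soft_threshold(b - t * g, t * lambda1)
      db <- bn - b
      if (smooth_f(bn) <= f0 + sum(g * db) + sum(db * db) / (2 * t) + 1e-12) {
        accepted <- TRUE
        break
      }
      t <- t / 2
    }
    if (!accepted) break
    b <- bn
    t <- t * 1.5
    f_new <- smooth_f(b) + lambda1 * sum(abs(b))
    if (f_prev - f_new < tol) {
      converged <- TRUE
      break
    }
    f_prev <- f_new
  }
  if (!converged && max_iter > 0L) warn("encode_test did not converge within max_iter")
  attr(b, "converged") <- converged
  b
}

#' Predict class probabilities for new samples
#'
#' Encodes each sample (column) through the stack with [encode_test()] and
#' applies the softmax head. Argmax ties break toward the lowest class
#' index.
#'
#' @param object a trained `dd_model`.
#' @param newdata feature matrix (columns are samples), single feature
#'   vector, or `dd_features`.
#' @param prior optional code prior passed to [encode_test()].
#' @param ... unused.
#' @return tibble with `sample`, `pred_index` (0-based), `pred_class`,
#'   `max_prob`, one `prob_<class>` column per class, and the codes in
#'   attribute `codes` (K_M x N matrix).
#' @export
predict.dd_model <- function(object, newdata, prior = NULL, ...) {
  ids <- NULL
  if (inherits(newdata, "dd_features")) {
    ids <- newdata$sample_ids
    newdata <- newdata$values
  }
  Y <- as.matrix(newdata)
  if (nrow(Y) == 1L && ncol(Y) > 1L) Y <- t(Y)
  N <- ncol(Y)
  codes <- vapply(seq_len(N), function(i) encode_test(object, Y[, i], prior = prior),
                  numeric(ncol(object$stack$dictionaries[[object$stack$n_layers]])))
  codes <- matrix(codes, ncol = N)
  G <- softmax_prob(object$theta, codes)
  G <- matrix(G, nrow = nrow(object$theta))
  pred <- apply(G, 2, which.max) - 1L # first max = lowest class index
  out <- tibble::tibble(sample = ids %||% sprintf("sample_%d", seq_len(N)),
                        pred_index = as.integer(pred),
                        pred_class = object$classes[pred + 1L],
                        max_prob = apply(G, 2, max))
  probs <- tibble::as_tibble(as.data.frame(t(G)))
  names(probs) <- paste0("prob_", object$classes)
  out <- dplyr::bind_cols(out, probs)
  attr(out, "codes") <- codes
  out
}

#' Row-normalised confusion matrix
#'
#' Entry (i, j) is the fraction of class-i samples predicted as class j;
#' rows of classes absent from `true` are all zero.
#'
#' @param true,predicted 0-based integer labels of equal length.
#' @param n_classes class count C.
#' @return C x C matrix with rows summing to 1 for present classes.
#' @export
confusion_matrix <- function(true, predicted, n_classes) {
  true <- as.integer(true); predicted <- as.integer(predicted)
  if (length(true) != length(predicted)) abort("label vectors must have equal length")
  if (any(c(true, predicted) < 0L) || any(c(true, predicted) >= n_classes)) {
    abort("label outside 0..C-1")
  }
  counts <- matrix(0, n_classes, n_classes)
  for (i in seq_along(true)) {
    counts[true[i] + 1L, predicted[i] + 1L] <- counts[true[i] + 1L, predicted[i] + 1L] + 1
  }
  rs <- rowSums(counts)
  out <- counts
  out[rs > 0, ] <- counts[rs > 0, , drop = FALSE] / rs[rs > 0]
  out
}

#' Classification metric suite
#'
#' Macro-averaged one-vs-rest precision, recall and F1, overall accuracy,
#' and balanced accuracy (mean per-class recall over classes present in the
#' truth), all as percentages. Classes with undefined precision or recall
#' contribute 0 to the macro averages, with a warning.
#'
#' @param true,predicted 0-based integer labels.
#' @param n_classes class count; default `max(labels) + 1`.
#' @return object of class `dd_metrics`: list with `summary` (tibble of
#'   metric/value), `per_class` (tibble) and `confusion` (row-normalised
#'   matrix).
#' @export
metric_suite <- function(true, predicted, n_classes = NULL) {
  true <- as.integer(true); predicted <- as.integer(predicted)
  if (length(true) < 1L) abort("at least one sample required")
  C <- n_classes %||% (max(c(true, predicted)) + 1L)
  conf <- confusion_matrix(true, predicted, C)
  per <- lapply(seq_len(C) - 1L, function(cl) {
    tp <- sum(true == cl & predicted == cl)
    fp <- sum(true != cl & predicted == cl)
    fn <- sum(true == cl & predicted != cl)
    prec <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
    rec <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
    f1 <- if (!is.na(prec) && !is.na(rec) && prec + rec > 0) {
      2 * prec * rec / (prec + rec)
    } else if (is.na(prec) || is.na(rec)) NA_real_ else 0
    tibble::tibble(class = cl, precision = prec, recall = rec, f1 = f1,
                   support = sum(true == cl))
  })
  per <- dplyr::bind_rows(per)
  if (anyNA(per[c("precision", "recall", "f1")])) {
    warn("some classes have undefined precision/recall; they contribute 0 to macro averages")
  }
  zero_na <- function(x) ifelse(is.na(x), 0, x)
  present <- per$support > 0
  balance <- mean(per$recall[present])
  summary <- tibble::tibble(
    metric = c("precision", "recall", "accuracy", "balance", "f1"),
    value = 100 * c(mean(zero_na(per$precision)),
                    mean(zero_na(per$recall)),
                    mean(true == predicted),
                    balance,
                    mean(zero_na(per$f1))))
  structure(list(summary = summary,
                 per_class = dplyr::mutate(per,
                   dplyr::across(c("precision", "recall", "f1"), ~ 100 * .x)),
                 confusion = conf),
            class = "dd_metrics")
}

#' @export
print.dd_metrics <- function(x, ...) {
  cat("<dd_metrics>\n")
  print(x$summary)
  invisible(x)
}

#' Evaluate a trained model on labelled features
#'
#' Convenience wrapper: predict every column, then compute the metric suite.
#'
#' @param model trained `dd_model`.
#' @param Z feature matrix or labelled `dd_features`.
#' @param labels 0-based labels (optional for labelled `dd_features`).
#' @return `dd_metrics` with the per-sample predictions in attribute
#'   `predictions`.
#' @export
evaluate_model <- function(model, Z, labels = NULL) {
  if (inherits(Z, "dd_features")) {
    labels <- labels %||% Z$labels
  }
  if (is.null(labels)) abort("`labels` are required")
  pred <- predict(model, Z)
  m <- metric_suite(labels, pred$pred_index, length(model$classes))
  attr(m, "predictions") <- dplyr::mutate(pred, true_index = as.integer(labels),
                                          .after = "sample")
  m
}

#' Cross-validate the full pipeline on labelled features
#'
#' Fits one model per fold on the fold's training indices and evaluates both
#' splits, returning per-fold Training/Testing metric rows.
#'
#' @param Z feature matrix or labelled `dd_features`.
#' @param H one-hot labels (optional for labelled `dd_features`).
#' @param cfg a [dd_config()].
#' @param folds a [make_folds()] plan (default fivefold, 70/30).
#' @return tibble with columns `fold`, `split` and one column per metric.
#' @export
cross_validate <- function(Z, H = NULL, cfg = dd_config(), folds = NULL) {
  inp <- resolve_inputs(Z, H)
  labels <- max.col(t(inp$H)) - 1L
  if (is.null(folds)) folds <- make_folds(labels, 5L, 0.70, cfg$seed)
  rows <- lapply(seq_along(folds$folds), function(f) {
    tr <- folds$folds[[f]]$train
    te <- folds$folds[[f]]$test
    model <- dd_train(inp$Z[, tr, drop = FALSE], inp$H[, tr, drop = FALSE], cfg)
    model$classes <- inp$classes
    mtr <- evaluate_model(model, inp$Z[, tr, drop = FALSE], labels[tr])
    mte <- evaluate_model(model, inp$Z[, te, drop = FALSE], labels[te])
    dplyr::bind_rows(
      dplyr::mutate(tidyr::pivot_wider(mtr$summary, names_from = "metric",
                                       values_from = "value"),
                    fold = f, split = "Training", .before = 1),
      dplyr::mutate(tidyr::pivot_wider(mte$summary, names_from = "metric",
                                       values_from = "value"),
                    fold = f, split = "Testing", .before = 1))
  })
  dplyr::bind_rows(rows)
}
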