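# Synthetic data with a planted multilayer dictionary model: class-specific
# sparse codes pushed through a known stack, optional atom-graph smoothness,
# Gaussian noise at a configured SNR, and a simple image renderer so the
# whole pipeline (files -> features -> training -> metrics) is exercisable
# without external data.

#' Plant a ground-truth multilayer dictionary model
#'
#' Draws random unit-norm dictionaries chaining through `dims`, and assigns
#' each class a contiguous block of final-layer atoms from which its sample
#' supports are drawn (blocks are disjoint, so class supports never overlap).
#' `smoothness` in `[0, 1)` correlates coefficients of adjacent atoms within
#' a class block (AR(1) across the block ordering), emulating codes that are
#' smooth along an atom neighbourhood graph.
#'
#' @param n_classes number of classes C (>= 2).
#' @param n_layers stack depth M.
#' @param dims integer vector `c(c, K_1, ..., K_M)` of length `n_layers + 1`.
#' @param sparsity nonzeros per sample; must not exceed the per-class block.
#' @param smoothness AR(1) coefficient correlating neighbouring atoms' codes.
#' @param snr_db default signal-to-noise ratio (dB) used by the samplers.
#' @param orthonormal if `TRUE`, dictionaries with `K_m <= dims[m]` are
#'   orthonormalised (QR), giving an identifiable planted model for
#'   recovery studies; default leaves atoms at random unit-sphere positions.
#' @param activation between-layer activation of the planted stack.
#' @param seed RNG seed; identical seeds give identical models.
#' @return object of class `dd_planted`.
#' @export
plant_model <- function(n_classes = 3L, n_layers = 2L,
                        dims = c(64L, 48L, 36L), sparsity = 5L,
                        smoothness = 0, snr_db = 20, orthonormal = FALSE,
                        activation = "relu", seed = 0L) {
  if (n_classes < 2L) abort("`n_classes` must be >= 2")
  if (length(dims) != n_layers + 1L) abort("`dims` must have length n_layers + 1")
  K_M <- dims[length(dims)]
  block_size <- K_M %/% n_classes
  if (sparsity > block_size) abort("`sparsity` exceeds the per-class atom block")
  dicts <- with_seed(seed, {
    lapply(seq_len(n_layers), function(m) {
      D <- matrix(rnorm(dims[m] * dims[m + 1]), dims[m], dims[m + 1])
      if (orthonormal && dims[m + 1] <= dims[m]) {
        qr.Q(qr(D))
      } else {
        D / rep(sqrt(colSums(D^2)), each = dims[m])
      }
    })
  })
  cuts <- floor(seq(0, K_M, length.out = n_classes + 1))
  blocks <- lapply(seq_len(n_classes), function(ci) (cuts[ci] + 1):cuts[ci + 1])
  structure(list(stack = layer_stack(dicts, activation = activation),
                 class_blocks = blocks,
                 n_classes = as.integer(n_classes),
                 sparsity = as.integer(sparsity),
                 smoothness = smoothness,
                 snr_db = snr_db,
                 dims = as.integer(dims),
                 seed = as.integer(seed)),
            class = "dd_planted")
}

# Draw the ground-truth code matrix for `n_per_class` samples per class.
draw_codes <- function(pm, n_per_class) {
  K_M <- pm$dims[length(pm$dims)]
  N <- n_per_class * pm$n_classes
  B <- matrix(0, K_M, N)
  labels <- integer(N)
  i <- 0L
  for (ci in seq_len(pm$n_classes)) {
    block <- pm$class_blocks[[ci]]
    for (s in seq_len(n_per_class)) {
      i <- i + 1L
      labels[i] <- ci - 1L
      # latent AR(1) over the ordered block atoms
      g <- numeric(length(block))
      g[1] <- rnorm(1)
      if (length(block) > 1) {
        for (t in 2:length(block)) {
          g[t] <- pm$smoothness * g[t - 1] +
            sqrt(1 - pm$smoothness^2) * rnorm(1)
        }
      }
      supp <- sample(seq_along(block), pm$sparsity)
      # non-negative coefficients: class-mean codes sit on the class block,
      # matching the ReLU decode semantics and keeping classes linearly
      # decodable from their codes
      B[block[supp], i] <- 0.5 + abs(g[supp])
    }
  }
  list(B = B, labels = labels)
}

#' Sample a synthetic feature dataset from a planted model
#'
#' Draws per-class sparse codes, decodes them through the planted stack and
#' adds i.i.d. Gaussian noise scaled to the requested SNR.
#'
#' @param pm a `dd_planted` model.
#' @param n_per_class samples per class.
#' @param seed RNG seed.
#' @param snr_db signal-to-noise ratio in dB; `Inf` for noise-free data.
#'   Defaults to the value planted in `pm`.
#' @return `dd_features` object with extra elements `true_codes`,
#'   `planted` (the model) and `snr_db_empirical`.
#' @export
sample_features <- function(pm, n_per_class = 50L, seed = 0L,
                            snr_db = pm$snr_db) {
  out <- with_seed(seed, {
    drawn <- draw_codes(pm, n_per_class)
    Z0 <- decode_stack(pm$stack, drawn$B)
    if (is.finite(snr_db)) {
      sigma <- sqrt(mean(Z0^2) / 10^(snr_db / 10))
      noise <- matrix(rnorm(length(Z0), sd = sigma), nrow(Z0), ncol(Z0))
    } else {
      noise <- Z0 * 0
    }
    list(drawn = drawn, Z0 = Z0, noise = noise)
  })
  Z <- out$Z0 + out$noise
  emp_snr <- if (sum(out$noise^2) > 0) {
    10 * log10(mean(out$Z0^2) / mean(out$noise^2))
  } else {
    Inf
  }
  structure(list(values = Z,
                 sample_ids = sprintf("synth_%04d", seq_len(ncol(Z))),
                 labels = out$drawn$labels,
                 classes = sprintf("class_%d", seq_len(pm$n_classes) - 1L),
                 split = rep("unassigned", ncol(Z)),
                 true_codes = out$drawn$B,
                 planted = pm,
                 snr_db_empirical = emp_snr),
            class = "dd_features")
}

# Deterministic blob centre for atom j inside an image of side `sz`,
# kept inside the central ellipse.
atom_position <- function(j, sz) {
  gx <- ((j * 37L) %% 29L) / 29
  gy <- ((j * 61L) %% 31L) / 31
  c(y = sz * (0.25 + 0.5 * gy), x = sz * (0.25 + 0.5 * gx))
}

#' Render a synthetic image dataset to PNG files plus a manifest
#'
#' Each sample's sparse code is rendered as a smooth background ellipse (a
#' cartoon "brain") plus one Gaussian blob per active atom: blob position is
#' a deterministic function of the atom index, amplitude follows the
#' coefficient, and blob size/eccentricity differ by class. Because classes
#' use disjoint atom blocks, the rendered classes are separable by design —
#' the renderer exercises the pipeline, it does not simulate MRI physics.
#'
#' @param pm a `dd_planted` model.
#' @param n_per_class images per class.
#' @param image_size square image side in pixels (>= 32).
#' @param seed RNG seed; identical seeds give byte-identical files.
#' @param out_dir directory for the PNG files and `manifest.csv`.
#' @return the manifest tibble (invisibly also written to
#'   `out_dir/manifest.csv`), with the planted model in attribute `truth`.
#' @export
sample_images <- function(pm, n_per_class = 50L, image_size = 64L,
                          seed = 0L, out_dir) {
  if (image_size < 32L) abort("`image_size` must be >= 32")
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) abort(sprintf("cannot create output directory '%s'", out_dir))
  }
  drawn <- with_seed(seed, draw_codes(pm, n_per_class))
  sz <- as.integer(image_size)
  yy <- matrix(seq_len(sz), sz, sz)
  xx <- t(yy)
  cy <- (sz + 1) / 2
  # smooth background ellipse
  ell <- ((yy - cy) / (0.42 * sz))^2 + ((xx - cy) / (0.36 * sz))^2
  background <- 0.35 * exp(-ell^2)
  paths <- character(ncol(drawn$B))
  labels <- character(ncol(drawn$B))
  for (i in seq_len(ncol(drawn$B))) {
    cls <- drawn$labels[i]
    img <- background
    active <- which(drawn$B[, i] != 0)
    sig_y <- sz * (0.030 + 0.022 * cls) # class-specific blob size
    sig_x <- sig_y * (1 + 0.6 * cls)    # and eccentricity
    for (j in active) {
      pos <- atom_position(j, sz)
      amp <- 0.45 * min(abs(drawn$B[j, i]), 2)
      img <- img + amp * exp(-(((yy - pos["y"]) / sig_y)^2 +
                                 ((xx - pos["x"]) / sig_x)^2) / 2)
    }
    img <- pmin(pmax(img, 0), 1)
    label <- sprintf("class_%d", cls)
    fname <- sprintf("%s_%04d.png", label, i)
    png::writePNG(img, file.path(out_dir, fname))
    paths[i] <- file.path(out_dir, fname)
    labels[i] <- label
  }
  manifest <- tibble::tibble(path = paths, label = labels, split = "unassigned")
  write_manifest(manifest, file.path(out_dir, "manifest.csv"))
  attr(manifest, "truth") <- pm
  invisible(manifest)
}
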