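# Image loading, the patch/flatten feature front-end, manifest handling and
# model serialisation.

DD_MODEL_FORMAT <- 1L

#' Feature-extractor specification
#'
#' Controls how a grayscale image becomes a feature vector. `"flatten"`
#' resizes to `resize_to`, bilinearly downsamples to `downsample_to` and
#' vectorises row-major. `"patchpool"` resizes to `resize_to`, slides a
#' `patch_size` x `patch_size` window at `patch_stride`, vectorises each
#' patch row-major, and pools the per-position mean and standard deviation of
#' the patch vectors on a fixed `pool_grid` x `pool_grid` spatial grid (patch
#' assigned to a cell by its centre). `"external"` delegates to a caller
#' supplied `extractor(image_matrix) -> numeric vector` hook, the slot where
#' e.g. pretrained-CNN features would plug in.
#'
#' @param kind `"flatten"`, `"patchpool"` or `"external"`.
#' @param resize_to target (height, width) in pixels before extraction.
#' @param downsample_to (height, width) for the flattened representation.
#' @param patch_size square patch side in pixels.
#' @param patch_stride patch step in pixels.
#' @param pool_grid pooling grid side g.
#' @param extractor function for `kind = "external"`.
#' @return an object of class `dd_feature_spec`.
#' @export
feature_spec <- function(kind = c("flatten", "patchpool", "external"),
                         resize_to = c(227L, 227L),
                         downsample_to = c(32L, 32L),
                         patch_size = 3L, patch_stride = 1L,
                         pool_grid = 4L, extractor = NULL) {
  kind <- match.arg(kind)
  resize_to <- as.integer(resize_to)
  if (patch_size < 1L) abort("`patch_size` must be >= 1")
  if (any(resize_to < patch_size)) abort("`resize_to` must be at least `patch_size`")
  if (kind == "external" && !is.function(extractor)) {
    abort("`extractor` function required for kind = 'external'")
  }
  structure(list(kind = kind, resize_to = resize_to,
                 downsample_to = as.integer(downsample_to),
                 patch_size = as.integer(patch_size),
                 patch_stride = as.integer(patch_stride),
                 pool_grid = as.integer(pool_grid),
                 extractor = extractor),
            class = "dd_feature_spec")
}

# Bilinear resize of an H x W matrix (EBImage backend).
resize_bilinear <- function(m, h, w) {
  if (nrow(m) == h && ncol(m) == w) return(m)
  out <- EBImage::imageData(EBImage::resize(EBImage::Image(m), w = h, h = w))
  matrix(out, nrow = h, ncol = w)
}

#' Load an image file as a grayscale intensity matrix
#'
#' Reads PNG/JPEG (via EBImage) or a single-slice NIfTI volume (via RNifti).
#' RGB images are collapsed to luminance with Rec.601 weights
#' (0.299, 0.587, 0.114). Intensities outside `[0, 1]` (e.g. raw NIfTI) are
#' linearly rescaled to `[0, 1]`; 8/16-bit PNG/JPEG arrive already scaled by
#' the reader, so a constant all-white image maps to 1.
#'
#' @param path file path; extension decides the reader.
#' @return list of class `dd_image` with `pixels` (H x W matrix in `[0,1]`),
#'   `label` (NA) and `source_path`.
#' @export
load_image <- function(path) {
  if (!file.exists(path)) abort(sprintf("cannot read image: '%s' does not exist", path))
  lower <- tolower(path)
  if (grepl("\\.nii(\\.gz)?$", lower)) {
    vol <- RNifti::readNifti(path)
    a <- as.array(vol)
    if (length(dim(a)) == 3L) {
      if (dim(a)[3] > 1L) {
        abort(sprintf("'%s' is a 3-D volume; extract a single slice before loading", path))
      }
      a <- a[, , 1]
    }
    px <- as.matrix(a)
  } else {
    img <- tryCatch(EBImage::readImage(path),
                    error = function(e) abort(sprintf("cannot read image '%s': %s",
                                                      path, conditionMessage(e))))
    a <- EBImage::imageData(img)
    if (length(dim(a)) == 3L) {
      nch <- dim(a)[3]
      px <- if (nch >= 3L) {
        0.299 * a[, , 1] + 0.587 * a[, , 2] + 0.114 * a[, , 3]
      } else {
        a[, , 1]
      }
    } else {
      px <- a
    }
    px <- t(px) # EBImage stores width-major; convert to rows = image rows
  }
  check_finite(px, "pixels")
  if (min(px) < 0 || max(px) > 1) {
    rng <- range(px)
    px <- if (diff(rng) > 0) (px - rng[1]) / diff(rng) else px * 0
  }
  if (nrow(px) < 8L || ncol(px) < 8L) abort("image must be at least 8x8 pixels")
  structure(list(pixels = px, label = NA_character_, source_path = path),
            class = "dd_image")
}

#' Extract a feature vector from an image
#'
#' Deterministic: identical image and spec give a bit-identical vector. See
#' [feature_spec()] for the three extraction kinds.
#'
#' @param img a `dd_image` or plain H x W matrix.
#' @param spec a `dd_feature_spec`.
#' @return numeric feature vector.
#' @export
extract_features <- function(img, spec = feature_spec()) {
  px <- if (inherits(img, "dd_image")) img$pixels else as.matrix(img)
  if (spec$kind == "external") return(as.numeric(spec$extractor(px)))
  px <- resize_bilinear(px, spec$resize_to[1], spec$resize_to[2])
  if (spec$kind == "flatten") {
    small <- resize_bilinear(px, spec$downsample_to[1], spec$downsample_to[2])
    return(as.vector(t(small))) # row-major
  }
  # patchpool
  p <- spec$patch_size
  st <- spec$patch_stride
  H <- nrow(px); W <- ncol(px)
  if (H < p || W < p) abort("image smaller than `patch_size` after resize")
  ys <- seq(1L, H - p + 1L, by = st)
  xs <- seq(1L, W - p + 1L, by = st)
  g <- spec$pool_grid
  # cell index for a patch by its centre
  cell_of <- function(centre, extent) pmin(g, floor((centre - 0.5) / extent * g) + 1L)
  nvec <- p * p
  sums <- array(0, c(g, g, nvec))
  sqs <- array(0, c(g, g, nvec))
  cnt <- matrix(0L, g, g)
  for (y in ys) {
    gy <- cell_of(y + (p - 1) / 2, H)
    for (x in xs) {
      gx <- cell_of(x + (p - 1) / 2, W)
      v <- as.vector(t(px[y:(y + p - 1L), x:(x + p - 1L)]))
      sums[gy, gx, ] <- sums[gy, gx, ] + v
      sqs[gy, gx, ] <- sqs[gy, gx, ] + v * v
      cnt[gy, gx] <- cnt[gy, gx] + 1L
    }
  }
  feats <- numeric(0)
  for (gy in seq_len(g)) {
    for (gx in seq_len(g)) {
      n <- cnt[gy, gx]
      if (n == 0L) {
        feats <- c(feats, numeric(2 * nvec))
      } else {
        mu <- sums[gy, gx, ] / n
        var <- pmax(sqs[gy, gx, ] / n - mu^2, 0)
        feats <- c(feats, mu, sqrt(var))
      }
    }
  }
  feats
}

#' Count sliding patches
#'
#' Number of `patch_size` x `patch_size` windows at `patch_stride` in an
#' H x W image; convenience used by tests and documentation examples.
#' @param h,w image height and width after resize.
#' @param patch_size,patch_stride window side and step.
#' @return integer patch count.
#' @export
n_patches <- function(h, w, patch_size, patch_stride = 1L) {
  length(seq(1L, h - patch_size + 1L, by = patch_stride)) *
    length(seq(1L, w - patch_size + 1L, by = patch_stride))
}

#' Read / write an image manifest
#'
#' A manifest is a CSV with header `path,label,split` mapping each image file
#' to its class label and its `train` / `test` / `unassigned` split.
#'
#' @param path CSV file path.
#' @return tibble with columns `path`, `label`, `split`.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) abort(sprintf("manifest '%s' does not exist", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("path", "label") %in% names(df))) {
    abort("manifest must have columns `path` and `label`")
  }
  if (is.null(df$split)) df$split <- "unassigned"
  validate_manifest(tibble::as_tibble(df[, c("path", "label", "split")]))
}

#' @rdname read_manifest
#' @param manifest tibble with columns `path`, `label`, `split`.
#' @export
write_manifest <- function(manifest, path) {
  manifest <- validate_manifest(manifest)
  utils::write.csv(manifest, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

validate_manifest <- function(manifest) {
  if (nrow(manifest) == 0L) abort("manifest has no rows")
  if (any(!nzchar(manifest$path))) abort("manifest paths must be non-empty")
  bad <- setdiff(unique(manifest$split), c("train", "test", "unassigned"))
  if (length(bad)) abort(sprintf("unknown split value(s): %s", paste(bad, collapse = ", ")))
  tibble::as_tibble(manifest)
}

#' Build the feature matrix from a manifest
#'
#' Loads every image in manifest order, extracts features, and maps labels to
#' 0-based class indices by sorted class name.
#'
#' @param manifest tibble from [read_manifest()] (or built in code).
#' @param spec a [feature_spec()].
#' @return object of class `dd_features`: list with `values` (c x N matrix,
#'   one column per sample), `sample_ids`, `labels` (0-based integers),
#'   `classes` (sorted class names) and `split`.
#' @export
build_feature_matrix <- function(manifest, spec = feature_spec()) {
  manifest <- validate_manifest(manifest)
  classes <- sort(unique(as.character(manifest$label)))
  cols <- lapply(manifest$path, function(p) extract_features(load_image(p), spec))
  lens <- lengths(cols)
  if (length(unique(lens)) != 1L) abort("internal: mixed feature lengths")
  values <- matrix(unlist(cols), nrow = lens[1])
  check_finite(values, "features")
  structure(list(values = values,
                 sample_ids = as.character(manifest$path),
                 labels = match(as.character(manifest$label), classes) - 1L,
                 classes = classes,
                 split = manifest$split),
            class = "dd_features")
}

#' @export
print.dd_features <- function(x, ...) {
  cat(sprintf("<dd_features> %d features x %d samples, %d classes\n",
              nrow(x$values), ncol(x$values), length(x$classes)))
  invisible(x)
}

#' Save / load a trained model
#'
#' The archive stores every array bit-exactly together with metadata (class
#' names, configuration, layer count, format version). Loading a file with a
#' different format version, or a corrupt file, raises an explicit error.
#'
#' @param model a `dd_model` from [dd_train()].
#' @param path destination file.
#' @return `load_model` returns the restored `dd_model`.
#' @export
save_model <- function(model, path) {
  if (!inherits(model, "dd_model")) abort("`model` must be a dd_model")
  payload <- list(format_version = DD_MODEL_FORMAT,
                  meta = list(classes = model$classes,
                              n_layers = model$stack$n_layers,
                              package_version = as.character(packageVersion("deepdict"))),
                  model = model)
  saveRDS(payload, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  payload <- tryCatch(readRDS(path),
                      error = function(e) abort(sprintf("cannot read model archive '%s': %s",
                                                        path, conditionMessage(e))))
  if (!is.list(payload) || is.null(payload$format_version)) {
    abort(sprintf("'%s' is not a model archive", path))
  }
  if (payload$format_version != DD_MODEL_FORMAT) {
    abort(sprintf("model format version %s not supported (expected %d)",
                  payload$format_version, DD_MODEL_FORMAT))
  }
  payload$model
}
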