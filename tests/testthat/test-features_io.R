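make_png <- function(m, path = tempfile(fileext = ".png")) {
  png::writePNG(m, path)
  path
}

test_that("load_image reads PNG, converts RGB by Rec.601 luminance and rescales", {
  # constant all-white image maps to 1.0 everywhere
  p <- make_png(matrix(1, 8, 8))
  img <- load_image(p)
  expect_s3_class(img, "dd_image")
  expect_equal(img$pixels, matrix(1, 8, 8))
  # all-zero image stays zero
  expect_equal(load_image(make_png(matrix(0, 8, 8)))$pixels, matrix(0, 8, 8))
  # pure red -> luminance 0.299
  rgb <- array(0, c(8, 8, 3))
  rgb[, , 1] <- 1
  img_r <- load_image(make_png(rgb))
  expect_equal(img_r$pixels, matrix(0.299, 8, 8), tolerance = 1e-6)
  expect_error(load_image(file.path(tempdir(), "no_such_file.png")), "exist")
})

test_that("load_image handles NIfTI slices and rejects volumes", {
  vol <- array(seq(0, 1000, length.out = 8 * 8 * 2), c(8, 8, 2))
  p3 <- tempfile(fileext = ".nii.gz")
  RNifti::writeNifti(RNifti::asNifti(vol), p3)
  expect_error(load_image(p3), "slice")
  slice <- matrix(seq(0, 500, length.out = 64), 8, 8)
  p2 <- tempfile(fileext = ".nii.gz")
  RNifti::writeNifti(RNifti::asNifti(slice), p2)
  px <- load_image(p2)$pixels
  expect_gte(min(px), 0)
  expect_lte(max(px), 1)
  expect_equal(dim(px), c(8, 8))
})

test_that("flatten extraction is a pure row-major vectorisation at native size", {
  set.seed(70)
  m <- matrix(runif(64), 8, 8)
  spec <- feature_spec("flatten", resize_to = c(8, 8), downsample_to = c(8, 8))
  v <- extract_features(m, spec)
  expect_length(v, 64)
  expect_equal(matrix(v, 8, 8, byrow = TRUE), m) # reshape inverse recovers image
  # purity: identical input and spec give bit-identical output
  expect_identical(v, extract_features(m, spec))
  # constant image flattens to a constant vector
  vc <- extract_features(matrix(0.5, 16, 16),
                         feature_spec("flatten", resize_to = c(8, 8),
                                      downsample_to = c(4, 4)))
  expect_equal(vc, rep(0.5, 16))
})

test_that("patchpool pools patch statistics on the spatial grid", {
  spec <- feature_spec("patchpool", resize_to = c(6, 6), patch_size = 3,
                       patch_stride = 1, pool_grid = 2)
  expect_equal(n_patches(6, 6, 3, 1), 16) # (6-3+1)^2
  # constant image: every pooled standard deviation is zero
  v <- extract_features(matrix(0.7, 6, 6), spec)
  expect_length(v, 2 * 2 * 2 * 9) # g^2 cells x (mean, sd) x 9 patch positions
  sds <- v[rep(c(FALSE, TRUE), each = 9, times = 4)]
  expect_equal(sds, rep(0, 36))
  means <- v[rep(c(TRUE, FALSE), each = 9, times = 4)]
  expect_equal(means, rep(0.7, 36))
  # ramp image produces deterministic, finite features
  ramp <- matrix(seq(0, 1, length.out = 36), 6, 6)
  v2 <- extract_features(ramp, spec)
  expect_true(all(is.finite(v2)))
  expect_identical(v2, extract_features(ramp, spec))
  expect_error(extract_features(matrix(1, 8, 8),
                                feature_spec("patchpool", resize_to = c(2, 2),
                                             patch_size = 3)),
               "patch_size")
})

test_that("external extractor hook is honoured", {
  spec <- feature_spec("external", extractor = function(px) c(mean(px), sd(px)))
  v <- extract_features(matrix(1:16 / 16, 4, 4), spec)
  expect_length(v, 2)
  expect_equal(v[1], mean(1:16 / 16))
})

test_that("manifest round-trips preserve rows and order", {
  man <- tibble::tibble(path = c("a.png", "b.png", "c.png"),
                        label = c("tumor", "healthy", "tumor"),
                        split = c("train", "test", "unassigned"))
  f <- tempfile(fileext = ".csv")
  write_manifest(man, f)
  back <- read_manifest(f)
  expect_equal(as.data.frame(back), as.data.frame(man))
  expect_error(write_manifest(man[0, ], tempfile()), "no rows")
  bad <- man
  bad$split[1] <- "validation"
  expect_error(write_manifest(bad, tempfile()), "split")
})

test_that("build_feature_matrix maps labels by sorted class name and keeps order", {
  dir <- withr::local_tempdir()
  paths <- vapply(1:3, function(i) {
    make_png(matrix(i / 4, 8, 8), file.path(dir, sprintf("im%d.png", i)))
  }, "")
  man <- tibble::tibble(path = paths[c(1, 2, 3)],
                        label = c("zeta", "alpha", "mid"),
                        split = "unassigned")
  fm <- build_feature_matrix(man, feature_spec("flatten", resize_to = c(8, 8),
                                               downsample_to = c(4, 4)))
  expect_s3_class(fm, "dd_features")
  expect_equal(fm$classes, c("alpha", "mid", "zeta"))
  expect_equal(fm$labels, c(2L, 0L, 1L)) # sorted-class indices, row order kept
  expect_equal(ncol(fm$values), 3)
  # duplicated path gives identical columns
  man2 <- tibble::tibble(path = rep(paths[1], 2), label = "a", split = "train")
  fm2 <- build_feature_matrix(man2, feature_spec("flatten", resize_to = c(8, 8),
                                                 downsample_to = c(4, 4)))
  expect_identical(fm2$values[, 1], fm2$values[, 2])
  expect_error(build_feature_matrix(man[0, ]), "no rows")
})

test_that("model archives round-trip bit-exactly and reject bad files", {
  fx <- tiny_planted_fixture(71)
  cfg <- dd_config(n_layers = 2, n_atoms = c(12, 9), epochs = 3,
                   init_sweeps = 3, seed = 71)
  model <- dd_train(fx$ds, cfg = cfg)
  f <- tempfile(fileext = ".rds")
  save_model(model, f)
  back <- load_model(f)
  expect_identical(back$stack$dictionaries, model$stack$dictionaries)
  expect_identical(back$theta, model$theta)
  expect_identical(back$B, model$B)
  B_new <- matrix(rnorm(9 * 2), 9, 2)
  expect_identical(decode_stack(back$stack, B_new),
                   decode_stack(model$stack, B_new))
  # metadata records the layer count
  payload <- readRDS(f)
  expect_equal(payload$meta$n_layers, 2L)
  # corrupt file errors, version mismatch errors
  bad <- tempfile(fileext = ".rds")
  writeLines("not an archive", bad)
  expect_error(load_model(bad), "archive")
  payload$format_version <- 999L
  saveRDS(payload, f)
  expect_error(load_model(f), "version")
})
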