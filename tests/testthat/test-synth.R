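# Synthetic patch generator: shapes, textures, datasets.

test_that("ellipse-free parameters rasterise a disc of the expected area", {
  m <- generate_mask(shape_params(base_radius = 10), seed = 1)
  expect_lt(abs(sum(m) - pi * 100) / (pi * 100), 0.05)
  expect_equal(ccvnuclei:::count_components4(m), 1L)
  expect_false(ccvnuclei:::mask_touches_border(m))
})

test_that("lobes and radial noise lengthen the traced contour", {
  disc <- generate_mask(shape_params(10), seed = 1)
  lobed <- generate_mask(shape_params(10, boundary_noise_amp = 3,
                                      n_lobes = 6L), seed = 1)
  expect_gt(contour_perimeter(trace_contour(lobed)),
            contour_perimeter(trace_contour(disc)))
})

test_that("mask generation is deterministic and validates fit", {
  sp <- shape_params(12, eccentricity = 1.3, boundary_noise_amp = 2,
                     n_lobes = 5L, center_jitter = 2)
  expect_identical(generate_mask(sp, seed = 7), generate_mask(sp, seed = 7))
  expect_error(generate_mask(shape_params(25, eccentricity = 1.4), seed = 1),
               "fit")
  expect_error(shape_params(10, boundary_noise_amp = 10), "smaller")
})

test_that("texture rendering hits the requested means and is reproducible", {
  m <- generate_mask(shape_params(10), seed = 1)
  # zero noise: exactly two grey values
  tex0 <- texture_params(noise_sd = 0)
  img0 <- generate_texture(m, tex0, seed = 1)
  expect_setequal(unique(as.numeric(img0)), c(90, 200))
  # noisy: within-mask mean stays within the standard-error bound
  tex <- texture_params(nucleus_mean_gray = 90, noise_sd = 10,
                        chromatin_grain = 2)
  img <- generate_texture(m, tex, seed = 2)
  expect_lt(abs(mean(img[m == 1]) - 90), 2 * 10 / sqrt(sum(m)) + 1e-9)
  expect_identical(img, generate_texture(m, tex, seed = 2))
  expect_true(all(img >= 0 & img <= 255))
  expect_error(generate_texture(matrix(0, 8, 8), tex, seed = 1), "empty")
})

test_that("datasets are balanced, uniquely labelled and seed-stable", {
  ds <- generate_dataset(5, seed = 3)
  expect_length(ds, 10L)
  expect_equal(as.numeric(table(patch_labels(ds))), c(5, 5))
  expect_false(anyDuplicated(patch_ids(ds)) > 0)
  ds2 <- generate_dataset(5, seed = 3)
  expect_identical(ds, ds2)
})

test_that("default class presets separate mean CCV", {
  ds <- generate_dataset(30, seed = 11)
  ccvs <- vapply(ds, function(p) ccv_of_mask(p$mask), integer(1))
  lab <- patch_labels(ds)
  expect_gt(mean(ccvs[lab == "abnormal"]), mean(ccvs[lab == "normal"]))
})

test_that("contour perimeter does not decrease with irregularity", {
  mean_perim <- function(amp, lobes) {
    mean(vapply(1:50, function(s) {
      m <- generate_mask(shape_params(10, boundary_noise_amp = amp,
                                      n_lobes = lobes), seed = s)
      contour_perimeter(trace_contour(m))
    }, numeric(1)))
  }
  p0 <- mean_perim(0, 0L)
  p1 <- mean_perim(1.5, 4L)
  p2 <- mean_perim(3, 4L)
  p3 <- mean_perim(3, 8L)
  expect_true(p0 <= p1 && p1 <= p2)
  expect_true(p2 <= p3)
})

test_that("with irregularity off the classes are shape-indistinguishable", {
  smooth <- default_class_params("abnormal")
  smooth$shape$boundary_noise_amp <- 0
  smooth$shape$n_lobes <- 0L
  smooth$shape$base_radius <- 12
  smooth$shape$eccentricity <- 1.15
  ds <- generate_dataset(40, normal = default_class_params("normal"),
                         abnormal = smooth, seed = 5)
  ccvs <- vapply(ds, function(p) ccv_of_mask(p$mask), integer(1))
  lab <- patch_labels(ds)
  d <- abs(mean(ccvs[lab == "abnormal"]) - mean(ccvs[lab == "normal"]))
  pooled_se <- sqrt(var(ccvs[lab == "abnormal"]) / 40 +
                      var(ccvs[lab == "normal"]) / 40)
  expect_lt(d, 3 * pooled_se + 1e-9)
})

test_that("patch sets round-trip through the PNG/CSV layout", {
  dir <- tempfile("patchset")
  on.exit(unlink(dir, recursive = TRUE), add = TRUE)
  ds <- generate_dataset(2, seed = 9)
  write_patch_set(ds, dir)
  expect_true(file.exists(file.path(dir, "labels.csv")))
  back <- read_patch_set(dir)
  expect_equal(patch_ids(back), patch_ids(ds))
  expect_equal(patch_labels(back), patch_labels(ds))
  expect_identical(back[[1]]$mask, ds[[1]]$mask)
  # 8-bit quantisation: grey values within half a level
  expect_lt(max(abs(back[[1]]$gray - ds[[1]]$gray)), 0.51)
})
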