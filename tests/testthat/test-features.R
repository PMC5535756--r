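# Feature bank: intensity, morphology, GLCM, LBP, Tamura.

test_that("intensity features match a direct per-pixel recomputation", {
  set.seed(2)
  gray <- matrix(runif(64 * 64, 0, 255), 64)
  mask <- make_disc_mask(8)
  fv <- intensity_features(gray, mask)
  x <- as.numeric(gray)
  expect_equal(unname(fv["int_patch_mean"]), mean(x))
  expect_equal(unname(fv["int_patch_median"]), median(x))
  expect_equal(unname(fv["int_patch_variance"]), mean((x - mean(x))^2))
  xm <- gray[mask == 1]
  expect_equal(unname(fv["int_nuc_mean"]), mean(xm))
  expect_equal(unname(fv["int_nuc_skewness"]),
               mean((xm - mean(xm))^3) / mean((xm - mean(xm))^2)^1.5)
  # constant patch: zero spread, defined skewness/kurtosis
  fc <- intensity_features(matrix(100, 64, 64), mask)
  expect_equal(unname(fc[c("int_patch_mean", "int_patch_variance",
                           "int_patch_skewness")]), c(100, 0, 0))
  # two-valued patch in equal parts
  half <- matrix(c(0, 255), 64, 64)
  expect_equal(unname(intensity_features(half, mask)["int_patch_mean"]),
               127.5)
})

test_that("morphology features behave on canonical shapes", {
  sq <- make_square_mask(10L)
  fv <- morphology_features(sq)
  expect_equal(unname(fv["morph_area"]), 100)
  expect_equal(unname(fv["morph_extent"]), 1)
  expect_gt(unname(fv["morph_solidity"]), 0.95)
  full <- matrix(1, 64, 64)
  expect_equal(unname(morphology_features(full)["morph_nc_ratio"]), 1)
  disc <- make_disc_mask(10)
  expect_lt(abs(morphology_features(disc)["morph_equiv_diameter"] - 20) / 20,
            0.05)
  expect_lt(unname(morphology_features(disc)["morph_eccentricity"]), 0.3)
  expect_error(morphology_features(matrix(0, 8, 8)), "empty")
})

test_that("GLCM statistics are exact on hand-built matrices", {
  # single-entry GLCM
  P1 <- matrix(0, 4, 4)
  P1[2, 2] <- 1
  s1 <- glcm_stats(P1)
  expect_equal(unname(s1[c("ASM", "ENT", "CON")]), c(1, 0, 0))
  # uniform 2x2 GLCM
  P2 <- matrix(0.25, 2, 2)
  s2 <- glcm_stats(P2)
  expect_equal(unname(s2["ASM"]), 0.25)
  expect_equal(unname(s2["ENT"]), log(4))
  # constant image: correlation undefined, flagged 0
  sc <- glcm_stats(glcm_matrix(matrix(7, 8, 8), levels = 4))
  expect_equal(unname(sc["COR"]), 0)
  expect_true(attr(sc, "cor_undefined"))
})

test_that("GLCM matches the nested-loop pixel-pair oracle", {
  set.seed(10)
  offsets <- list(c(1L, 0L), c(1L, -1L), c(0L, -1L), c(-1L, -1L))
  for (case in 1:100) {
    n <- sample(3:8, 1)
    gray <- matrix(sample(0:255, n * n, replace = TRUE), n)
    off <- offsets[[sample(4, 1)]]
    levels <- sample(c(4L, 8L, 16L), 1)
    expect_equal(glcm_matrix(gray, levels, off),
                 oracle_glcm(gray, levels, off))
  }
})

test_that("LBP histograms are one-hot on constants and sum to 1 per cell", {
  hc <- lbp_histogram(matrix(50, 64, 64))
  expect_length(hc, 16L * 256L)
  # constant image: every pixel codes 0, each cell histogram is one-hot
  expect_equal(sum(hc), 16)
  expect_equal(unname(hc[seq(1, 16 * 256, by = 256)]), rep(1, 16))
  set.seed(5)
  h <- lbp_histogram(matrix(runif(64 * 64, 0, 255), 64))
  sums <- vapply(1:16, function(i) sum(h[(i - 1) * 256 + 1:256]), numeric(1))
  expect_equal(sums, rep(1, 16))
  hu <- lbp_histogram(matrix(runif(64 * 64, 0, 255), 64), mode = "uniform")
  expect_length(hu, 16L * 59L)
  expect_error(lbp_histogram(matrix(0, 30, 30)), "divisible")
})

test_that("LBP codes match a hand-unrolled oracle on a toy image", {
  set.seed(6)
  img <- matrix(sample(0:255, 25), 5)
  # oracle: code of the centre pixel (3,3) from its 8 neighbours, bits
  # clockwise from top-left with weights 1,2,4,...,128
  nb <- c(img[2, 2], img[2, 3], img[2, 4], img[3, 4],
          img[4, 4], img[4, 3], img[4, 2], img[3, 2])
  code_oracle <- sum(2^(0:7) * (img[3, 3] < nb))
  p <- ccvnuclei:::pad_replicate(img, 1L)
  codes <- matrix(0L, 5, 5)
  dirs <- list(c(-1, -1), c(-1, 0), c(-1, 1), c(0, 1),
               c(1, 1), c(1, 0), c(1, -1), c(0, -1))
  w <- 1L
  for (d in dirs) {
    codes <- codes + w * (img < p[1 + d[1] + 1:5, 1 + d[2] + 1:5])
    w <- w * 2L
  }
  expect_equal(codes[3, 3], code_oracle)
})

test_that("Tamura statistics rank canonical textures correctly", {
  expect_equal(unname(tamura_features(matrix(42, 64, 64))["tamura_contrast"]),
               0)
  checker <- function(block) {
    b <- matrix(0, 64, 64)
    idx <- (((row(b) - 1) %/% block) + ((col(b) - 1) %/% block)) %% 2
    b[idx == 1] <- 255
    b
  }
  coarse <- tamura_features(checker(16))
  fine <- tamura_features(checker(2))
  expect_gt(coarse["tamura_coarseness"], fine["tamura_coarseness"])
  stripes <- matrix(rep(c(0, 0, 255, 255), 16), 64, 64)
  set.seed(8)
  noise <- matrix(runif(64 * 64, 0, 255), 64)
  expect_gt(tamura_features(stripes)["tamura_directionality"],
            tamura_features(noise)["tamura_directionality"])
})

test_that("extractors are deterministic and consistent under translation", {
  ds <- generate_dataset(1, seed = 21)
  p <- ds[[1]]
  # build a patch with uniform background so a (2,2) shift is exact
  gray <- matrix(200, 64, 64)
  gray[p$mask == 1] <- p$gray[p$mask == 1]
  shift <- function(m, d) {
    out <- matrix(m[1, 1], 64, 64)
    out[(1 + d):64, (1 + d):64] <- m[1:(64 - d), 1:(64 - d)]
    out
  }
  gray2 <- shift(gray, 2L)
  mask2 <- shift(p$mask, 2L)
  expect_equal(intensity_features(gray, p$mask),
               intensity_features(gray2, mask2))
  expect_equal(glcm_features(gray), glcm_features(gray2))
  m1 <- morphology_features(p$mask)
  m2 <- morphology_features(mask2)
  keep <- setdiff(names(m1), "morph_centroid_offset")
  expect_equal(m1[keep], m2[keep])
})

test_that("every feature is finite on generator output", {
  ds <- generate_dataset(3, seed = 31)
  fs <- extract_all(ds)
  expect_true(all(is.finite(fs$values)))
})
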