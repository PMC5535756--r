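# Sparse-contribution feature selection.

test_that("row normalisation maps to [0,1] and is invertible", {
  v <- rbind(a = c(2, 4, 6), b = c(0, 0.5, 1), c = c(7, 7, 7))
  colnames(v) <- c("s1", "s2", "s3")
  nr <- normalize01(v)
  expect_equal(unname(nr$values["a", ]), c(0, 0.5, 1))
  expect_equal(unname(nr$values["b", ]), c(0, 0.5, 1))
  expect_true(nr$constant["c"])
  expect_equal(unname(nr$values["c", ]), c(0, 0, 0))
  # inverse transform recovers the input
  back <- nr$values["a", ] * (nr$row_minmax["a", "max"] -
                                nr$row_minmax["a", "min"]) +
    nr$row_minmax["a", "min"]
  expect_equal(unname(back), c(2, 4, 6), tolerance = 1e-12)
})

test_that("redundancy pruning drops correlated rows, keeps independents", {
  set.seed(61)
  base <- rnorm(50)
  v <- rbind(base, base, -base, rnorm(50))
  expect_equal(remove_redundant(v, 0.95), c(1L, 4L))
  # anticorrelated pair counts as redundant via |rho|
  expect_equal(remove_redundant(rbind(base, -base), 0.99), 1L)
  # independent rows survive a high threshold
  v2 <- matrix(rnorm(10 * 200), 10, 200)
  expect_equal(remove_redundant(v2, 0.99), 1:10)
  expect_error(remove_redundant(v2, 0), "rho_max")
})

test_that("contrast mapping satisfies the unit-range contract", {
  cm <- contrast_map(c(0, 1))
  expect_equal(cm$mu, 0.5)
  expect_equal(cm$sigma, 0.5)  # population SD
  expect_equal(cm$eps, 0)
  expect_equal(cm$x, c(-1, 1))
  expect_equal(contrast_map(rep(3, 5))$x, rep(0, 5))
  set.seed(62)
  for (i in 1:50) {
    row <- runif(sample(5:40, 1))
    cm <- contrast_map(row)
    expect_lte(max(abs(cm$x)), 1 + 1e-12)
    if (cm$eps > 0) {
      expect_equal(max(abs(cm$x)), 1)  # bound is tight when eps engaged
    }
  }
})

test_that("unit-circle contributions match the worked cases", {
  labels <- rep(c("normal", "abnormal"), each = 5)
  # normal at +0.8, abnormal at -0.8: C = 10 * (1 - 0.6) = 4
  x <- c(rep(0.8, 5), rep(-0.8, 5))
  expect_equal(feature_contribution(x, labels)$C, 4, tolerance = 1e-12)
  # x = 0 contributes nothing; x = +1 normal with s = +1 contributes 1
  x2 <- c(1, rep(0, 4), rep(-0.5, 5))
  r2 <- feature_contribution(x2, labels)
  expect_equal(r2$C, 1 + 5 * (1 - sqrt(0.75)), tolerance = 1e-12)
  # shared-sign class means are removed
  x3 <- c(rep(0.5, 5), rep(0.2, 5))
  expect_true(feature_contribution(x3, labels)$removed)
  # label swap leaves C invariant (s flips with the classes)
  swapped <- rep(c("abnormal", "normal"), each = 5)
  expect_equal(feature_contribution(x, swapped)$C,
               feature_contribution(x, labels)$C)
})

test_that("fitting recovers planted structure and drops the duplicate", {
  pl <- make_planted_fs(seed = 63)
  model <- sc_fit(pl$fs, pl$labels)
  expect_true(all(c("inf1", "inf2") %in% model$kept_names))
  expect_false("dup1" %in% model$kept_names)
  expect_true(all(diff(model$kept_indices) > 0))
  expect_true(model$k <= model$m1 && model$m1 <= model$m)
  # delta1 = +Inf: nothing survives
  expect_error(sc_fit(pl$fs, pl$labels, delta1 = Inf), "delta1")
  # delta1 = -Inf with pruning off: every sign-consistent feature kept
  loose <- sc_fit(pl$fs, pl$labels, rho_max = 1, delta1 = -Inf)
  expect_equal(loose$k, sum(loose$sign_ok))
})

test_that("transform reproduces fit-time output and sparsifies correctly", {
  pl <- make_planted_fs(seed = 64)
  model <- sc_fit(pl$fs, pl$labels, delta2 = 0.05)
  out1 <- sc_transform(model, pl$fs)
  out2 <- sc_transform(model, pl$fs)
  expect_identical(out1$values, out2$values)
  expect_true(all(abs(out1$values) <= 1))
  # delta2 = 0 zeroes nothing beyond exact zeros
  dense <- sc_transform(model, pl$fs, delta2 = 0)
  raw <- sc_transform(model, pl$fs, delta2 = -1)  # keep everything
  expect_equal(sum(dense$values == 0), sum(raw$values == 0))
  # zero count at delta2 = 0.05 matches a direct scan
  expect_equal(sum(out1$values == 0), sum(abs(raw$values) <= 0.05))
  # sparsity is non-decreasing in delta2
  z <- vapply(c(0, 0.05, 0.1, 0.3),
              function(d) sum(sc_transform(model, pl$fs, delta2 = d)$values == 0),
              numeric(1))
  expect_true(all(diff(z) >= 0))
  # mismatched feature rows are rejected
  bad <- pl$fs
  rownames(bad$values)[1] <- "renamed"
  expect_error(sc_transform(model, bad), "match")
})

test_that("planted informative features rank above the 90th percentile", {
  hits <- 0L
  for (s in 1:100) {
    pl <- make_planted_fs(n_per_class = 50, seed = s)
    model <- sc_fit(pl$fs, pl$labels, rho_max = 1, delta1 = -Inf)
    C <- model$contributions
    names(C) <- model$contribution_names
    C[is.na(C)] <- -Inf
    cut <- quantile(C[is.finite(C)], 0.9, names = FALSE, type = 1)
    if (all(C[c("inf1", "inf2")] >= cut)) hits <- hits + 1L
  }
  expect_gte(hits, 95L)
})

test_that("selection chain m >= m1 >= m2 = k holds on generator data", {
  ds <- generate_dataset(15, seed = 65)
  fs <- extract_all(ds, feature_config(groups = c("intensity", "morphology",
                                                  "glcm"), filter = FALSE))
  model <- sc_fit(fs, patch_labels(ds))
  expect_true(model$k == model$m2 && model$m2 <= model$m1 &&
                model$m1 <= model$m)
  sel <- sc_transform(model, fs)
  expect_equal(nrow(sel$values), model$k)
})
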