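# Concave-convex variation: tangent points, curve splitting, slopes,
# alternation counting, the class model and the adjustment weights.

test_that("tangent points hit the bounding box with first-index ties", {
  disc <- make_disc_mask(10, cx = 32, cy = 32)
  quad <- tangent_points(trace_contour(disc))
  expect_equal(unname(quad$left["col"]), 22)
  expect_equal(unname(quad$right["col"]), 42)
  expect_equal(unname(quad$top["row"]), 22)
  expect_equal(unname(quad$bottom["row"]), 42)
  sq <- trace_contour(make_square_mask(10L))
  qs <- tangent_points(sq)
  # tracing starts at the top-left corner: left and top tie there
  expect_equal(unname(qs$idx[c("left", "top")]), c(1L, 1L))
  expect_error(tangent_points(matrix(c(5, 5), 1, 2)), "degenerate")
})

test_that("curve splitting partitions the contour into four arcs", {
  ct <- trace_contour(make_disc_mask(10))
  quad <- tangent_points(ct)
  curves <- split_curves(ct, quad)
  expect_length(curves, 4L)
  lens <- vapply(curves, nrow, integer(1))
  expect_lte(max(lens) - min(lens), 4L)
  # concatenation (dropping duplicated endpoints) reproduces the contour
  recon <- do.call(rbind, lapply(curves, function(cv) cv[-nrow(cv), , drop = FALSE]))
  ord <- order(quad$idx)
  expect_equal(nrow(recon), nrow(ct))
  expect_setequal(paste(recon[, 1], recon[, 2]), paste(ct[, 1], ct[, 2]))
  # square: arcs are the four sides
  sq <- trace_contour(make_square_mask(10L))
  sq_curves <- split_curves(sq, tangent_points(sq))
  sides <- vapply(sq_curves, function(cv) {
    all(cv[, 1] == cv[1, 1]) || all(cv[, 2] == cv[1, 2])
  }, logical(1))
  expect_gte(sum(sides), 3L)  # the wrap-around arc may join two corners
})

test_that("curve sampling keeps endpoints at every interval", {
  cv <- cbind(col = 1:10, row = rep(1, 10))
  s2 <- sample_curve(cv, 2L)
  expect_equal(s2[, "col"], c(1, 3, 5, 7, 9, 10))
  expect_equal(sample_curve(cv, 1L), cv)
  expect_equal(sample_curve(cv, 50L)[, "col"], c(1, 10))
  expect_error(sample_curve(cv, 0L), "interval")
})

test_that("slope vectors follow the two-point slope formula", {
  s <- rbind(c(0, 0), c(2, 2), c(4, 8))
  expect_equal(slope_vector(s), c(1, 2))
  collinear <- cbind(0:5, (0:5) * 3)
  expect_equal(slope_vector(collinear), rep(3, 5))
  # vertical pairs are skipped
  vert <- rbind(c(2, 0), c(2, 5), c(4, 4))
  expect_equal(slope_vector(vert), c(2))
  expect_length(slope_vector(rbind(c(1, 1), c(1, 9))), 0L)
})

test_that("alternation counting matches the worked sign sequence", {
  expect_equal(sign_alternations(c(1, 1, -1, -1, 1, -1)), 3L)
  expect_equal(sign_alternations(rep(1, 6)), 0L)
  expect_equal(alternation_count(c(1, 2, 3, 4)), 0L)  # monotone slopes
  expect_equal(alternation_count(c(1, 2)), 0L)        # too short
  # zeros inherit the previous nonzero sign
  expect_equal(sign_alternations(c(1, 0, -1)), 1L)
  expect_equal(sign_alternations(c(0, 0, 1, -1)), 1L)
})

test_that("alternation counting equals the pair-scan oracle on random runs", {
  set.seed(81)
  for (i in 1:1000) {
    dk <- sample(c(-1, 0, 1), sample(2:14, 1), replace = TRUE)
    expect_equal(sign_alternations(dk), oracle_alternations(dk))
  }
})

test_that("contour CCV separates smooth from lobed shapes", {
  wins <- 0L
  for (s in 1:50) {
    ell <- generate_mask(shape_params(12, eccentricity = 1.5), seed = s)
    star <- generate_mask(shape_params(12, boundary_noise_amp = 3,
                                       n_lobes = 8L), seed = s)
    if (ccv_of_mask(ell) <= ccv_of_mask(star)) wins <- wins + 1L
  }
  expect_gte(wins, 45L)
})

test_that("CCV is translation-invariant, mirror-stable, zero for a diamond", {
  for (s in 1:5) {
    m <- generate_mask(shape_params(10, boundary_noise_amp = 2.5,
                                    n_lobes = 6L), seed = s)
    # exact under rigid translation (slopes are unchanged)
    shifted <- matrix(0, 64, 64)
    shifted[3:64, 4:64] <- m[1:62, 1:61]
    expect_identical(ccv_of_mask(shifted), ccv_of_mask(m))
    # mirroring reverses the traversal, so the 2-pixel sampling grid moves:
    # the count is stable only up to rasterisation jitter
    expect_lte(abs(ccv_of_mask(m[, ncol(m):1]) - ccv_of_mask(m)), 4L)
    expect_lte(abs(ccv_of_mask(m[nrow(m):1, ]) - ccv_of_mask(m)), 4L)
  }
  # plus-shaped 4-point diamond: every curve is too short to alternate
  d4 <- matrix(0, 9, 9)
  d4[5, 4:6] <- 1
  d4[4:6, 5] <- 1
  expect_equal(ccv_of_mask(d4), 0L)
})

test_that("the class CCV model averages training values and flags order", {
  model <- fit_ccv_model(c(2, 4, 10, 14),
                         c("normal", "normal", "abnormal", "abnormal"))
  expect_equal(model$m1, 3)
  expect_equal(model$m2, 12)
  expect_false(model$degenerate)
  expect_warning(fit_ccv_model(c(5, 5, 5, 5),
                               c("normal", "normal", "abnormal", "abnormal")),
                 "adjustment")
  expect_error(fit_ccv_model(c(1, 2), c("normal", "normal")), "both classes")
  ds <- generate_dataset(100, seed = 82)
  ccvs <- vapply(ds, function(p) ccv_of_mask(p$mask), integer(1))
  m <- fit_ccv_model(ccvs, patch_labels(ds))
  expect_lt(m$m1, m$m2)
})

test_that("adjustment weights follow the piecewise-linear contract", {
  model <- ccv_model(10, 20)
  expect_equal(weight_normal(5, model), 1.2)
  expect_equal(weight_normal(15, model), 1.0)
  expect_equal(weight_normal(25, model), 0.8)
  expect_equal(weight_abnormal(25, model), 1.2)
  expect_equal(weight_abnormal(15, model), 1.0)
  expect_equal(weight_abnormal(5, model), 0.8)
  grid <- seq(0, 30, length.out = 1000)
  wn <- weight_normal(grid, model)
  wa <- weight_abnormal(grid, model)
  expect_true(all(wn >= 0.8 & wn <= 1.2 & wa >= 0.8 & wa <= 1.2))
  expect_equal(wn + wa, rep(2, 1000))
  expect_true(all(diff(wn) <= 1e-12) && all(diff(wa) >= -1e-12))
  expect_lt(max(abs(diff(wn))), 0.01)  # continuity on a fine grid
  expect_error(weight_normal(5, ccv_model(20, 10)), "degenerate")
})

test_that("posterior adjustment flips, keeps and clips as specified", {
  model <- ccv_model(10, 20)
  preds <- data.frame(
    id = c("a", "b", "c"),
    initial_label = factor(c("normal", "normal", "normal"),
                           levels = c("normal", "abnormal")),
    p_initial = c(0.6, 0.7, 0.9),
    p_abnormal = c(0.4, 0.3, 0.1))
  adj <- adjust_predictions(preds, ccvs = c(25, 15, 5), model)
  # 0.6 * 0.8 = 0.48 < 0.5: flips to abnormal
  expect_equal(adj$p_final[1], 0.48)
  expect_equal(as.character(adj$final_label[1]), "abnormal")
  # omega = 1 keeps the label
  expect_equal(adj$omega[2], 1.0)
  expect_equal(as.character(adj$final_label[2]), "normal")
  # boosted probability clips at 1
  expect_equal(adj$p_final[3], 1.0)
  expect_equal(as.character(adj$final_label[3]), "normal")
  expect_error(adjust_predictions(preds, c(1, 2), model), "per prediction")
})
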