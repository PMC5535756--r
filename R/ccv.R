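# Concave-convex variation (CCV): an inflection-count statistic of the
# nucleus contour.  The contour's axis-aligned bounding box yields four
# tangent points which split the contour into four curves; each curve is
# sampled at a fixed pixel interval, slopes from the curve's anchor tangent
# point to every sampled point form a slope vector K, and the CCV of the
# curve is the number of sign alternations of the slope differences dK.
# The contour CCV is the sum over the four curves.  Class mean CCVs (m1
# for normal, m2 for abnormal) drive a piecewise-linear weight in
# [0.8, 1.2] that multiplies each classifier's initial posterior.

#' Tangent points of a contour with its bounding box
#'
#' The four points where the contour meets its circumscribed axis-aligned
#' rectangle: the extreme point in each axis direction, ties broken by the
#' smallest traversal index.
#'
#' @param contour n x 2 matrix (`col`, `row`) from [trace_contour()].
#' @return Object of class `tangent_quad`: list with `left`, `right`,
#'   `top`, `bottom` (each a `(col, row)` pair) and `idx`, their traversal
#'   indices.
#' @export
tangent_points <- function(contour) {
  if (!is.matrix(contour) || nrow(contour) < 4L) {
    stop("degenerate contour: fewer than 4 points", call. = FALSE)
  }
  col <- contour[, 1L]; row <- contour[, 2L]
  idx <- c(left = which.min(col), right = which.max(col),
           top = which.min(row), bottom = which.max(row))
  structure(list(left = contour[idx["left"], ],
                 right = contour[idx["right"], ],
                 top = contour[idx["top"], ],
                 bottom = contour[idx["bottom"], ],
                 idx = idx),
            class = "tangent_quad")
}

#' Split a closed contour into four curves at the tangent points
#'
#' The four arcs run between consecutive tangent points in traversal
#' order, each including both endpoints; concatenating the arcs (dropping
#' the duplicated endpoints) reproduces the contour.
#'
#' @param contour n x 2 contour matrix.
#' @param quad A [tangent_points()] result.
#' @return List of four point matrices, named `anchor-next` by the tangent
#'   points they join.
#' @export
split_curves <- function(contour, quad) {
  n <- nrow(contour)
  ord <- order(quad$idx)
  starts <- quad$idx[ord]
  nm <- names(quad$idx)[ord]
  curves <- vector("list", 4L)
  names(curves) <- paste(nm, nm[c(2:4, 1L)], sep = "-")
  for (j in 1:4) {
    a <- starts[j]
    b <- if (j < 4L) starts[j + 1L] else starts[1L]
    rng <- if (j < 4L) a:b else c(a:n, seq_len(b))
    curves[[j]] <- contour[rng, , drop = FALSE]
  }
  curves
}

#' Sample points along a curve at a fixed interval
#'
#' Every `interval`-th point along the traversal order, always including
#' the first and last points.
#'
#' @param curve Point matrix.
#' @param interval Sampling interval in points (>= 1).
#' @return Point matrix of the samples.
#' @export
sample_curve <- function(curve, interval = 2L) {
  if (interval < 1L) stop("interval must be >= 1", call. = FALSE)
  n <- nrow(curve)
  if (n == 0L) return(curve)
  idx <- seq(1L, n, by = interval)
  if (idx[length(idx)] != n) idx <- c(idx, n)
  curve[idx, , drop = FALSE]
}

#' Slope vector from a curve's anchor to its sampled points
#'
#' The anchor is the first sample; slopes `k = (y1 - y2) / (x1 - x2)` are
#' computed from the anchor to each subsequent sample.  Samples vertically
#' aligned with the anchor (zero column difference) are skipped so the
#' vector stays finite.
#'
#' @param samples Point matrix from [sample_curve()].
#' @return Numeric vector of slopes (possibly empty).
#' @export
slope_vector <- function(samples) {
  if (nrow(samples) < 2L) return(numeric(0))
  anchor <- samples[1L, ]
  dx <- anchor[1L] - samples[-1L, 1L]
  dy <- anchor[2L] - samples[-1L, 2L]
  keep <- dx != 0
  as.numeric(dy[keep] / dx[keep])
}

#' Sign alternations of a slope-difference vector
#'
#' Counts adjacent pairs of `dk` with strictly opposite signs.  Zero
#' entries inherit the most recent nonzero sign (and are neutral when no
#' prior nonzero sign exists), so plateaus from rasterised lines do not
#' create spurious inflections.
#'
#' @param dk Numeric vector of slope differences (or their signs).
#' @return Nonnegative integer count.
#' @export
#' @examples
#' sign_alternations(c(1, 1, -1, -1, 1, -1))  # 3
sign_alternations <- function(dk) {
  n <- length(dk)
  if (n < 2L) return(0L)
  s <- sign(dk)
  for (i in seq_len(n)[-1L]) if (s[i] == 0) s[i] <- s[i - 1L]
  count <- 0L
  for (i in seq_len(n - 1L)) {
    if (s[i] != 0 && s[i + 1L] != 0 && s[i] * s[i + 1L] < 0) {
      count <- count + 1L
    }
  }
  count
}

#' Alternation count of a slope vector
#'
#' Forms the slope-difference vector `dK` (`dk_n = k_{n+1} - k_n`) and
#' counts its sign alternations; vectors with fewer than 3 slopes
#' contribute 0.
#'
#' @param K Numeric slope vector.
#' @return Nonnegative integer.
#' @export
alternation_count <- function(K) {
  if (length(K) < 3L) return(0L)
  sign_alternations(diff(K))
}

#' Concave-convex variation of a contour
#'
#' Splits the contour at its four bounding-box tangent points, samples
#' each curve at `interval`-pixel steps, and sums the alternation counts
#' of the four slope vectors.
#'
#' @param contour n x 2 contour matrix.
#' @param interval Curve sampling interval in pixels.
#' @return Nonnegative integer CCV value.
#' @export
#' @examples
#' m <- generate_mask(shape_params(10), seed = 1)
#' ccv_of_contour(trace_contour(m))
ccv_of_contour <- function(contour, interval = 2L) {
  quad <- tangent_points(contour)
  curves <- split_curves(contour, quad)
  sum(vapply(curves, function(cv) {
    alternation_count(slope_vector(sample_curve(cv, interval)))
  }, integer(1)))
}

#' CCV of a nucleus mask
#'
#' Convenience wrapper: traces the mask boundary and computes its CCV.
#'
#' @param mask Binary 0/1 matrix.
#' @param interval Curve sampling interval in pixels.
#' @return Nonnegative integer CCV value.
#' @export
ccv_of_mask <- function(mask, interval = 2L) {
  ccv_of_contour(trace_contour(mask), interval = interval)
}

#' Construct or fit the class CCV model
#'
#' `ccv_model(m1, m2)` builds the model directly; [fit_ccv_model()]
#' estimates the class means from training CCVs.  The model is flagged
#' `degenerate` when `m1 >= m2` (normal contours should be the more
#' regular class).
#'
#' @param m1 Mean CCV of normal training contours.
#' @param m2 Mean CCV of abnormal training contours.
#' @return Object of class `ccv_model`.
#' @export
ccv_model <- function(m1, m2) {
  stopifnot_scalar(m1, "m1")
  stopifnot_scalar(m2, "m2")
  if (m1 < 0 || m2 < 0) stop("mean CCVs must be >= 0", call. = FALSE)
  structure(list(m1 = m1, m2 = m2, degenerate = m1 >= m2),
            class = "ccv_model")
}

#' @rdname ccv_model
#' @param ccvs Numeric CCV values of the training contours.
#' @param labels Class labels aligned with `ccvs`.
#' @export
fit_ccv_model <- function(ccvs, labels) {
  labels <- as_class_factor(labels)
  if (length(ccvs) != length(labels)) {
    stop("ccvs and labels must be aligned", call. = FALSE)
  }
  if (!all(.class_levels %in% labels)) {
    stop("both classes must be present", call. = FALSE)
  }
  model <- ccv_model(mean(ccvs[labels == "normal"]),
                     mean(ccvs[labels == "abnormal"]))
  if (model$degenerate) {
    warning("mean CCV of normal contours is not below the abnormal mean; ",
            "the adjustment weights are unavailable", call. = FALSE)
  }
  model
}

#' @export
print.ccv_model <- function(x, ...) {
  cat(sprintf("CCV model: m1 (normal) = %.3f, m2 (abnormal) = %.3f%s\n",
              x$m1, x$m2, if (x$degenerate) "  [degenerate]" else ""))
  invisible(x)
}

check_ccv_model <- function(model) {
  stopifnot(inherits(model, "ccv_model"))
  if (model$degenerate) {
    stop("degenerate CCV model (m1 >= m2); weights undefined", call. = FALSE)
  }
  invisible(model)
}

#' Adjustment weight for samples initially classified normal
#'
#' Piecewise-linear, continuous and monotone decreasing in the CCV value:
#' 1.2 up to `m1`, falling linearly through 1.0 at the midpoint
#' `(m1 + m2) / 2`, and saturating at 0.8 from `m2` on.  A regular contour
#' (low CCV) therefore boosts the normal posterior; an irregular one
#' shrinks it.
#'
#' @param ccv CCV value(s) of the test contour(s).
#' @param model A non-degenerate [ccv_model()].
#' @return Weight(s) in [0.8, 1.2].
#' @export
#' @examples
#' m <- ccv_model(10, 20)
#' weight_normal(c(5, 15, 25), m)  # 1.2, 1.0, 0.8
weight_normal <- function(ccv, model) {
  check_ccv_model(model)
  m1 <- model$m1; m2 <- model$m2
  mid <- (m1 + m2) / 2
  ifelse(ccv <= m1, 1.2,
         ifelse(ccv <= mid, 1.2 + 0.4 * (ccv - m1) / (m1 - m2),
                ifelse(ccv < m2, 0.8 + 0.4 * (ccv - m2) / (m1 - m2), 0.8)))
}

#' Adjustment weight for samples initially classified abnormal
#'
#' Mirror image of [weight_normal()]: monotone increasing from 0.8 below
#' `m1` to 1.2 at and beyond `m2`; the two weight functions sum to 2
#' everywhere.
#'
#' @inheritParams weight_normal
#' @return Weight(s) in [0.8, 1.2].
#' @export
weight_abnormal <- function(ccv, model) {
  check_ccv_model(model)
  m1 <- model$m1; m2 <- model$m2
  mid <- (m1 + m2) / 2
  ifelse(ccv <= m1, 0.8,
         ifelse(ccv <= mid, 0.8 + 0.4 * (ccv - m1) / (m2 - m1),
                ifelse(ccv < m2, 1.2 + 0.4 * (ccv - m2) / (m2 - m1), 1.2)))
}

#' Adjust initial classifier predictions with the CCV weights
#'
#' For each sample the weight is [weight_normal()] when the initial label
#' is normal and [weight_abnormal()] otherwise; the adjusted probability is
#' `p_final = min(1, p_initial * omega)` and the final label keeps the
#' initial label iff `p_final >= 1/2`, otherwise it flips.  The column
#' `p_abnormal_adj` re-expresses the adjusted probability as the abnormal
#' class score (for threshold sweeps).
#'
#' @param preds Data frame from [initial_predictions()].
#' @param ccvs CCV values aligned with the rows of `preds`.
#' @param model A non-degenerate [ccv_model()].
#' @return `preds` extended with `ccv`, `omega`, `p_final`, `final_label`,
#'   `p_abnormal_adj`.
#' @export
adjust_predictions <- function(preds, ccvs, model) {
  check_ccv_model(model)
  if (length(ccvs) != nrow(preds) || anyNA(ccvs)) {
    stop("one CCV value per prediction required", call. = FALSE)
  }
  is_norm <- preds$initial_label == "normal"
  omega <- ifelse(is_norm, weight_normal(ccvs, model),
                  weight_abnormal(ccvs, model))
  p_final <- pmin(pmax(preds$p_initial * omega, 0), 1)
  keep <- p_final >= 0.5
  flip <- ifelse(is_norm, "abnormal", "normal")
  final <- ifelse(keep, as.character(preds$initial_label), flip)
  out <- preds
  out$ccv <- ccvs
  out$omega <- omega
  out$p_final <- p_final
  out$final_label <- factor(final, levels = .class_levels)
  out$p_abnormal_adj <- ifelse(is_norm, 1 - p_final, p_final)
  out
}
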