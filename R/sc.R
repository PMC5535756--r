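# Sparse-contribution (SC) filter feature selection: per-row min-max
# normalisation, Pearson redundancy pruning, contrast mapping to [-1, 1],
# unit-circle contribution scoring against the class labels, contribution
# thresholding, and sparsification of near-zero entries.

#' Row-wise min-max normalisation
#'
#' Maps each feature row to [0, 1] by `(x - min) / (max - min)`.  Constant
#' rows map to all zeros and are flagged for removal.
#'
#' @param fs A [feature_matrix()] or numeric matrix with rownames.
#' @return List with `values` (normalised matrix), `row_minmax` (m x 2
#'   matrix of the per-row min and max) and `constant` (logical).
#' @export
normalize01 <- function(fs) {
  values <- if (inherits(fs, "feature_matrix")) fs$values else fs
  rmin <- apply(values, 1, min)
  rmax <- apply(values, 1, max)
  constant <- (rmax - rmin) < 1e-12
  denom <- ifelse(constant, 1, rmax - rmin)
  out <- (values - rmin) / denom
  out[constant, ] <- 0
  list(values = out, row_minmax = cbind(min = rmin, max = rmax),
       constant = constant)
}

#' Redundancy pruning by Pearson correlation
#'
#' Greedy scan in row order: a feature is dropped when the absolute Pearson
#' correlation with any earlier kept feature is at least `rho_max`; the
#' earlier feature is retained.  Correlations that are undefined (constant
#' rows) are treated as 0.
#'
#' @param values Numeric matrix, features in rows.
#' @param rho_max Redundancy threshold in (0, 1].
#' @return Integer vector of kept row indices (strictly increasing).
#' @export
remove_redundant <- function(values, rho_max = 0.95) {
  if (!(rho_max > 0 && rho_max <= 1)) {
    stop("rho_max must be in (0, 1]", call. = FALSE)
  }
  m <- nrow(values)
  if (m == 1L) return(1L)
  cm <- suppressWarnings(abs(stats::cor(t(values))))
  cm[!is.finite(cm)] <- 0
  kept <- integer(0)
  for (i in seq_len(m)) {
    if (length(kept) == 0L || all(cm[i, kept] < rho_max)) {
      kept <- c(kept, i)
    }
  }
  kept
}

#' Contrast mapping of one feature row to [-1, 1]
#'
#' Computes `x* = (x - mu) / (sigma + eps)` where `mu` and `sigma` are the
#' row mean and (population) standard deviation and `eps` is the smallest
#' nonnegative value guaranteeing `|x*| <= 1`, i.e.
#' `eps = max(0, max|x - mu| - sigma)`.  A constant row maps to zeros.
#'
#' @param row Numeric vector.
#' @return List with `x` (mapped row), `mu`, `sigma`, `eps`.
#' @export
#' @examples
#' contrast_map(c(0, 1))$x  # -1, 1
contrast_map <- function(row) {
  mu <- mean(row)
  sigma <- sqrt(mean((row - mu)^2))
  if (sigma < 1e-12) {
    return(list(x = rep(0, length(row)), mu = mu, sigma = 0, eps = 1e-12))
  }
  eps <- max(0, max(abs(row - mu)) - sigma)
  list(x = (row - mu) / (sigma + eps), mu = mu, sigma = sigma, eps = eps)
}

#' Unit-circle contribution value of one mapped feature row
#'
#' For a contrast-mapped row (values in [-1, 1]) and binary class labels,
#' let `s = sign(mean of the normal samples)` and `y_i = sqrt(1 - x_i^2)`
#' (the unit-circle ordinate).  Each normal sample contributes
#' `s * sign(x_i) * (1 - y_i)`, each abnormal sample contributes
#' `-s * sign(x_i) * (1 - y_i)`, and the contribution value `C(x)` is the
#' sum over all samples.  Rows whose class means do not lie on opposite
#' sides of zero (`mean_normal * mean_abnormal >= 0`) are flagged as
#' removed and get `C = NA`.
#'
#' @param x Numeric vector with `|x| <= 1`.
#' @param labels Class labels aligned with `x`.
#' @return List with `C`, `removed` (logical), `s`.
#' @export
feature_contribution <- function(x, labels) {
  labels <- as_class_factor(labels)
  if (any(abs(x) > 1 + 1e-9)) {
    stop("mapped values must lie in [-1, 1]", call. = FALSE)
  }
  if (!all(.class_levels %in% labels)) {
    stop("both classes must be present", call. = FALSE)
  }
  x <- pmin(pmax(x, -1), 1)
  normal <- labels == "normal"
  mn <- mean(x[normal])
  ma <- mean(x[!normal])
  if (mn * ma >= 0) {
    return(list(C = NA_real_, removed = TRUE, s = sign(mn)))
  }
  s <- sign(mn)
  contrib <- s * sign(x) * (1 - sqrt(1 - x^2))
  contrib[!normal] <- -contrib[!normal]
  list(C = sum(contrib), removed = FALSE, s = s)
}

#' Fit the sparse-contribution selection model
#'
#' Pipeline: min-max normalise each row (constant rows dropped), prune
#' redundant rows by Pearson correlation, contrast-map the survivors to
#' [-1, 1], remove rows whose class means share a sign, score the rest by
#' their unit-circle contribution `C(x)` and keep those with
#' `C(x) >= delta1`.  All per-row parameters are stored for transform-time
#' reuse on test data.
#'
#' @param fs A [feature_matrix()] (features x samples).
#' @param labels Class labels per sample (column).
#' @param rho_max Redundancy threshold.
#' @param delta1 Contribution threshold; `NULL` uses the 60th percentile of
#'   the surviving contribution values.
#' @param delta2 Sparsification threshold applied by [sc_transform()].
#' @return An object of class `sc_model`.
#' @export
sc_fit <- function(fs, labels, rho_max = 0.95, delta1 = NULL, delta2 = 0.05) {
  stopifnot(inherits(fs, "feature_matrix"))
  labels <- as_class_factor(labels)
  if (length(labels) != ncol(fs$values)) {
    stop("one label per sample column required", call. = FALSE)
  }
  if (!all(.class_levels %in% labels)) {
    stop("both classes must be present", call. = FALSE)
  }
  m <- nrow(fs$values)
  norm <- normalize01(fs)
  nonconst <- which(!norm$constant)
  # Step 1b: redundancy pruning among non-constant rows
  kept1 <- nonconst[remove_redundant(norm$values[nonconst, , drop = FALSE],
                                     rho_max)]
  m1 <- length(kept1)
  # Step 2: contrast mapping + contribution scoring
  maps <- lapply(kept1, function(i) contrast_map(norm$values[i, ]))
  contribs <- lapply(maps, function(mp) feature_contribution(mp$x, labels))
  C <- vapply(contribs, `[[`, numeric(1), "C")
  sign_ok <- !vapply(contribs, `[[`, logical(1), "removed")
  if (is.null(delta1)) {
    if (!any(sign_ok)) {
      stop("no feature separates the class means; cannot set delta1",
           call. = FALSE)
    }
    delta1 <- stats::quantile(C[sign_ok], 0.60, names = FALSE)
  }
  keep2 <- sign_ok & !is.na(C) & C >= delta1
  if (!any(keep2)) {
    stop("no features survive the contribution threshold; lower delta1",
         call. = FALSE)
  }
  kept <- kept1[keep2]
  structure(list(
    feature_names = rownames(fs$values),
    kept_indices = kept,
    kept_names = rownames(fs$values)[kept],
    row_minmax = norm$row_minmax[kept, , drop = FALSE],
    contrast_params = do.call(rbind, lapply(maps[keep2], function(mp) {
      c(mu = mp$mu, sigma = mp$sigma, eps = mp$eps)
    })),
    orientation = vapply(contribs[keep2], `[[`, numeric(1), "s"),
    contributions = C,
    contribution_names = rownames(fs$values)[kept1],
    sign_ok = sign_ok,
    delta1 = delta1, delta2 = delta2, rho_max = rho_max,
    m = m, m1 = m1, m2 = length(kept), k = length(kept)),
    class = "sc_model")
}

#' @export
print.sc_model <- function(x, ...) {
  cat("sparse-contribution selection model\n")
  cat(sprintf("  features: %d -> %d (redundancy) -> %d (contribution)\n",
              x$m, x$m1, x$k))
  cat(sprintf("  rho_max = %.3g, delta1 = %.4g, delta2 = %.3g\n",
              x$rho_max, x$delta1, x$delta2))
  invisible(x)
}

#' Apply a fitted selection model
#'
#' Selects the kept feature rows, applies the stored min-max and contrast
#' parameters (values outside [-1, 1] on new data are clamped), and zeroes
#' entries with `|x| <= delta2`, producing the sparse selected matrix.
#'
#' @param model An `sc_model` from [sc_fit()].
#' @param fs A [feature_matrix()] with the same feature rows as at fit time.
#' @param delta2 Optional override of the stored sparsification threshold.
#' @return A sparse [feature_matrix()] with `k` rows.
#' @export
sc_transform <- function(model, fs, delta2 = model$delta2) {
  stopifnot(inherits(model, "sc_model"), inherits(fs, "feature_matrix"))
  if (!all(model$kept_names %in% rownames(fs$values))) {
    stop("feature rows do not match the fitted model", call. = FALSE)
  }
  v <- fs$values[model$kept_names, , drop = FALSE]
  rng <- model$row_minmax[, "max"] - model$row_minmax[, "min"]
  rng[rng < 1e-12] <- 1
  v <- (v - model$row_minmax[, "min"]) / rng
  v <- (v - model$contrast_params[, "mu"]) /
    (model$contrast_params[, "sigma"] + model$contrast_params[, "eps"])
  v <- pmin(pmax(v, -1), 1)
  v[abs(v) <= delta2] <- 0
  groups <- if (inherits(fs, "feature_matrix")) {
    fs$groups[match(model$kept_names, rownames(fs$values))]
  } else NULL
  feature_matrix(v, groups = groups)
}

#' Serialise a selection model to JSON
#' @param model An `sc_model`.
#' @param path Output path.
#' @export
write_sc_model <- function(model, path) {
  jsonlite::write_json(unclass(model), path, auto_unbox = TRUE, digits = NA,
                       matrix = "columnmajor")
  invisible(path)
}
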