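# Feature matrix container: features in rows (m), samples in columns (n),
# with named feature rows and per-row group membership.

#' Construct a feature matrix
#'
#' @param values m x n numeric matrix, features in rows, samples in
#'   columns; must carry row and column names.
#' @param groups Optional character vector of feature-group labels per row
#'   (derived from the name prefix when missing).
#' @return An object of class `feature_matrix`.
#' @export
feature_matrix <- function(values, groups = NULL) {
  if (!is.matrix(values) || is.null(rownames(values)) ||
      is.null(colnames(values))) {
    stop("values must be a matrix with row (feature) and column (sample) names",
         call. = FALSE)
  }
  if (anyNA(values) || any(!is.finite(values))) {
    stop("feature matrix must not contain missing or non-finite values",
         call. = FALSE)
  }
  if (is.null(groups)) {
    groups <- sub("_.*$", "", rownames(values))
  }
  stopifnot(length(groups) == nrow(values))
  structure(list(values = values, groups = groups), class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("feature_matrix: %d features x %d samples\n",
              nrow(x$values), ncol(x$values)))
  tb <- table(x$groups)
  cat("  groups:", paste(sprintf("%s=%d", names(tb), tb), collapse = ", "),
      "\n")
  invisible(x)
}

#' @export
as.matrix.feature_matrix <- function(x, ...) x$values

#' @export
dim.feature_matrix <- function(x) dim(x$values)

#' Feature-extraction configuration
#'
#' Controls which feature groups [extract_all()] computes and their
#' parameters.  The delivered dimension budget is whatever the selected
#' groups produce (22 intensity + 10 morphology + 25 GLCM + 16 x 256 (or
#' 59) LBP + 257 SIFT + 3 Tamura with all groups on).
#'
#' @param groups Feature groups to compute, in output order.
#' @param filter Apply the bilateral filter to the grey patch before the
#'   intensity/texture extractors (the mask-only morphology group is
#'   unaffected).
#' @param sigma_spatial,sigma_range,window Bilateral filter parameters.
#' @param glcm_levels,glcm_idm GLCM quantisation levels and IDM variant.
#' @param lbp_mode `"raw"` (256 bins/cell) or `"uniform"` (59 bins/cell).
#' @param sift_octaves,sift_contrast SIFT pyramid depth and contrast gate.
#' @return A list of class `feature_config`.
#' @export
feature_config <- function(groups = c("intensity", "morphology", "glcm",
                                      "lbp", "sift", "tamura"),
                           filter = TRUE, sigma_spatial = 3, sigma_range = 25,
                           window = 7L, glcm_levels = 16L,
                           glcm_idm = "standard", lbp_mode = "raw",
                           sift_octaves = 3L, sift_contrast = 0.02) {
  groups <- match.arg(groups, several.ok = TRUE)
  structure(list(groups = groups, filter = filter,
                 sigma_spatial = sigma_spatial, sigma_range = sigma_range,
                 window = window, glcm_levels = glcm_levels,
                 glcm_idm = glcm_idm, lbp_mode = lbp_mode,
                 sift_octaves = sift_octaves, sift_contrast = sift_contrast),
            class = "feature_config")
}

# feature vector of a single patch record
extract_patch_features <- function(patch, config = feature_config()) {
  gray <- patch$gray
  if (isTRUE(config$filter)) {
    gray <- bilateral_filter(gray, config$sigma_spatial, config$sigma_range,
                             config$window)
  }
  parts <- list()
  for (g in config$groups) {
    parts[[g]] <- switch(
      g,
      intensity = intensity_features(gray, patch$mask),
      morphology = morphology_features(patch$mask),
      glcm = glcm_features(gray, levels = config$glcm_levels,
                           idm = config$glcm_idm),
      lbp = lbp_histogram(gray, mode = config$lbp_mode),
      sift = sift_features(gray, n_octaves = config$sift_octaves,
                           contrast_threshold = config$sift_contrast),
      tamura = tamura_features(gray))
  }
  unlist(parts, use.names = TRUE)
}

#' Extract the full feature bank of a patch set
#'
#' Applies the configured extractors to every patch (after optional
#' bilateral filtering of the grey image) and assembles the feature matrix
#' with features in rows and samples in columns.  Any per-patch failure
#' aborts with the offending patch id.
#'
#' @param patches A `patch_set` (or list of `patch_record`s).
#' @param config A [feature_config()].
#' @return A [feature_matrix()] with one column per patch.
#' @export
#' @examples
#' ds <- generate_dataset(2, seed = 1)
#' fs <- extract_all(ds, feature_config(groups = c("intensity", "morphology")))
#' dim(fs)
extract_all <- function(patches, config = feature_config()) {
  if (length(patches) == 0L) stop("no patches supplied", call. = FALSE)
  cols <- vector("list", length(patches))
  for (i in seq_along(patches)) {
    p <- patches[[i]]
    cols[[i]] <- tryCatch(
      extract_patch_features(p, config),
      error = function(e) {
        stop(sprintf("feature extraction failed for patch '%s': %s",
                     p$id, conditionMessage(e)), call. = FALSE)
      })
  }
  values <- do.call(cbind, cols)
  # strip the unlist() group prefix, keeping the extractor's own names
  rn <- sub("^[a-z]+\\.", "", rownames(values))
  groups <- sub("\\..*$", "", rownames(values))
  rownames(values) <- rn
  colnames(values) <- patch_ids(patches)
  feature_matrix(values, groups = groups)
}

#' Write a feature matrix as CSV
#'
#' One row per feature (columns: `feature`, `group`, then one column per
#' sample id); the orientation on disk matches the in-memory layout.
#'
#' @param fs A `feature_matrix`.
#' @param path Output file path.
#' @export
write_feature_matrix <- function(fs, path) {
  df <- data.frame(feature = rownames(fs$values), group = fs$groups,
                   fs$values, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a feature matrix written by [write_feature_matrix()]
#' @param path CSV file path.
#' @return A `feature_matrix`.
#' @export
read_feature_matrix <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  values <- as.matrix(df[, -(1:2), drop = FALSE])
  rownames(values) <- df$feature
  feature_matrix(values, groups = df$group)
}
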