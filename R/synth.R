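# Synthetic single-nucleus patch generator.
#
# Stands in for segmented H&E single-cell patches: each record is a 64x64
# grey image plus a binary nucleus mask.  Shapes are star-convex regions
# defined by a polar radius function
#   r(theta) = r_ellipse(theta) + A * sin(n_lobes * theta + phase) + eta(theta)
# so the number and depth of contour concavities is controlled directly.
# Normal-style parameters (n_lobes = 0, boundary_noise_amp = 0) give a
# rasterised ellipse; abnormal-style parameters add sinusoidal lobes and a
# smooth random radial perturbation eta (low-order Fourier series scaled to
# half the lobe amplitude).

#' Shape parameters for the synthetic nucleus generator
#'
#' @param base_radius Nucleus semi-minor radius in pixels.
#' @param eccentricity Ratio of semi-major to semi-minor axis (>= 1).
#' @param boundary_noise_amp Amplitude, in pixels, of the contour
#'   irregularity: the sinusoidal lobe term uses this amplitude directly and
#'   the random radial perturbation is scaled to half of it.  Zero gives a
#'   smooth ellipse.
#' @param n_lobes Number of sinusoidal lobes superimposed on the radius
#'   function (integer >= 0).
#' @param center_jitter Maximum uniform displacement of the nucleus centre
#'   from the patch centre, in pixels.
#' @return An object of class `shape_params`.
#' @export
#' @examples
#' shape_params(base_radius = 10)
shape_params <- function(base_radius, eccentricity = 1,
                         boundary_noise_amp = 0, n_lobes = 0L,
                         center_jitter = 0) {
  stopifnot_scalar(base_radius, "base_radius", positive = TRUE)
  stopifnot_scalar(eccentricity, "eccentricity")
  stopifnot_scalar(boundary_noise_amp, "boundary_noise_amp")
  stopifnot_scalar(n_lobes, "n_lobes")
  stopifnot_scalar(center_jitter, "center_jitter")
  if (eccentricity < 1) stop("eccentricity must be >= 1", call. = FALSE)
  if (boundary_noise_amp < 0 || center_jitter < 0 || n_lobes < 0) {
    stop("boundary_noise_amp, n_lobes and center_jitter must be >= 0",
         call. = FALSE)
  }
  if (boundary_noise_amp >= base_radius) {
    stop("boundary_noise_amp must be smaller than base_radius", call. = FALSE)
  }
  structure(list(base_radius = base_radius,
                 eccentricity = eccentricity,
                 boundary_noise_amp = boundary_noise_amp,
                 n_lobes = as.integer(round(n_lobes)),
                 center_jitter = center_jitter),
            class = "shape_params")
}

#' Texture parameters for the synthetic nucleus generator
#'
#' @param nucleus_mean_gray Mean grey level inside the nucleus (0-255).
#' @param background_mean_gray Mean grey level of the background (0-255).
#' @param noise_sd Standard deviation of the grey-level noise.
#' @param chromatin_grain Correlation length, in pixels, of the chromatin
#'   texture inside the nucleus (Gaussian-smoothed noise field).
#' @return An object of class `texture_params`.
#' @export
texture_params <- function(nucleus_mean_gray = 90, background_mean_gray = 200,
                           noise_sd = 10, chromatin_grain = 2) {
  stopifnot_scalar(nucleus_mean_gray, "nucleus_mean_gray")
  stopifnot_scalar(background_mean_gray, "background_mean_gray")
  stopifnot_scalar(noise_sd, "noise_sd")
  stopifnot_scalar(chromatin_grain, "chromatin_grain")
  if (nucleus_mean_gray < 0 || nucleus_mean_gray > 255 ||
      background_mean_gray < 0 || background_mean_gray > 255) {
    stop("grey means must be in [0, 255]", call. = FALSE)
  }
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  if (chromatin_grain < 0) stop("chromatin_grain must be >= 0", call. = FALSE)
  structure(list(nucleus_mean_gray = nucleus_mean_gray,
                 background_mean_gray = background_mean_gray,
                 noise_sd = noise_sd,
                 chromatin_grain = chromatin_grain),
            class = "texture_params")
}

#' Default per-class shape and texture presets
#'
#' The presets define the study conditions of the synthetic benchmark:
#' normal nuclei are smooth ellipses, abnormal nuclei are slightly larger,
#' darker (hyperchromatic), coarser-textured and carry a lobed, noisy
#' contour.
#'
#' @param label `"normal"` or `"abnormal"`.
#' @return A list with elements `shape` and `texture`.
#' @export
default_class_params <- function(label = c("normal", "abnormal")) {
  label <- match.arg(label)
  if (label == "normal") {
    list(shape = shape_params(base_radius = 12, eccentricity = 1.15,
                              boundary_noise_amp = 0, n_lobes = 0L,
                              center_jitter = 3),
         texture = texture_params(nucleus_mean_gray = 90,
                                  background_mean_gray = 200,
                                  noise_sd = 10, chromatin_grain = 2))
  } else {
    list(shape = shape_params(base_radius = 13, eccentricity = 1.25,
                              boundary_noise_amp = 2.5, n_lobes = 5L,
                              center_jitter = 3),
         texture = texture_params(nucleus_mean_gray = 80,
                                  background_mean_gray = 200,
                                  noise_sd = 12, chromatin_grain = 3))
  }
}

# worst-case radius the shape can reach, used for the fit-in-frame check
max_shape_radius <- function(shape) {
  shape$base_radius * shape$eccentricity + 1.5 * shape$boundary_noise_amp +
    shape$center_jitter
}

#' Generate a binary nucleus mask
#'
#' Rasterises the polar radius function onto a `size` x `size` grid.  The
#' result always contains a single 4-connected foreground component that
#' does not touch the image border.
#'
#' @param shape A [shape_params()] object.
#' @param seed Integer seed; identical inputs give identical masks.
#' @param size Patch side length in pixels.
#' @return A `size` x `size` 0/1 matrix (rows = image rows).
#' @export
#' @examples
#' m <- generate_mask(shape_params(10), seed = 1)
#' sum(m) / (pi * 100)  # close to 1
generate_mask <- function(shape, seed, size = 64L) {
  stopifnot(inherits(shape, "shape_params"))
  if (max_shape_radius(shape) > size / 2 - 2) {
    stop("shape cannot fit in the frame with a 2-pixel margin", call. = FALSE)
  }
  with_seed(seed, {
    rot <- stats::runif(1, 0, 2 * pi)
    phase <- stats::runif(1, 0, 2 * pi)
    jx <- stats::runif(1, -shape$center_jitter, shape$center_jitter)
    jy <- stats::runif(1, -shape$center_jitter, shape$center_jitter)
    fourier <- matrix(stats::rnorm(10), nrow = 2)  # harmonics 2..6
    cx <- (size + 1) / 2 + jx
    cy <- (size + 1) / 2 + jy
    a <- shape$base_radius * shape$eccentricity
    b <- shape$base_radius
    col <- matrix(rep(seq_len(size), each = size), nrow = size)   # x
    row <- matrix(rep(seq_len(size), times = size), nrow = size)  # y
    dx <- col - cx
    dy <- row - cy
    rho <- sqrt(dx^2 + dy^2)
    theta <- atan2(dy, dx)
    phi <- theta - rot
    r_ell <- a * b / sqrt((b * cos(phi))^2 + (a * sin(phi))^2)
    r <- r_ell
    if (shape$boundary_noise_amp > 0) {
      if (shape$n_lobes > 0) {
        r <- r + shape$boundary_noise_amp * sin(shape$n_lobes * phi + phase)
      }
      eta <- matrix(0, size, size)
      for (h in 2:6) {
        eta <- eta + fourier[1, h - 1] * cos(h * phi) +
          fourier[2, h - 1] * sin(h * phi)
      }
      amax <- max(abs(fourier)) * sqrt(10)  # conservative bound on |eta|
      if (amax > 0) {
        eta <- eta / max(abs(range(eta)), 1e-9)
        r <- r + 0.5 * shape$boundary_noise_amp * eta
      }
    }
    mask <- matrix(as.numeric(rho <= r), size, size)
    if (sum(mask) == 0 || mask_touches_border(mask) ||
        count_components4(mask) != 1L) {
      stop("generated mask is degenerate; adjust shape parameters",
           call. = FALSE)
    }
    mask
  })
}

#' Render a grey-level texture onto a nucleus mask
#'
#' Grey values are `nucleus_mean_gray` inside the mask and
#' `background_mean_gray` outside, plus zero-mean noise of standard
#' deviation `noise_sd`.  Inside the mask the noise field is smoothed with a
#' Gaussian of width `chromatin_grain` (then re-standardised and re-centred
#' within the mask), emulating chromatin clumping; the background noise is
#' white.  Values are clipped to [0, 255].
#'
#' @param mask Binary matrix from [generate_mask()].
#' @param tex A [texture_params()] object.
#' @param seed Integer seed.
#' @return A numeric matrix of grey values in [0, 255].
#' @export
generate_texture <- function(mask, tex, seed) {
  check_mask(mask)
  stopifnot(inherits(tex, "texture_params"))
  size_r <- nrow(mask); size_c <- ncol(mask)
  with_seed(seed, {
    img <- matrix(tex$background_mean_gray, size_r, size_c)
    inside <- mask == 1
    img[inside] <- tex$nucleus_mean_gray
    if (tex$noise_sd > 0) {
      fg <- matrix(stats::rnorm(size_r * size_c), size_r, size_c)
      if (tex$chromatin_grain > 0) fg <- gaussian_blur(fg, tex$chromatin_grain)
      # re-centre/re-scale within the mask so the within-mask mean and SD of
      # the rendered noise are exactly 0 and noise_sd before clipping
      v <- fg[inside]
      s <- stats::sd(v)
      v <- if (is.na(s) || s < 1e-12) rep(0, length(v)) else (v - mean(v)) / s
      bgn <- stats::rnorm(size_r * size_c)
      bg <- matrix(bgn - mean(bgn), size_r, size_c)
      img[inside] <- img[inside] + tex$noise_sd * v
      img[!inside] <- img[!inside] + tex$noise_sd * bg[!inside]
    }
    pmin(pmax(img, 0), 255)
  })
}

#' Generate one labelled patch record
#'
#' @param id Sample identifier string.
#' @param label `"normal"` or `"abnormal"`.
#' @param shape,tex Class parameter objects.
#' @param seed Integer seed.
#' @return A `patch_record`: list with `gray`, `mask`, `label`, `id`.
#' @export
generate_patch <- function(id, label, shape, tex, seed) {
  mask <- generate_mask(shape, seed = derive_seed(seed, 1L))
  gray <- generate_texture(mask, tex, seed = derive_seed(seed, 2L))
  structure(list(gray = gray, mask = mask,
                 label = match.arg(label, .class_levels), id = id),
            class = "patch_record")
}

#' Generate a balanced labelled patch dataset
#'
#' Each patch draws its own random stream from a per-patch seed derived from
#' `seed`, so the dataset is order-independent and reproducible.  Mild
#' patch-to-patch variation is added on top of the class presets: the base
#' radius is scaled by a lognormal-ish factor with coefficient of variation
#' `radius_cv`, and both grey means are jittered by up to `mean_jitter` grey
#' levels, so that no single feature separates the classes perfectly.
#'
#' @param n_per_class Number of patches per class (>= 1).
#' @param normal,abnormal Per-class parameter lists with elements `shape`
#'   and `texture` (see [default_class_params()]).
#' @param seed Integer master seed.
#' @param radius_cv Relative SD of the per-patch radius scaling.
#' @param mean_jitter Maximum uniform grey-mean jitter per patch.
#' @return A `patch_set`: list of `patch_record`s.
#' @export
#' @examples
#' ds <- generate_dataset(3, seed = 1)
#' table(patch_labels(ds))
generate_dataset <- function(n_per_class,
                             normal = default_class_params("normal"),
                             abnormal = default_class_params("abnormal"),
                             seed = 1L, radius_cv = 0.08, mean_jitter = 8) {
  if (n_per_class < 1) stop("n_per_class must be >= 1", call. = FALSE)
  n_per_class <- as.integer(n_per_class)
  params <- list(normal = normal, abnormal = abnormal)
  records <- vector("list", 2L * n_per_class)
  idx <- 0L
  for (lab in .class_levels) {
    p <- params[[lab]]
    for (i in seq_len(n_per_class)) {
      idx <- idx + 1L
      sd_i <- derive_seed(seed, idx * 7L)
      jit <- with_seed(derive_seed(sd_i, 3L), {
        list(rf = exp(stats::rnorm(1, 0, radius_cv)),
             mj = stats::runif(2, -mean_jitter, mean_jitter))
      })
      sh <- p$shape
      sh$base_radius <- sh$base_radius * jit$rf
      tx <- p$texture
      tx$nucleus_mean_gray <- min(255, max(0, tx$nucleus_mean_gray + jit$mj[1]))
      tx$background_mean_gray <-
        min(255, max(0, tx$background_mean_gray + jit$mj[2]))
      records[[idx]] <- generate_patch(
        id = sprintf("%s_%04d", lab, i), label = lab,
        shape = sh, tex = tx, seed = sd_i)
    }
  }
  structure(records, class = "patch_set")
}

#' Labels of a patch set
#' @param patches A `patch_set` or list of `patch_record`s.
#' @return Factor with levels `normal`, `abnormal`.
#' @export
patch_labels <- function(patches) {
  as_class_factor(vapply(patches, `[[`, character(1), "label"))
}

#' Sample ids of a patch set
#' @param patches A `patch_set` or list of `patch_record`s.
#' @return Character vector of ids.
#' @export
patch_ids <- function(patches) {
  vapply(patches, `[[`, character(1), "id")
}

#' @export
print.patch_set <- function(x, ...) {
  cat(sprintf("patch_set: %d patches (%s)\n", length(x),
              paste(sprintf("%s=%d", names(table(patch_labels(x))),
                            table(patch_labels(x))), collapse = ", ")))
  invisible(x)
}

#' Write a patch set to disk
#'
#' Writes `<id>_gray.png` and `<id>_mask.png` pairs plus a `labels.csv`
#' (columns `id`, `label`).  The same layout is read back by
#' [read_patch_set()] and is the reader contract for real data.
#'
#' @param patches A `patch_set`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_patch_set <- function(patches, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (p in patches) {
    png::writePNG(p$gray / 255, file.path(dir, paste0(p$id, "_gray.png")))
    png::writePNG(p$mask, file.path(dir, paste0(p$id, "_mask.png")))
  }
  utils::write.csv(
    data.frame(id = patch_ids(patches), label = as.character(patch_labels(patches))),
    file.path(dir, "labels.csv"), row.names = FALSE)
  invisible(dir)
}

#' Read a patch set written by [write_patch_set()]
#'
#' Grey images are rescaled to [0, 255]; 8-bit masks are binarised at 128.
#'
#' @param dir Directory containing `labels.csv` and the PNG pairs.
#' @return A `patch_set`.
#' @export
read_patch_set <- function(dir) {
  lab <- utils::read.csv(file.path(dir, "labels.csv"),
                         colClasses = "character")
  records <- vector("list", nrow(lab))
  for (i in seq_len(nrow(lab))) {
    id <- lab$id[i]
    gray <- read_gray_png(file.path(dir, paste0(id, "_gray.png")))
    mask <- read_gray_png(file.path(dir, paste0(id, "_mask.png")))
    records[[i]] <- structure(
      list(gray = gray, mask = matrix(as.numeric(mask >= 128), nrow(mask)),
           label = match.arg(lab$label[i], .class_levels), id = id),
      class = "patch_record")
  }
  structure(records, class = "patch_set")
}

read_gray_png <- function(path) {
  a <- png::readPNG(path)
  if (length(dim(a)) == 3L) a <- a[, , 1L]  # first channel of RGB(A) input
  a * 255
}
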