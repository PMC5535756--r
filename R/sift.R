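# Compact SIFT: difference-of-Gaussian keypoint detection over a Gaussian
# scale-space pyramid, orientation assignment from the gradient-orientation
# histogram, and 4x4x8 gradient descriptors.  Variable-count keypoints are
# aggregated into a fixed-length feature vector (count + descriptor
# mean/SD) for the feature bank.

# central-difference gradient magnitude and direction of a smoothed image
# (replicate-padded borders)
sift_gradient <- function(L) {
  nr <- nrow(L); nc <- ncol(L)
  p <- pad_replicate(L, 1L)
  dxv <- p[1L + seq_len(nr), 2L + seq_len(nc)] - p[1L + seq_len(nr), seq_len(nc)]
  dyv <- p[2L + seq_len(nr), 1L + seq_len(nc)] - p[seq_len(nr), 1L + seq_len(nc)]
  list(val = sqrt(dxv^2 + dyv^2), dir = atan2(dyv, dxv))
}

# Gaussian pyramid for one octave: images at sigma0 * 2^((i-1)/ns),
# i = 1..ns+3, built by incremental blurring.
build_octave <- function(base, sigma0, ns) {
  imgs <- vector("list", ns + 3L)
  imgs[[1L]] <- base
  sig <- sigma0 * 2^((seq_len(ns + 3L) - 1) / ns)
  for (i in 2:(ns + 3L)) {
    inc <- sqrt(max(sig[i]^2 - sig[i - 1L]^2, 1e-6))
    imgs[[i]] <- gaussian_blur(imgs[[i - 1L]], inc)
  }
  imgs
}

# Detection engine shared by sift_keypoints() and sift_features(): builds
# the pyramid once, locates extrema, assigns orientations, and keeps the
# pyramid's Gaussian layers around so descriptors reuse their gradients.
sift_detect <- function(gray, n_octaves = 3L, n_scales = 3L, sigma0 = 1.6,
                        contrast_threshold = 0.02, edge_ratio = 10,
                        max_keypoints = 80L) {
  base <- gaussian_blur(gray / 255, sqrt(max(sigma0^2 - 0.25, 0.01)))
  kps <- list()
  layers <- list()  # layers[[o]][[s]]: Gaussian image at octave o, level s
  for (o in seq_len(n_octaves)) {
    if (min(dim(base)) < 8L) break
    G <- build_octave(base, sigma0, n_scales)
    layers[[o]] <- G
    D <- lapply(seq_len(n_scales + 2L), function(i) G[[i + 1L]] - G[[i]])
    nr <- nrow(base)
    nc <- ncol(base)
    for (s in 2:(n_scales + 1L)) {
      d0 <- D[[s]]
      # contrast gate first; neighbour comparison only at candidates
      cand <- which(abs(d0) >= contrast_threshold)
      if (length(cand) == 0L) next
      r0 <- (cand - 1L) %% nr + 1L
      c0 <- (cand - 1L) %/% nr + 1L
      cand <- cand[r0 > 1L & r0 < nr & c0 > 1L & c0 < nc]
      if (length(cand) == 0L) next
      centre <- d0[cand]
      is_max <- rep(TRUE, length(cand))
      is_min <- is_max
      for (lay in (s - 1L):(s + 1L)) {
        dl <- D[[lay]]
        for (dr in -1:1) for (dc in -1:1) {
          if (lay == s && dr == 0L && dc == 0L) next
          nb <- dl[cand + dr + dc * nr]
          is_max <- is_max & (centre > nb)
          is_min <- is_min & (centre < nb)
        }
      }
      sel <- cand[is_max | is_min]
      if (length(sel) == 0L) next
      # edge rejection via the 2x2 Hessian of the DoG layer
      dxx <- d0[sel + nr] + d0[sel - nr] - 2 * d0[sel]
      dyy <- d0[sel + 1L] + d0[sel - 1L] - 2 * d0[sel]
      dxy <- (d0[sel + 1L + nr] - d0[sel + 1L - nr] -
                d0[sel - 1L + nr] + d0[sel - 1L - nr]) / 4
      tr <- dxx + dyy
      det <- dxx * dyy - dxy^2
      keep <- det > 0 & tr^2 / det < (edge_ratio + 1)^2 / edge_ratio
      if (!any(keep)) next
      sel <- sel[keep]
      rr <- (sel - 1L) %% nr + 1L
      cc <- (sel - 1L) %/% nr + 1L
      kps[[length(kps) + 1L]] <- data.frame(
        col = (cc - 1) * 2^(o - 1) + 1,
        row = (rr - 1) * 2^(o - 1) + 1,
        octave = o, scale = s,
        sigma = sigma0 * 2^((s - 1) / n_scales) * 2^(o - 1),
        response = abs(d0[sel]),
        oct_row = rr, oct_col = cc)
    }
    # next octave: downsample the image at twice the base scale
    src <- G[[n_scales + 1L]]
    base <- src[seq(1L, nrow(src), by = 2L), seq(1L, ncol(src), by = 2L),
                drop = FALSE]
  }
  empty <- data.frame(col = numeric(0), row = numeric(0), octave = integer(0),
                      scale = integer(0), sigma = numeric(0),
                      response = numeric(0), oct_row = integer(0),
                      oct_col = integer(0), orientation = numeric(0))
  if (length(kps) == 0L) {
    return(list(kp = empty, n_keypoints = 0L, grads = list()))
  }
  kp <- do.call(rbind, kps)
  kp <- kp[order(-kp$response), , drop = FALSE]
  if (nrow(kp) > max_keypoints) kp <- kp[seq_len(max_keypoints), , drop = FALSE]
  n_located <- nrow(kp)
  # gradients of the pyramid layers actually used, computed once each
  grads <- list()
  need <- unique(kp[, c("octave", "scale")])
  for (k in seq_len(nrow(need))) {
    key <- sprintf("o%d_s%d", need$octave[k], need$scale[k])
    grads[[key]] <- sift_gradient(layers[[need$octave[k]]][[need$scale[k]]])
  }
  rows_out <- vector("list", 2L * nrow(kp))
  nout <- 0L
  for (k in seq_len(nrow(kp))) {
    g <- grads[[sprintf("o%d_s%d", kp$octave[k], kp$scale[k])]]
    oris <- dominant_orientations(g, kp$oct_row[k], kp$oct_col[k],
                                  sigma_rel = 1.5 * sigma0)
    for (ori in oris) {
      row <- kp[k, , drop = FALSE]
      row$orientation <- ori
      nout <- nout + 1L
      rows_out[[nout]] <- row
    }
  }
  out <- do.call(rbind, rows_out[seq_len(nout)])
  rownames(out) <- NULL
  list(kp = out, n_keypoints = n_located, grads = grads)
}

#' SIFT keypoints of a grey patch
#'
#' Detects scale-space extrema of the difference-of-Gaussian pyramid
#' (26-neighbour comparison), rejects low-contrast and edge-like responses,
#' and assigns one or two dominant gradient orientations per keypoint.
#'
#' @param gray Grey-value matrix in [0, 255].
#' @param n_octaves Number of pyramid octaves.
#' @param n_scales DoG levels searched per octave.
#' @param sigma0 Base smoothing scale in pixels.
#' @param contrast_threshold Minimum |DoG| response (image scaled to [0,1]).
#' @param edge_ratio Maximum principal-curvature ratio.
#' @param max_keypoints Keep at most this many strongest keypoints.
#' @return Data frame with columns `col`, `row` (base-image coordinates),
#'   `octave`, `scale`, `sigma`, `response`, `orientation`; attribute
#'   `n_keypoints` is the number of distinct located extrema (before
#'   orientation splitting).
#' @export
sift_keypoints <- function(gray, n_octaves = 3L, n_scales = 3L, sigma0 = 1.6,
                           contrast_threshold = 0.02, edge_ratio = 10,
                           max_keypoints = 80L) {
  det <- sift_detect(gray, n_octaves, n_scales, sigma0, contrast_threshold,
                     edge_ratio, max_keypoints)
  out <- det$kp
  attr(out, "n_keypoints") <- det$n_keypoints
  out
}

# orientation histogram peaks (36 bins, Gaussian-weighted window); returns
# the dominant orientation plus at most one secondary peak >= 80% of it
dominant_orientations <- function(grad, row, col, sigma_rel) {
  nr <- nrow(grad$val); nc <- ncol(grad$val)
  rad <- max(3L, as.integer(round(3 * sigma_rel)))
  r1 <- max(1L, row - rad):min(nr, row + rad)
  c1 <- max(1L, col - rad):min(nc, col + rad)
  dr <- outer(r1 - row, rep(1, length(c1)))
  dc <- outer(rep(1, length(r1)), c1 - col)
  w <- exp(-(dr^2 + dc^2) / (2 * sigma_rel^2)) * grad$val[r1, c1, drop = FALSE]
  ang <- grad$dir[r1, c1, drop = FALSE] %% (2 * pi)
  bins <- pmin(floor(ang / (2 * pi) * 36) + 1L, 36L)
  h <- numeric(36)
  acc <- rowsum(as.numeric(w), bins)
  h[as.integer(rownames(acc))] <- acc
  h <- (h + h[c(36, 1:35)] + h[c(2:36, 1)]) / 3  # circular smoothing
  if (max(h) <= 0) return(0)
  pk <- which.max(h)
  oris <- (pk - 0.5) / 36 * 2 * pi
  h2 <- h; h2[pk] <- -Inf
  pk2 <- which.max(h2)
  if (h[pk2] >= 0.8 * h[pk] && pk2 != pk) {
    oris <- c(oris, (pk2 - 0.5) / 36 * 2 * pi)
  }
  oris
}

# 128-d descriptor: 4x4 spatial cells x 8 orientation bins over a rotated,
# scale-normalised 16x16 sample grid (nearest-pixel sampling)
sift_descriptor <- function(grad, row, col, orientation, sigma_rel) {
  nr <- nrow(grad$val); nc <- ncol(grad$val)
  step <- sigma_rel / 1.6
  u <- rep(seq(-7.5, 7.5, by = 1), times = 16)
  v <- rep(seq(-7.5, 7.5, by = 1), each = 16)
  ct <- cos(orientation); st <- sin(orientation)
  sc <- col + step * (ct * u - st * v)
  sr <- row + step * (st * u + ct * v)
  pc <- pmin(pmax(as.integer(round(sc)), 1L), nc)
  pr <- pmin(pmax(as.integer(round(sr)), 1L), nr)
  idx <- (pc - 1L) * nr + pr
  mag <- grad$val[idx] * exp(-(u^2 + v^2) / (2 * 8^2))
  ang <- (grad$dir[idx] - orientation) %% (2 * pi)
  obin <- pmin(floor(ang / (2 * pi) * 8) + 1L, 8L)
  cellu <- pmin(floor((u + 8) / 4) + 1L, 4L)
  cellv <- pmin(floor((v + 8) / 4) + 1L, 4L)
  d <- numeric(128)
  flat <- ((cellv - 1L) * 4L + (cellu - 1L)) * 8L + obin
  acc <- rowsum(mag, flat)
  d[as.integer(rownames(acc))] <- acc
  nrm <- sqrt(sum(d^2))
  if (nrm > 0) {
    d <- pmin(d / nrm, 0.2)
    d <- d / sqrt(sum(d^2))
  }
  d
}

#' Aggregated SIFT features
#'
#' Runs the keypoint detector ([sift_keypoints()]), computes the 128-d
#' descriptor of every keypoint/orientation, and aggregates the
#' variable-count set into a fixed vector: the keypoint count plus the
#' per-dimension mean and standard deviation of the descriptors (zeros
#' when no keypoints are found).
#'
#' @inheritParams sift_keypoints
#' @return Named numeric vector of length 257.
#' @export
sift_features <- function(gray, n_octaves = 3L, n_scales = 3L, sigma0 = 1.6,
                          contrast_threshold = 0.02, edge_ratio = 10,
                          max_keypoints = 80L) {
  det <- sift_detect(gray, n_octaves, n_scales, sigma0, contrast_threshold,
                     edge_ratio, max_keypoints)
  nm <- c("sift_n_keypoints",
          sprintf("sift_desc_mean_%03d", 1:128),
          sprintf("sift_desc_sd_%03d", 1:128))
  kp <- det$kp
  if (nrow(kp) == 0L) {
    out <- c(0, numeric(256))
    names(out) <- nm
    return(out)
  }
  desc <- matrix(0, nrow(kp), 128)
  for (k in seq_len(nrow(kp))) {
    g <- det$grads[[sprintf("o%d_s%d", kp$octave[k], kp$scale[k])]]
    sig_rel <- sigma0 * 2^((kp$scale[k] - 1) / n_scales)
    desc[k, ] <- sift_descriptor(g, kp$oct_row[k], kp$oct_col[k],
                                 kp$orientation[k], sig_rel)
  }
  mu <- colMeans(desc)
  sdv <- if (nrow(desc) >= 2L) apply(desc, 2, stats::sd) else numeric(128)
  out <- c(det$n_keypoints, mu, sdv)
  names(out) <- nm
  out
}
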