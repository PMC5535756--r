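# Hand-crafted feature bank: intensity statistics, region morphology,
# grey-level co-occurrence statistics, local binary patterns and Tamura
# texture statistics.  SIFT aggregates live in sift.R.

#' Intensity summary features
#'
#' Summary statistics of the grey values over the whole patch
#' (`int_patch_*`) and within the nucleus mask (`int_nuc_*`): mean, median,
#' variance, standard deviation, skewness, kurtosis (excess), min, max,
#' range, and the lower/upper quartiles.  Skewness and kurtosis of a
#' constant region are reported as 0.
#'
#' @param gray Grey-value matrix.
#' @param mask Binary nucleus mask of the same dimensions.
#' @return Named numeric vector (22 values).
#' @export
intensity_features <- function(gray, mask) {
  check_mask(mask)
  stopifnot(all(dim(gray) == dim(mask)))
  stats_of <- function(x, prefix) {
    q <- stats::quantile(x, c(0.25, 0.75), names = FALSE)
    v <- c(mean = mean(x), median = stats::median(x),
           variance = mean((x - mean(x))^2),
           sd = sqrt(mean((x - mean(x))^2)),
           skewness = safe_moment_skewness(x),
           kurtosis = safe_moment_kurtosis(x),
           min = min(x), max = max(x), range = max(x) - min(x),
           q25 = q[1], q75 = q[2])
    names(v) <- paste0(prefix, names(v))
    v
  }
  c(stats_of(as.numeric(gray), "int_patch_"),
    stats_of(as.numeric(gray[mask == 1]), "int_nuc_"))
}

#' Morphology features of the nucleus mask
#'
#' Area (pixel count), perimeter, equivalent diameter, major/minor axis
#' lengths (from second-order central moments, as in standard region
#' properties), eccentricity, solidity (area over convex-hull area),
#' extent (area over bounding-box area), centroid offset from the patch
#' centre, and the nucleocytoplasmic ratio (mask area over patch area).
#' The perimeter is the traced 8-connected contour length when the
#' component is border-free, otherwise the count of exposed 4-edges.
#'
#' @param mask Binary 0/1 matrix with a single foreground component.
#' @return Named numeric vector (10 values).
#' @export
morphology_features <- function(mask) {
  check_mask(mask)
  nr <- nrow(mask); nc <- ncol(mask)
  idx <- which(mask == 1)
  rows <- (idx - 1L) %% nr + 1L
  cols <- (idx - 1L) %/% nr + 1L
  area <- length(idx)
  if (!mask_touches_border(mask) && count_components4(mask) == 1L) {
    perim <- contour_perimeter(trace_contour(mask))
  } else {
    # exposed 4-edge count (frame boundary counts as background)
    p <- matrix(0, nr + 2L, nc + 2L)
    p[2:(nr + 1L), 2:(nc + 1L)] <- mask
    inner <- p[2:(nr + 1L), 2:(nc + 1L)]
    perim <- sum(inner * (4 - p[1:nr, 2:(nc + 1L)] - p[3:(nr + 2L), 2:(nc + 1L)] -
                            p[2:(nr + 1L), 1:nc] - p[2:(nr + 1L), 3:(nc + 2L)]))
  }
  cx <- mean(cols); cy <- mean(rows)
  # second-order central moments with the 1/12 pixel-extent term
  mu20 <- mean((cols - cx)^2) + 1 / 12
  mu02 <- mean((rows - cy)^2) + 1 / 12
  mu11 <- mean((cols - cx) * (rows - cy))
  common <- sqrt(max(0, (mu20 - mu02)^2 + 4 * mu11^2))
  l1 <- (mu20 + mu02 + common) / 2
  l2 <- (mu20 + mu02 - common) / 2
  major <- 4 * sqrt(max(l1, 0))
  minor <- 4 * sqrt(max(l2, 0))
  ecc <- if (l1 > 0) sqrt(max(0, 1 - l2 / l1)) else 0
  # convex hull area of boundary pixel centres, corrected to pixel counts
  # (polygon area + boundary length / 2 + 1, Pick-style)
  hull_area <- area
  if (area >= 3) {
    h <- grDevices::chull(cols, rows)
    hx <- cols[h]; hy <- rows[h]
    n <- length(h)
    if (n >= 3) {
      j <- c(2:n, 1L)
      a_poly <- abs(sum(hx * hy[j] - hx[j] * hy)) / 2
      p_poly <- sum(sqrt((hx[j] - hx)^2 + (hy[j] - hy)^2))
      hull_area <- a_poly + p_poly / 2 + 1
    }
  }
  bbox <- (max(cols) - min(cols) + 1) * (max(rows) - min(rows) + 1)
  c(morph_area = area,
    morph_perimeter = perim,
    morph_equiv_diameter = 2 * sqrt(area / pi),
    morph_major_axis = major,
    morph_minor_axis = minor,
    morph_eccentricity = ecc,
    morph_solidity = area / hull_area,
    morph_extent = area / bbox,
    morph_centroid_offset = sqrt((cx - (nc + 1) / 2)^2 + (cy - (nr + 1) / 2)^2),
    morph_nc_ratio = area / (nr * nc))
}

#' Grey-level co-occurrence matrix
#'
#' Quantises the grey values into `levels` equal-width bins over [0, 255],
#' accumulates co-occurrences at the given pixel offset, symmetrises and
#' normalises to sum 1.
#'
#' @param gray Grey-value matrix (values in [0, 255]).
#' @param levels Number of grey levels (>= 2).
#' @param offset Integer pair `(dcol, drow)`.
#' @return `levels` x `levels` matrix summing to 1.
#' @export
glcm_matrix <- function(gray, levels = 16L, offset = c(1L, 0L)) {
  if (levels < 2) stop("levels must be >= 2", call. = FALSE)
  q <- pmin(floor(gray * levels / 256) + 1L, levels)
  nr <- nrow(q); nc <- ncol(q)
  dc <- offset[1L]; dr <- offset[2L]
  r1 <- max(1L, 1L - dr):min(nr, nr - dr)
  c1 <- max(1L, 1L - dc):min(nc, nc - dc)
  a <- q[r1, c1, drop = FALSE]
  b <- q[r1 + dr, c1 + dc, drop = FALSE]
  counts <- matrix(tabulate((a - 1L) * levels + b, nbins = levels * levels),
                   levels, levels, byrow = TRUE)
  counts <- counts + t(counts)  # symmetrise
  counts / sum(counts)
}

#' GLCM statistics
#'
#' The five classical co-occurrence statistics of a normalised GLCM `P`:
#' angular second moment `ASM = sum(P^2)`, entropy
#' `ENT = -sum(P log P)` (natural log), contrast
#' `CON = sum((i-j)^2 P)`, correlation `COR` using the marginal means and
#' standard deviations, and the inverse difference moment
#' `IDM = sum(P / (1 + (i-j)^2))`.  `idm = "literal"` uses the denominator
#' `1 + (i+j)^2` instead (a printed variant kept for comparison; it is not
#' a homogeneity measure).  For a constant image the marginal SDs are 0 and
#' `COR` is reported as 0 with attribute `cor_undefined = TRUE`.
#'
#' @param P Normalised co-occurrence matrix.
#' @param idm `"standard"` or `"literal"`.
#' @return Named vector `ASM`, `ENT`, `CON`, `COR`, `IDM`.
#' @export
glcm_stats <- function(P, idm = c("standard", "literal")) {
  idm <- match.arg(idm)
  n <- nrow(P)
  i <- matrix(rep(seq_len(n), times = n), n)   # row index
  j <- matrix(rep(seq_len(n), each = n), n)
  asm <- sum(P^2)
  ent <- -sum(P[P > 0] * log(P[P > 0]))
  con <- sum((i - j)^2 * P)
  px <- rowSums(P); py <- colSums(P)
  ux <- sum(seq_len(n) * px); uy <- sum(seq_len(n) * py)
  sx <- sqrt(sum((seq_len(n) - ux)^2 * px))
  sy <- sqrt(sum((seq_len(n) - uy)^2 * py))
  cor_undef <- sx < 1e-12 || sy < 1e-12
  cor <- if (cor_undef) 0 else (sum(i * j * P) - ux * uy) / (sx * sy)
  idm_v <- if (idm == "standard") sum(P / (1 + (i - j)^2)) else
    sum(P / (1 + (i + j)^2))
  out <- c(ASM = asm, ENT = ent, CON = con, COR = cor, IDM = idm_v)
  attr(out, "cor_undefined") <- cor_undef
  out
}

# default offsets: distance 1 at 0, 45, 90, 135 degrees in (dcol, drow)
.glcm_offsets <- list(`0` = c(1L, 0L), `45` = c(1L, -1L),
                      `90` = c(0L, -1L), `135` = c(-1L, -1L))

#' GLCM feature vector
#'
#' The five statistics per offset plus their mean over offsets.
#'
#' @inheritParams glcm_matrix
#' @param offsets Named list of `(dcol, drow)` offsets.
#' @param idm Passed to [glcm_stats()].
#' @return Named numeric vector of length `5 * (length(offsets) + 1)`.
#' @export
glcm_features <- function(gray, levels = 16L, offsets = .glcm_offsets,
                          idm = "standard") {
  per <- lapply(offsets, function(off) {
    glcm_stats(glcm_matrix(gray, levels, off), idm = idm)
  })
  out <- numeric(0)
  for (nm in names(per)) {
    v <- per[[nm]]
    names(v) <- paste0("glcm_", names(v), "_", nm)
    out <- c(out, v)
  }
  m <- rowMeans(do.call(cbind, per))
  names(m) <- paste0("glcm_", names(m), "_mean")
  c(out, m)
}

# uniform-pattern (u2) mapping: 256 codes -> 59 bins
.lbp_uniform_map <- local({
  map <- integer(256)
  nextbin <- 1L
  for (code in 0:255) {
    bits <- as.integer(intToBits(code))[1:8]
    trans <- sum(bits != bits[c(2:8, 1)])
    if (trans <= 2L) {
      map[code + 1L] <- nextbin
      nextbin <- nextbin + 1L
    } else {
      map[code + 1L] <- 59L
    }
  }
  map
})

#' Local binary pattern cell histograms
#'
#' Computes the 8-neighbour LBP code of every pixel (a neighbour is marked
#' 1 when the centre grey value is less than the neighbour's; image borders
#' are replicate-padded), divides the patch into 16x16-pixel cells, builds a
#' normalised code histogram per cell, and concatenates the cell histograms
#' in row-major cell order.  `mode = "raw"` keeps all 256 codes per cell;
#' `mode = "uniform"` maps codes to the 59 uniform-pattern bins.
#'
#' Bit order: neighbours clockwise from the top-left, with bit weights
#' 1, 2, 4, ..., 128.
#'
#' @param gray Grey-value matrix whose sides are multiples of `cell`.
#' @param cell Cell side length in pixels.
#' @param mode `"raw"` (256 bins) or `"uniform"` (59 bins).
#' @return Named numeric vector; each cell's bins sum to 1.
#' @export
lbp_histogram <- function(gray, cell = 16L, mode = c("raw", "uniform")) {
  mode <- match.arg(mode)
  nr <- nrow(gray); nc <- ncol(gray)
  if (nr %% cell != 0 || nc %% cell != 0) {
    stop("image sides must be divisible by the cell size", call. = FALSE)
  }
  p <- pad_replicate(gray, 1L)
  # neighbours clockwise from top-left, (drow, dcol)
  nbr <- list(c(-1L, -1L), c(-1L, 0L), c(-1L, 1L), c(0L, 1L),
              c(1L, 1L), c(1L, 0L), c(1L, -1L), c(0L, -1L))
  code <- matrix(0L, nr, nc)
  w <- 1L
  for (d in nbr) {
    shifted <- p[1L + d[1L] + seq_len(nr), 1L + d[2L] + seq_len(nc),
                 drop = FALSE]
    code <- code + w * (gray < shifted)
    w <- w * 2L
  }
  nbins <- if (mode == "raw") 256L else 59L
  cells_r <- nr %/% cell
  cells_c <- nc %/% cell
  out <- numeric(cells_r * cells_c * nbins)
  nm <- character(length(out))
  k <- 0L
  for (cr in seq_len(cells_r)) {
    for (cc in seq_len(cells_c)) {
      block <- code[(cr - 1L) * cell + seq_len(cell),
                    (cc - 1L) * cell + seq_len(cell)]
      v <- as.integer(block)
      if (mode == "uniform") v <- .lbp_uniform_map[v + 1L] - 1L
      h <- tabulate(v + 1L, nbins = nbins)
      h <- h / sum(h)
      out[k + seq_len(nbins)] <- h
      nm[k + seq_len(nbins)] <-
        sprintf("lbp_c%d%d_b%03d", cr, cc, seq_len(nbins) - 1L)
      k <- k + nbins
    }
  }
  names(out) <- nm
  out
}

#' Tamura texture features
#'
#' The three classical Tamura statistics:
#' * coarseness — per pixel, box means over windows `windows` are compared
#'   at opposite half-window offsets horizontally and vertically; the
#'   window with the largest difference wins and coarseness is the mean
#'   winning window size;
#' * contrast — `sigma / kurtosis^(1/4)` with `kurtosis = mu4 / sigma^4`
#'   (0 for a constant image);
#' * directionality — peakedness of the gradient-orientation histogram
#'   (16 bins over half a turn, gradient magnitudes above a small threshold),
#'   scaled so an orientation-free image scores near 0 and a single
#'   orientation scores near 1.
#'
#' @param gray Grey-value matrix.
#' @param windows Coarseness window sizes in pixels.
#' @param grad_threshold Minimum mean absolute gradient for a pixel to vote
#'   in the orientation histogram.
#' @return Named vector `tamura_coarseness`, `tamura_contrast`,
#'   `tamura_directionality`.
#' @export
tamura_features <- function(gray, windows = c(1L, 2L, 4L, 8L, 16L),
                            grad_threshold = 12) {
  nr <- nrow(gray); nc <- ncol(gray)
  # coarseness
  best_sz <- matrix(windows[1L], nr, nc)
  best_e <- matrix(-Inf, nr, nc)
  for (w in windows) {
    A <- box_mean(gray, w)
    h <- max(1L, w %/% 2L)
    Ap <- pad_replicate(A, h)
    eh <- abs(Ap[h + seq_len(nr), h + h + seq_len(nc), drop = FALSE] -
                Ap[h + seq_len(nr), seq_len(nc), drop = FALSE])
    ev <- abs(Ap[h + h + seq_len(nr), h + seq_len(nc), drop = FALSE] -
                Ap[seq_len(nr), h + seq_len(nc), drop = FALSE])
    e <- pmax(eh, ev)
    upd <- e > best_e + 1e-12
    best_sz[upd] <- w
    best_e[upd] <- e[upd]
  }
  coarseness <- mean(best_sz)
  # contrast
  x <- as.numeric(gray)
  s2 <- mean((x - mean(x))^2)
  contrast <- if (s2 < 1e-12) 0 else {
    kurt <- mean((x - mean(x))^4) / s2^2
    sqrt(s2) / kurt^0.25
  }
  # directionality
  p <- pad_replicate(gray, 1L)
  gx <- (p[1L + seq_len(nr), 2L + seq_len(nc)] -
           p[1L + seq_len(nr), seq_len(nc)]) / 2
  gy <- (p[2L + seq_len(nr), 1L + seq_len(nc)] -
           p[seq_len(nr), 1L + seq_len(nc)]) / 2
  mag <- (abs(gx) + abs(gy)) / 2
  keep <- mag >= grad_threshold
  if (!any(keep)) {
    directionality <- 0
  } else {
    ang <- atan2(gy[keep], gx[keep]) %% pi  # orientation in [0, pi)
    nb <- 16L
    h <- tabulate(pmin(floor(ang / pi * nb) + 1L, nb), nbins = nb)
    h <- h / sum(h)
    peak <- which.max(h)
    centers <- (seq_len(nb) - 0.5) * pi / nb
    d <- abs(centers - centers[peak])
    d <- pmin(d, pi - d)  # wrapped angular distance, period pi
    spread <- sum(h * d^2)
    directionality <- max(0, 1 - spread / (pi^2 / 12))  # uniform -> ~0
  }
  c(tamura_coarseness = coarseness, tamura_contrast = contrast,
    tamura_directionality = directionality)
}
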