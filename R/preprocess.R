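# Patch preprocessing: bilateral filtering and contour tracing.

#' Bilateral filter
#'
#' Edge-preserving smoothing: each output pixel is a normalised weighted
#' mean of its window, with weights the product of a spatial Gaussian and a
#' grey-level (range) Gaussian.  As `sigma_range` grows the filter tends to
#' a plain truncated Gaussian blur; on a constant image it is the identity.
#'
#' @param gray Numeric matrix of grey values.
#' @param sigma_spatial Spatial Gaussian width in pixels.
#' @param sigma_range Range Gaussian width in grey levels (0-255 scale).
#' @param window Odd window side length.
#' @return Filtered matrix of the same dimensions; values stay within the
#'   input range.
#' @export
#' @examples
#' img <- matrix(runif(64 * 64, 0, 255), 64)
#' f <- bilateral_filter(img)
bilateral_filter <- function(gray, sigma_spatial = 3, sigma_range = 25,
                             window = 7L) {
  if (!is.matrix(gray) || length(gray) == 0) {
    stop("gray must be a nonempty matrix", call. = FALSE)
  }
  stopifnot_scalar(sigma_spatial, "sigma_spatial", positive = TRUE)
  stopifnot_scalar(sigma_range, "sigma_range", positive = TRUE)
  if (window %% 2 != 1 || window < 1) {
    stop("window must be a positive odd integer", call. = FALSE)
  }
  r <- (window - 1L) %/% 2L
  p <- pad_replicate(gray, r)
  nr <- nrow(gray); nc <- ncol(gray)
  acc <- matrix(0, nr, nc)
  wsum <- matrix(0, nr, nc)
  for (dr in -r:r) {
    for (dc in -r:r) {
      shifted <- p[r + dr + seq_len(nr), r + dc + seq_len(nc), drop = FALSE]
      ws <- exp(-(dr^2 + dc^2) / (2 * sigma_spatial^2))
      w <- ws * exp(-((shifted - gray)^2) / (2 * sigma_range^2))
      acc <- acc + w * shifted
      wsum <- wsum + w
    }
  }
  acc / wsum
}

# Moore neighbourhood in clockwise screen order (col right, row down),
# starting West.  Columns: dcol, drow.
.moore_dirs <- matrix(c(-1L,  0L,   # W
                        -1L, -1L,   # NW
                         0L, -1L,   # N
                         1L, -1L,   # NE
                         1L,  0L,   # E
                         1L,  1L,   # SE
                         0L,  1L,   # S
                        -1L,  1L),  # SW
                      ncol = 2L, byrow = TRUE)

#' Trace the nucleus boundary
#'
#' Moore-neighbour tracing with Jacob's stopping criterion, clockwise in
#' image coordinates (origin top-left, columns increasing right, rows
#' increasing down), starting from the topmost of the leftmost foreground
#' pixels.  The mask must contain exactly one 4-connected foreground
#' component that does not touch the image border.
#'
#' @param mask Binary 0/1 matrix.
#' @return An n x 2 integer matrix with columns `col`, `row`, ordered
#'   clockwise; attribute `closed = TRUE`.
#' @export
#' @examples
#' m <- matrix(0, 8, 8); m[3:5, 3:5] <- 1
#' trace_contour(m)
trace_contour <- function(mask) {
  check_mask(mask)
  if (mask_touches_border(mask)) {
    stop("foreground component touches the image border", call. = FALSE)
  }
  ncomp <- count_components4(mask)
  if (ncomp != 1L) {
    stop(sprintf("mask must contain exactly one component (found %d)", ncomp),
         call. = FALSE)
  }
  nr <- nrow(mask)
  fg <- which(mask == 1)
  cols <- (fg - 1L) %/% nr + 1L
  rows <- (fg - 1L) %% nr + 1L
  cmin <- min(cols)
  start <- c(cmin, min(rows[cols == cmin]))  # topmost of leftmost
  is_fg <- function(p) mask[p[2L], p[1L]] == 1
  dir_index <- function(d) {
    which(.moore_dirs[, 1L] == d[1L] & .moore_dirs[, 2L] == d[2L])
  }
  pts_list <- list(start)
  cur <- start
  bpos <- start + c(-1L, 0L)  # West neighbour is background (leftmost column)
  first_move <- NULL
  iter <- 0L
  repeat {
    iter <- iter + 1L
    if (iter > 8L * length(fg) + 8L) {
      stop("contour tracing failed to terminate", call. = FALSE)
    }
    d0 <- dir_index(bpos - cur)
    lastbg <- bpos
    found <- FALSE
    for (k in 1:8) {
      idx <- (d0 + k - 1L) %% 8L + 1L
      cand <- cur + .moore_dirs[idx, ]
      if (is_fg(cand)) { found <- TRUE; break }
      lastbg <- cand
    }
    if (!found) break  # isolated single pixel
    if (cur[1L] == start[1L] && cur[2L] == start[2L]) {
      if (is.null(first_move)) {
        first_move <- cand
      } else if (cand[1L] == first_move[1L] && cand[2L] == first_move[2L]) {
        break  # Jacob's criterion: leaving start the same way twice
      }
    }
    if (!(cand[1L] == start[1L] && cand[2L] == start[2L])) {
      pts_list[[length(pts_list) + 1L]] <- cand
    }
    bpos <- lastbg
    cur <- cand
  }
  pts <- do.call(rbind, pts_list)
  dimnames(pts) <- list(NULL, c("col", "row"))
  attr(pts, "closed") <- TRUE
  pts
}

#' Length of a traced contour
#'
#' Sum of step lengths between consecutive contour points (1 for 4-steps,
#' sqrt(2) for diagonal steps), including the closing step.
#'
#' @param contour Matrix from [trace_contour()].
#' @param closed Include the closing segment.
#' @return Numeric length in pixels.
#' @export
contour_perimeter <- function(contour, closed = TRUE) {
  n <- nrow(contour)
  if (n < 2L) return(0)
  nxt <- if (closed) c(2:n, 1L) else 2:n
  cur <- if (closed) 1:n else 1:(n - 1L)
  sum(sqrt(rowSums((contour[nxt, , drop = FALSE] -
                      contour[cur, , drop = FALSE])^2)))
}
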