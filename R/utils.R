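# Internal helpers shared across modules.

# canonical label levels; "abnormal" is the positive (HCC) class everywhere
.class_levels <- c("normal", "abnormal")

as_class_factor <- function(labels) {
  f <- factor(as.character(labels), levels = .class_levels)
  if (anyNA(f)) {
    stop("labels must be 'normal' or 'abnormal'", call. = FALSE)
  }
  f
}

# Evaluate `code` with the RNG seeded to `seed`, restoring the caller's RNG
# state afterwards so library code never clobbers the session stream.
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = genv)
    } else if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
      rm(".Random.seed", envir = genv)
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

# Per-item substream seed derived from a master seed.  Linear congruential
# mix kept below 2^31 - 1; exact in double arithmetic (max product < 2^53).
derive_seed <- function(seed, i) {
  as.integer(((abs(seed) %% 2147483647) * 48271 + i * 69621) %% 2147483647)
}

stopifnot_scalar <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("'%s' must be a finite numeric scalar", name), call. = FALSE)
  }
  if (positive && x <= 0) {
    stop(sprintf("'%s' must be > 0", name), call. = FALSE)
  }
  invisible(x)
}

check_mask <- function(mask) {
  if (!is.matrix(mask) || any(!mask %in% c(0, 1))) {
    stop("mask must be a binary (0/1) matrix", call. = FALSE)
  }
  if (sum(mask) == 0) stop("mask is empty", call. = FALSE)
  invisible(mask)
}

# Number of 4-connected foreground components (iterative flood fill).
count_components4 <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  seen <- matrix(FALSE, nr, nc)
  ncomp <- 0L
  fg <- which(mask == 1)
  stack <- integer(length(fg))
  for (start in fg) {
    if (seen[start]) next
    ncomp <- ncomp + 1L
    top <- 1L
    stack[1L] <- start
    seen[start] <- TRUE
    while (top > 0L) {
      p <- stack[top]
      top <- top - 1L
      r <- (p - 1L) %% nr + 1L
      c <- (p - 1L) %/% nr + 1L
      if (r > 1L && mask[p - 1L] == 1 && !seen[p - 1L]) {
        seen[p - 1L] <- TRUE; top <- top + 1L; stack[top] <- p - 1L
      }
      if (r < nr && mask[p + 1L] == 1 && !seen[p + 1L]) {
        seen[p + 1L] <- TRUE; top <- top + 1L; stack[top] <- p + 1L
      }
      if (c > 1L && mask[p - nr] == 1 && !seen[p - nr]) {
        seen[p - nr] <- TRUE; top <- top + 1L; stack[top] <- p - nr
      }
      if (c < nc && mask[p + nr] == 1 && !seen[p + nr]) {
        seen[p + nr] <- TRUE; top <- top + 1L; stack[top] <- p + nr
      }
    }
  }
  ncomp
}

mask_touches_border <- function(mask) {
  any(mask[1, ] == 1) || any(mask[nrow(mask), ] == 1) ||
    any(mask[, 1] == 1) || any(mask[, ncol(mask)] == 1)
}

# Replicate-pad a matrix by `r` pixels on every side.
pad_replicate <- function(m, r) {
  nr <- nrow(m); nc <- ncol(m)
  ri <- c(rep(1L, r), seq_len(nr), rep(nr, r))
  ci <- c(rep(1L, r), seq_len(nc), rep(nc, r))
  m[ri, ci, drop = FALSE]
}

# Separable Gaussian blur with replicate padding (shift-and-accumulate;
# images here are 64x64 so this stays cheap).
gaussian_blur <- function(m, sigma) {
  if (sigma <= 0) return(m)
  r <- max(1L, as.integer(ceiling(3 * sigma)))
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k <- k / sum(k)
  p <- pad_replicate(m, r)
  nr <- nrow(m); nc <- ncol(m)
  # horizontal pass
  h <- matrix(0, nr + 2 * r, nc)
  for (i in seq_along(k)) {
    h <- h + k[i] * p[, (i - 1L) + seq_len(nc), drop = FALSE]
  }
  # vertical pass
  out <- matrix(0, nr, nc)
  for (i in seq_along(k)) {
    out <- out + k[i] * h[(i - 1L) + seq_len(nr), , drop = FALSE]
  }
  out
}

# Box mean of window w (odd or even) using an integral image on a
# replicate-padded matrix; window is centred (even windows lean up-left).
box_mean <- function(m, w) {
  if (w <= 1) return(m)
  lo <- w %/% 2L
  hi <- w - lo - 1L
  p <- pad_replicate(m, w)
  ii <- apply(apply(p, 2, cumsum), 1, cumsum)  # transposed integral image
  ii <- t(ii)
  nr <- nrow(m); nc <- ncol(m)
  r1 <- w + seq_len(nr) - lo - 1L
  r2 <- w + seq_len(nr) + hi
  c1 <- w + seq_len(nc) - lo - 1L
  c2 <- w + seq_len(nc) + hi
  z <- rbind(0, cbind(0, ii))
  (z[r2 + 1L, c2 + 1L, drop = FALSE] - z[r1, c2 + 1L, drop = FALSE] -
     z[r2 + 1L, c1, drop = FALSE] + z[r1, c1, drop = FALSE]) / (w * w)
}

safe_moment_skewness <- function(x) {
  s <- sqrt(mean((x - mean(x))^2))
  if (s < 1e-12) return(0)
  mean((x - mean(x))^3) / s^3
}

safe_moment_kurtosis <- function(x) {
  s <- sqrt(mean((x - mean(x))^2))
  if (s < 1e-12) return(0)
  mean((x - mean(x))^4) / s^4 - 3
}
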