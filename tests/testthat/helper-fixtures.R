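# Shared fixtures, built in code.

# rasterised disc: pixel centres within radius r of (cx, cy)
make_disc_mask <- function(r = 10, cx = 32, cy = 32, size = 64L) {
  col <- matrix(rep(seq_len(size), each = size), nrow = size)
  row <- matrix(rep(seq_len(size), times = size), nrow = size)
  matrix(as.numeric((col - cx)^2 + (row - cy)^2 <= r^2), size, size)
}

make_square_mask <- function(side = 10L, top = 20L, left = 20L, size = 64L) {
  m <- matrix(0, size, size)
  m[top:(top + side - 1L), left:(left + side - 1L)] <- 1
  m
}

# independent pair-scan oracle for the slope-difference alternation count:
# plain loop, zeros inherit the last nonzero sign
oracle_alternations <- function(dk) {
  s <- sign(dk)
  last <- 0
  count <- 0L
  prev <- 0
  for (i in seq_along(s)) {
    si <- if (s[i] == 0) last else s[i]
    if (s[i] != 0) last <- s[i]
    if (prev != 0 && si != 0 && prev * si < 0) count <- count + 1L
    if (si != 0) prev <- si
  }
  count
}

# nested-loop GLCM oracle: count pixel pairs directly, symmetrise, normalise
oracle_glcm <- function(gray, levels, offset) {
  q <- pmin(floor(gray * levels / 256) + 1L, levels)
  nr <- nrow(q); nc <- ncol(q)
  counts <- matrix(0, levels, levels)
  for (r in seq_len(nr)) {
    for (c in seq_len(nc)) {
      r2 <- r + offset[2L]; c2 <- c + offset[1L]
      if (r2 >= 1 && r2 <= nr && c2 >= 1 && c2 <= nc) {
        counts[q[r, c], q[r2, c2]] <- counts[q[r, c], q[r2, c2]] + 1
      }
    }
  }
  counts <- counts + t(counts)
  counts / sum(counts)
}

# small planted feature matrix for selection tests: rows 1-2 informative
# (class means +/- delta), row 3 duplicates row 1, the rest pure noise
make_planted_fs <- function(n_per_class = 100, n_noise = 17, delta = 0.5,
                            noise_sd = 0.2, seed = 1) {
  set.seed(seed)
  n <- 2L * n_per_class
  labels <- rep(c("normal", "abnormal"), each = n_per_class)
  informative <- function() {
    c(rnorm(n_per_class, delta, noise_sd), rnorm(n_per_class, -delta, noise_sd))
  }
  f1 <- informative()
  f2 <- informative()
  rows <- rbind(f1, f2, f1,
                matrix(rnorm(n_noise * n, 0, 1), n_noise, n))
  rownames(rows) <- c("inf1", "inf2", "dup1",
                      sprintf("noise%02d", seq_len(n_noise)))
  colnames(rows) <- sprintf("s%03d", seq_len(n))
  list(fs = feature_matrix(rows), labels = labels)
}

# tiny patch set + cheap feature config for pipeline-level tests
quick_config <- function(seed = 1, n_train = 10L, n_test = 5L, ...) {
  experiment_config(
    seed = seed, n_train_per_class = n_train, n_test_per_class = n_test,
    features = feature_config(groups = c("intensity", "morphology", "glcm"),
                              filter = FALSE),
    ...)
}
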