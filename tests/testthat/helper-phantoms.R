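# Shared fixture builders. Everything is generated in code at test time.

# Small lesion phantom in the high-contrast regime used for segmentation
# work (two-level background + noise, lesion ~12x noise).
seg_phantom <- function(seed = 3, semi_axes = c(10, 8, 6),
                        center = c(32, 32, 12), contrast = 60) {
  generate_phantom(lesion = list(center = center, semi_axes = semi_axes,
                                 contrast = contrast),
                   texture_sd = 2, noise_sd = 5, seed = seed)
}

# Standard seed set for seg_phantom: glioma triangle at the lesion center,
# normal triangle in healthy tissue.
seg_seeds <- function(slice = 12L) {
  tibble::tibble(
    slice = slice,
    row = c(32, 30, 34, 16, 16, 24),
    col = c(32, 28, 36, 16, 26, 16),
    label = factor(c("glioma", "glioma", "glioma",
                     "normal", "normal", "normal"),
                   levels = c("glioma", "normal")))
}

# Tiny detection cohort (already normalized) for classifier-level tests.
small_cohort <- function(n = 4, seed = 7, contrast = 30) {
  normalize_cohort(generate_detection_cohort(n_pos = n, n_neg = n,
                                             contrast = contrast,
                                             seed = seed))
}

# Brute-force HOG oracle: per-pixel gradient, unsigned angle, linear
# circular binning, L2 normalization — written independently of the
# package's vectorized path.
oracle_hog <- function(patch, n_bins = 9, epsilon = 1e-6) {
  nr <- nrow(patch); nc <- ncol(patch)
  h <- numeric(n_bins)
  width <- 180 / n_bins
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    ip <- min(i + 1, nr); im <- max(i - 1, 1)
    jp <- min(j + 1, nc); jm <- max(j - 1, 1)
    gy <- (patch[ip, j] - patch[im, j]) / 2
    gx <- (patch[i, jp] - patch[i, jm]) / 2
    mag <- sqrt(gx^2 + gy^2)
    if (mag == 0) next
    th <- (atan2(gy, gx) * 180 / pi) %% 180
    pos <- th / width
    lo <- floor(pos); frac <- pos - lo
    h[(lo %% n_bins) + 1] <- h[(lo %% n_bins) + 1] + mag * (1 - frac)
    h[((lo + 1) %% n_bins) + 1] <- h[((lo + 1) %% n_bins) + 1] + mag * frac
  }
  nrm <- sqrt(sum(h^2))
  if (nrm == 0) h else h / (nrm + epsilon)
}

# Brute-force FCM oracle: direct alternating formula evaluation from many
# random restarts, keeping the lowest-objective solution.
oracle_fcm <- function(points, c = 2, m = 2, n_restarts = 25, iters = 300,
                       seed = 1) {
  points <- as.matrix(points)
  best <- NULL
  set.seed(seed)
  for (r in seq_len(n_restarts)) {
    v <- points[sample(nrow(points), c), , drop = FALSE] +
      matrix(stats::rnorm(c * ncol(points), sd = 1e-3), c)
    for (it in seq_len(iters)) {
      d2 <- sapply(seq_len(c), function(i)
        colSums((t(points) - v[i, ])^2))
      d2 <- matrix(d2, ncol = c)
      u <- matrix(0, nrow(points), c)
      for (k in seq_len(nrow(points))) {
        if (any(d2[k, ] == 0)) {
          u[k, ] <- (d2[k, ] == 0) / sum(d2[k, ] == 0)
        } else {
          w <- d2[k, ]^(-1 / (m - 1))
          u[k, ] <- w / sum(w)
        }
      }
      v_new <- t(sapply(seq_len(c), function(i)
        colSums(points * u[, i]^m) / sum(u[, i]^m)))
      v_new <- matrix(v_new, nrow = c)
      if (max(abs(v_new - v)) < 1e-10) { v <- v_new; break }
      v <- v_new
    }
    obj <- sum(sapply(seq_len(c), function(i)
      u[, i]^m * colSums((t(points) - v[i, ])^2)))
    if (is.null(best) || obj < best$obj)
      best <- list(centroids = v, memberships = u, obj = obj)
  }
  best
}

# All-pairs AUC oracle with half-credit for ties.
oracle_auc <- function(scores, positive) {
  sp <- scores[positive]; sn <- scores[!positive]
  tot <- 0
  for (a in sp) for (b in sn)
    tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(sp) * length(sn))
}

# Match two centroid sets up to row permutation; returns max abs deviation.
centroid_mismatch <- function(a, b) {
  d1 <- max(abs(a - b))
  d2 <- max(abs(a - b[c(2, 1), , drop = FALSE]))
  min(d1, d2)
}
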