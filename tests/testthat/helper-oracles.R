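# Independent brute-force oracles and small fixture builders. Every oracle
# here deliberately uses a different code path (explicit loops, exhaustive
# enumeration) from the implementation it checks.

# Two-pass looped region means: H(phi) = 1 iff phi >= 0.
bf_region_means <- function(image, phi) {
  s1 <- n1 <- s2 <- n2 <- 0
  for (i in seq_len(nrow(image))) {
    for (j in seq_len(ncol(image))) {
      if (phi[i, j] >= 0) {
        s1 <- s1 + image[i, j]; n1 <- n1 + 1
      } else {
        s2 <- s2 + image[i, j]; n2 <- n2 + 1
      }
    }
  }
  list(c1 = s1 / n1, c2 = s2 / n2)
}

# Pixel-looped confusion counts.
bf_confusion <- function(pred, truth) {
  tp <- fp <- tn <- fn <- 0L
  for (k in seq_along(pred)) {
    if (pred[k] && truth[k]) tp <- tp + 1L
    else if (pred[k] && !truth[k]) fp <- fp + 1L
    else if (!pred[k] && truth[k]) fn <- fn + 1L
    else tn <- tn + 1L
  }
  list(tp = tp, fp = fp, tn = tn, fn = fn)
}

# Optimal 2-means of weighted 1-D values by exhaustive enumeration of all
# contiguous 2-partitions of the sorted support (optimal 1-D clusters are
# intervals).
bf_kmeans2 <- function(values) {
  uv <- sort(unique(values))
  w <- tabulate(match(values, uv), nbins = length(uv))
  best <- NULL
  best_sse <- Inf
  for (cut in seq_len(length(uv) - 1L)) {
    lo <- seq_len(cut)
    hi <- (cut + 1L):length(uv)
    m1 <- sum(w[lo] * uv[lo]) / sum(w[lo])
    m2 <- sum(w[hi] * uv[hi]) / sum(w[hi])
    sse <- sum(w[lo] * (uv[lo] - m1)^2) + sum(w[hi] * (uv[hi] - m2)^2)
    if (sse < best_sse) {
      best_sse <- sse
      best <- c(m1, m2)
    }
  }
  best
}

random_mask <- function(nr, nc, p = 0.5) {
  matrix(stats::runif(nr * nc) < p, nr, nc)
}

# Separable noiseless phantom used by the exactness checks: the three base
# intensities survive untouched, so Stage 1 and Stage 2 admit closed-form
# truth.
noiseless_phantom <- function() {
  generate_phantom(phantom_params(
    height = 96L, width = 128L, band_center_row = 48, band_curvature = 8,
    band_thickness = 40L, mu_bg = 0.10, mu_band = 0.75, mu_fluid = 0.12,
    pockets = list(c(50, 44, 6, 12), c(46, 90, 5, 9)),
    speckle_shape = 0, blur_sigma = 0, seed = 1L
  ))
}

# Minimal hand-built roi_result for operator-level tests.
toy_roi <- function(mask, C, centers = c(0.1, 0.8)) {
  structure(
    list(mask = mask, boundary = octdme:::mask_boundary(mask), C = C,
         c_mode = "roi_mean", centers = centers),
    class = "roi_result"
  )
}
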