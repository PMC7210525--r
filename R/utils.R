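# Internal validation helpers and raster primitives shared across modules.

stop_octdme <- function(msg, class, call. = sys.call(-1)) {
  cond <- structure(
    class = c(class, "octdme_error", "error", "condition"),
    list(message = msg, call = call.)
  )
  stop(cond)
}

# Numeric image matrix with intensities in [0, 1]; min_dim applies at pipeline
# entry points (file readers, phantoms), low-level operators accept any grid.
check_image <- function(x, arg = "image", min_dim = 1L) {
  if (!is.matrix(x) || !is.numeric(x)) {
    stop_octdme(sprintf("`%s` must be a numeric matrix", arg),
                "octdme_contract_error")
  }
  if (anyNA(x) || !all(is.finite(x))) {
    stop_octdme(sprintf("`%s` contains non-finite values", arg),
                "octdme_contract_error")
  }
  if (min(x) < 0 || max(x) > 1) {
    stop_octdme(sprintf("`%s` intensities must lie in [0, 1]", arg),
                "octdme_contract_error")
  }
  if (nrow(x) < min_dim || ncol(x) < min_dim) {
    stop_octdme(sprintf("`%s` must be at least %dx%d pixels", arg,
                        min_dim, min_dim),
                "octdme_contract_error")
  }
  invisible(x)
}

check_mask <- function(x, arg = "mask") {
  if (!is.matrix(x) || !is.logical(x)) {
    stop_octdme(sprintf("`%s` must be a logical matrix", arg),
                "octdme_contract_error")
  }
  if (anyNA(x)) {
    stop_octdme(sprintf("`%s` contains NA", arg), "octdme_contract_error")
  }
  invisible(x)
}

check_same_shape <- function(a, b, what = "inputs") {
  if (!identical(dim(a), dim(b))) {
    stop_octdme(
      sprintf("%s have mismatched shapes: %dx%d vs %dx%d", what,
              nrow(a), ncol(a), nrow(b), ncol(b)),
      "octdme_contract_error"
    )
  }
  invisible(TRUE)
}

check_scalar <- function(x, arg, lo = -Inf, hi = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lo || x > hi) {
    stop_octdme(sprintf("`%s` must be a finite scalar in [%s, %s]",
                        arg, format(lo), format(hi)),
                "octdme_contract_error")
  }
  invisible(x)
}

# Shift a matrix by (dr, dc); vacated cells take `fill`. result[i, j] is
# m[i - dr, j - dc] where that index exists.
shift_mat <- function(m, dr, dc, fill) {
  nr <- nrow(m)
  nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  r_dst <- max(1L, 1L + dr):min(nr, nr + dr)
  c_dst <- max(1L, 1L + dc):min(nc, nc + dc)
  if (length(r_dst) < 1L || length(c_dst) < 1L) return(out)
  out[r_dst, c_dst] <- m[r_dst - dr, c_dst - dc]
  out
}

# Foreground pixels with at least one FALSE 4-neighbor; off-grid counts as
# background, so the frame border of a full mask is boundary.
mask_boundary <- function(mask) {
  bg <- !mask
  nb_bg <- shift_mat(bg, 1L, 0L, TRUE) | shift_mat(bg, -1L, 0L, TRUE) |
    shift_mat(bg, 0L, 1L, TRUE) | shift_mat(bg, 0L, -1L, TRUE)
  mask & nb_bg
}

# Truncated, normalized 2-D Gaussian convolution with replicated borders.
# The kernel is clipped to fit inside the grid on very small inputs.
gaussian_smooth <- function(x, sigma, radius = ceiling(4 * sigma)) {
  radius <- min(radius, (min(dim(x)) - 1L) %/% 2L)
  if (sigma <= 0 || radius < 1L) return(x)
  kern <- EBImage::makeBrush(2L * radius + 1L, shape = "Gaussian",
                             sigma = sigma)
  y <- EBImage::filter2(x, kern, boundary = "replicate")
  matrix(as.numeric(y), nrow(x), ncol(x))
}

# 8-connected component labeling: EBImage::bwlabel is 4-connected, so labels
# touching diagonally are merged with a union-find pass.
label_components8 <- function(mask) {
  lab <- EBImage::bwlabel(mask * 1)
  lab <- matrix(as.integer(round(lab)), nrow(mask), ncol(mask))
  n <- max(lab)
  if (n <= 1L) return(lab)
  parent <- seq_len(n)
  find_root <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  nr <- nrow(lab)
  nc <- ncol(lab)
  merge_pairs <- function(a, b) {
    keep <- a > 0L & b > 0L & a != b
    if (!any(keep)) return(invisible(NULL))
    pairs <- unique(cbind(a[keep], b[keep]))
    for (k in seq_len(nrow(pairs))) {
      ra <- find_root(pairs[k, 1L])
      rb <- find_root(pairs[k, 2L])
      if (ra != rb) parent[max(ra, rb)] <<- min(ra, rb)
    }
    invisible(NULL)
  }
  merge_pairs(lab[-nr, -nc], lab[-1L, -1L])  # \ diagonal
  merge_pairs(lab[-nr, -1L], lab[-1L, -nc])  # / diagonal
  root <- vapply(seq_len(n), find_root, integer(1L))
  relab <- match(root, sort(unique(root)))
  out <- lab
  out[lab > 0L] <- relab[lab[lab > 0L]]
  out
}

largest_component8 <- function(mask) {
  lab <- label_components8(mask)
  if (max(lab) == 0L) return(mask & FALSE)
  sizes <- tabulate(lab[lab > 0L])
  lab == which.max(sizes)
}

fill_holes <- function(mask) {
  filled <- EBImage::fillHull(mask * 1)
  matrix(as.numeric(filled) > 0.5, nrow(mask), ncol(mask))
}

erode_mask <- function(mask, radius) {
  if (radius < 1L) return(mask)
  kern <- EBImage::makeBrush(2L * radius + 1L, shape = "box")
  out <- EBImage::erode(mask * 1, kern)
  matrix(as.numeric(out) > 0.5, nrow(mask), ncol(mask))
}

# Row-major (row, then column) ordering of TRUE cells, 1-based coordinates.
which_rowmajor <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE]
}
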