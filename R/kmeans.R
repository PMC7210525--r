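# Stage 1: intensity K-means partition of the B-scan into retina and
# background, ROI mask extraction, and the retinal reference intensity C.

#' Deterministic intensity K-means
#'
#' Lloyd iteration on the one-dimensional intensity distribution of the
#' image (value-weighted over the unique intensities, which is equivalent to
#' clustering every pixel but independent of image size). Initialization is
#' deterministic: for `K = 2` the initial centers are the minimum and
#' maximum observed intensity; otherwise evenly spaced quantiles. Iteration
#' stops when the largest center shift is below `tol` or after `max_iter`
#' sweeps. Ties in the nearest-center assignment go to the lower center
#' index.
#'
#' @param image Numeric matrix with intensities in `[0, 1]`.
#' @param K Number of clusters (>= 2).
#' @param max_iter Maximum Lloyd sweeps.
#' @param tol Convergence tolerance on the largest center shift.
#' @return An object of class `cluster_model`: `centers` (ascending),
#'   `labels` (integer matrix, 1-based cluster index per pixel), `K`,
#'   `iterations`, and `sse_trace` (within-cluster sum of squares after each
#'   sweep; non-increasing).
#' @export
kmeans_intensity <- function(image, K = 2L, max_iter = 100L, tol = 1e-8) {
  check_image(image)
  check_scalar(K, "K", lo = 2)
  check_scalar(max_iter, "max_iter", lo = 1)
  check_scalar(tol, "tol", lo = 0)
  K <- as.integer(K)

  v <- as.vector(image)
  uv <- sort(unique(v))
  if (length(uv) < K) {
    stop_octdme(
      sprintf("degenerate clustering: image has %d distinct intensities but K = %d",
              length(uv), K),
      "octdme_degenerate_clustering_error"
    )
  }
  w <- tabulate(match(v, uv), nbins = length(uv))

  centers <- if (K == 2L) {
    c(uv[1L], uv[length(uv)])
  } else {
    unname(stats::quantile(v, probs = seq(0, 1, length.out = K), type = 1))
  }

  sse_trace <- numeric(0)
  assign_lab <- integer(length(uv))
  it <- 0L
  repeat {
    it <- it + 1L
    d <- abs(outer(uv, centers, "-"))
    assign_lab <- max.col(-d, ties.method = "first")
    new_centers <- centers
    for (k in seq_len(K)) {
      sel <- assign_lab == k
      if (any(sel)) {
        new_centers[k] <- sum(w[sel] * uv[sel]) / sum(w[sel])
      }
    }
    sse_trace[it] <- sum(w * (uv - new_centers[assign_lab])^2)
    shift <- max(abs(new_centers - centers))
    centers <- new_centers
    if (shift < tol || it >= max_iter) break
  }

  # Final assignment against the returned centers, sorted ascending.
  ord <- order(centers)
  centers <- centers[ord]
  d <- abs(outer(uv, centers, "-"))
  assign_lab <- max.col(-d, ties.method = "first")
  labels <- matrix(assign_lab[match(v, uv)], nrow(image), ncol(image))

  structure(
    list(centers = centers, labels = labels, K = K, iterations = it,
         sse_trace = sse_trace),
    class = "cluster_model"
  )
}

#' @export
print.cluster_model <- function(x, ...) {
  cat(sprintf("Intensity K-means (K = %d, %d iteration%s)\n", x$K,
              x$iterations, if (x$iterations == 1L) "" else "s"))
  cat("  centers:", format(x$centers, digits = 4), "\n")
  invisible(x)
}

#' Extract the retinal ROI from a 2-cluster model
#'
#' The retina is hyper-reflective relative to the vitreous/background, so the
#' foreground is the brighter of the two clusters. Enclosed background holes
#' (hypo-reflective fluid pockets) are filled, and the largest 8-connected
#' component is kept, yielding a single solid retinal region. The scalar
#' reference intensity `C` consumed by the modified signed pressure force is
#' the mean image intensity over the ROI (mode `"roi_mean"`, the default) or
#' over its complement (mode `"background_mean"`).
#'
#' @param image Numeric matrix in `[0, 1]`.
#' @param model A `cluster_model` with `K = 2` fit on `image`.
#' @param c_mode Which region's mean intensity defines `C`.
#' @return An object of class `roi_result`: `mask` (logical), `boundary`
#'   (logical; mask pixels with a background 4-neighbor), `C`, `c_mode`,
#'   and `centers` (the Stage-1 cluster centers, ascending).
#' @export
extract_roi <- function(image, model, c_mode = c("roi_mean", "background_mean")) {
  check_image(image)
  if (!inherits(model, "cluster_model") || model$K != 2L) {
    stop_octdme("`model` must be a cluster_model with K = 2",
                "octdme_contract_error")
  }
  check_same_shape(image, model$labels, "image and cluster labels")
  c_mode <- match.arg(c_mode)

  fg <- model$labels == which.max(model$centers)
  if (!any(fg)) {
    stop_octdme("empty ROI: no pixel assigned to the brighter cluster",
                "octdme_empty_roi_error")
  }
  mask <- largest_component8(fill_holes(fg))
  C <- if (c_mode == "roi_mean") mean(image[mask]) else mean(image[!mask])

  structure(
    list(mask = mask, boundary = mask_boundary(mask), C = C,
         c_mode = c_mode, centers = model$centers),
    class = "roi_result"
  )
}

#' @export
print.roi_result <- function(x, ...) {
  cat(sprintf("Retinal ROI: %d px (%.1f%% of frame), C = %.4f (%s)\n",
              sum(x$mask), 100 * mean(x$mask), x$C, x$c_mode))
  invisible(x)
}
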