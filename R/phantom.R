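# Seeded synthetic OCT B-scan phantoms: a bright curved retinal band over a
# dark background, optional dark ellipsoidal fluid pockets inside the band,
# multiplicative gamma speckle of mean 1, optional Gaussian blur, and
# ground-truth ROI/DME masks drawn from the pre-noise geometry.

band_row_at <- function(col, width, center_row, curvature) {
  x <- 2 * (col - 1) / width - 1
  center_row + curvature * x^2
}

band_mask_of <- function(height, width, center_row, curvature, thickness) {
  rows <- matrix(seq_len(height), height, width)
  centerline <- matrix(band_row_at(seq_len(width), width, center_row,
                                   curvature),
                       height, width, byrow = TRUE)
  abs(rows - centerline) <= thickness / 2
}

ellipse_mask_of <- function(height, width, pocket) {
  rows <- matrix(seq_len(height), height, width)
  cols <- matrix(seq_len(width), height, width, byrow = TRUE)
  ((rows - pocket[1L]) / pocket[3L])^2 +
    ((cols - pocket[2L]) / pocket[4L])^2 <= 1
}

#' Phantom parameters
#'
#' Geometry and noise settings for one synthetic B-scan. The retinal band is
#' the set of pixels within `band_thickness/2` of the parabola
#' `row(col) = band_center_row + band_curvature * (2*(col-1)/width - 1)^2`
#' (1-based columns); pockets are ellipses
#' `(center_row, center_col, semi_axis_r, semi_axis_c)` that must lie
#' strictly inside the band. Speckle is multiplicative gamma noise with
#' shape `speckle_shape` and mean 1 (`0` disables it); `blur_sigma` is the
#' standard deviation of an optional Gaussian blur.
#'
#' @param height,width Image size in pixels (>= 64).
#' @param band_center_row Band centerline row at the image mid-column.
#' @param band_curvature Parabolic sag (pixels) across the width.
#' @param band_thickness Band thickness in pixels.
#' @param mu_bg,mu_band,mu_fluid Mean intensities in `[0, 1]`; the band must
#'   be brighter than both background and fluid.
#' @param pockets List of length-4 numeric vectors
#'   `(center_row, center_col, semi_axis_r, semi_axis_c)`.
#' @param speckle_shape Gamma shape of the multiplicative speckle (>= 0).
#' @param blur_sigma Gaussian blur standard deviation (>= 0).
#' @param seed Integer seed; identical parameters give bit-identical samples.
#' @return A validated `phantom_params` object.
#' @export
phantom_params <- function(height = 128L, width = 192L,
                           band_center_row = height / 2,
                           band_curvature = 8, band_thickness = 40L,
                           mu_bg = 0.10, mu_band = 0.75, mu_fluid = 0.12,
                           pockets = list(), speckle_shape = 30,
                           blur_sigma = 1, seed = 1L) {
  check_scalar(height, "height", lo = 64)
  check_scalar(width, "width", lo = 64)
  check_scalar(band_center_row, "band_center_row")
  check_scalar(band_curvature, "band_curvature")
  check_scalar(band_thickness, "band_thickness", lo = 1)
  check_scalar(mu_bg, "mu_bg", 0, 1)
  check_scalar(mu_band, "mu_band", 0, 1)
  check_scalar(mu_fluid, "mu_fluid", 0, 1)
  check_scalar(speckle_shape, "speckle_shape", lo = 0)
  check_scalar(blur_sigma, "blur_sigma", lo = 0)
  check_scalar(seed, "seed")
  if (mu_fluid >= mu_band || mu_bg >= mu_band) {
    stop_octdme("the band must be brighter than background and fluid (mu_bg < mu_band, mu_fluid < mu_band)",
                "octdme_contract_error")
  }
  height <- as.integer(height)
  width <- as.integer(width)

  band <- band_mask_of(height, width, band_center_row, band_curvature,
                       band_thickness)
  band_interior <- band & !mask_boundary(band)
  for (i in seq_along(pockets)) {
    p <- pockets[[i]]
    if (!is.numeric(p) || length(p) != 4L || any(!is.finite(p)) ||
        p[3L] <= 0 || p[4L] <= 0) {
      stop_octdme(
        sprintf("pocket %d must be numeric (center_row, center_col, semi_axis_r, semi_axis_c) with positive semi-axes", i),
        "octdme_contract_error"
      )
    }
    ell <- ellipse_mask_of(height, width, p)
    if (!any(ell) || any(ell & !band_interior)) {
      stop_octdme(
        sprintf("pocket %d does not lie strictly inside the retinal band", i),
        "octdme_contract_error"
      )
    }
  }

  structure(
    list(height = height, width = width, band_center_row = band_center_row,
         band_curvature = band_curvature, band_thickness = band_thickness,
         mu_bg = mu_bg, mu_band = mu_band, mu_fluid = mu_fluid,
         pockets = pockets, speckle_shape = speckle_shape,
         blur_sigma = blur_sigma, seed = as.integer(seed)),
    class = "phantom_params"
  )
}

#' Generate one synthetic B-scan
#'
#' Base intensities are `mu_band` on the band, `mu_fluid` inside pockets and
#' `mu_bg` elsewhere; per-pixel multiplicative gamma speckle (mean 1) and
#' Gaussian blur are then applied and the result is clipped to `[0, 1]`.
#' Truth masks come from the pre-noise geometry: `roi_truth` is the band
#' (pockets included), `dme_truth` the pocket union.
#'
#' @param params A [phantom_params()] object.
#' @return A `phantom_sample`: `image`, `roi_truth`, `dme_truth`, `params`.
#' @export
generate_phantom <- function(params) {
  stopifnot(inherits(params, "phantom_params"))
  h <- params$height
  w <- params$width

  band <- band_mask_of(h, w, params$band_center_row, params$band_curvature,
                       params$band_thickness)
  dme <- matrix(FALSE, h, w)
  for (p in params$pockets) dme <- dme | ellipse_mask_of(h, w, p)

  img <- matrix(params$mu_bg, h, w)
  img[band] <- params$mu_band
  img[dme] <- params$mu_fluid

  if (params$speckle_shape > 0) {
    noise <- withr::with_seed(
      params$seed,
      stats::rgamma(h * w, shape = params$speckle_shape,
                    rate = params$speckle_shape)
    )
    img <- img * matrix(noise, h, w)
  }
  if (params$blur_sigma > 0) {
    img <- gaussian_smooth(img, params$blur_sigma)
  }
  img <- pmin(pmax(img, 0), 1)

  structure(
    list(image = img, roi_truth = band, dme_truth = dme, params = params),
    class = "phantom_sample"
  )
}

#' @export
print.phantom_sample <- function(x, ...) {
  cat(sprintf("Phantom B-scan %dx%d: band %d px, %d pocket%s (%d px), speckle shape %g, blur %g\n",
              x$params$height, x$params$width, sum(x$roi_truth),
              length(x$params$pockets),
              if (length(x$params$pockets) == 1L) "" else "s",
              sum(x$dme_truth), x$params$speckle_shape,
              x$params$blur_sigma))
  invisible(x)
}

#' Seeded suite of randomized phantoms
#'
#' Draws `n` phantoms with randomized band geometry and 0-3 pockets each,
#' at the study noise conditions: `speckle_shape = 30`, `blur_sigma = 1`,
#' `mu_bg = 0.10`, `mu_band = 0.75`, `mu_fluid = 0.12`, on a 128x192 grid.
#' Pocket placements are proposed inside the band with a 4-pixel clearance
#' and redrawn (deterministically) up to 20 times; an unplaceable pocket is
#' dropped. Per-sample sub-seeds derive from `seed`, so the suite is fully
#' reproducible element by element.
#'
#' @param n Number of phantoms (>= 1).
#' @param seed Integer master seed.
#' @return List of `phantom_sample` objects.
#' @export
default_suite <- function(n, seed = 0L) {
  check_scalar(n, "n", lo = 1)
  check_scalar(seed, "seed")
  n <- as.integer(n)
  height <- 128L
  width <- 192L

  specs <- withr::with_seed(as.integer(seed), {
    sub_seeds <- sample.int(2147483646L, n)
    lapply(seq_len(n), function(i) {
      center_row <- stats::runif(1, height / 2 - 8, height / 2 + 8)
      curvature <- stats::runif(1, 4, 14)
      thickness <- sample(36:48, 1)
      band <- band_mask_of(height, width, center_row, curvature, thickness)
      clear <- erode_mask(band, 4L)
      pockets <- list()
      for (j in seq_len(sample(0:3, 1))) {
        for (try in 1:20) {
          ar <- sample(4:7, 1)
          ac <- sample(8:14, 1)
          cc <- stats::runif(1, ac + 3, width - ac - 2)
          off_max <- thickness / 2 - ar - 3
          cr <- band_row_at(cc, width, center_row, curvature) +
            stats::runif(1, -max(off_max, 0), max(off_max, 0))
          ell <- ellipse_mask_of(height, width, c(cr, cc, ar, ac))
          if (any(ell) && !any(ell & !clear)) {
            pockets[[length(pockets) + 1L]] <- c(cr, cc, ar, ac)
            break
          }
        }
      }
      list(center_row = center_row, curvature = curvature,
           thickness = thickness, pockets = pockets,
           seed = sub_seeds[i])
    })
  })

  lapply(specs, function(sp) {
    generate_phantom(phantom_params(
      height = height, width = width,
      band_center_row = sp$center_row, band_curvature = sp$curvature,
      band_thickness = sp$thickness, pockets = sp$pockets,
      speckle_shape = 30, blur_sigma = 1, seed = sp$seed
    ))
  })
}
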