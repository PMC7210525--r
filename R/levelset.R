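# Stage 2 core operators: signed pressure force fields, the balloon
# evolution step, and selective binary + Gaussian regularization.
#
# Convention: phi > 0 is the interior of the evolving contour, phi < 0 the
# exterior; the binary Heaviside counts phi = 0 as interior.

#' Level set evolution parameters
#'
#' @param alpha Balloon force (nonzero). Positive values drive the interior
#'   toward regions brighter than the running signed-pressure threshold,
#'   negative values toward darker regions (the DME task targets
#'   hypo-reflective fluid, so [run_sbgfrls_oct()] defaults to `alpha = -20`).
#' @param dt Explicit Euler time step (> 0).
#' @param sigma Standard deviation (pixels) of the Gaussian regularization
#'   kernel, truncated at 4 sigma; `0` disables smoothing.
#' @param max_iter Iteration cap (>= 1).
#' @param conv_tol Relative interior-area change below which an iteration
#'   counts as stationary.
#' @param conv_window Number of consecutive stationary iterations required to
#'   declare convergence.
#' @return An `evolution_params` object (validated list).
#' @export
evolution_params <- function(alpha = 20, dt = 1, sigma = 1,
                             max_iter = 2000L, conv_tol = 1e-3,
                             conv_window = 5L) {
  check_scalar(alpha, "alpha")
  if (alpha == 0) {
    stop_octdme("`alpha` must be nonzero", "octdme_contract_error")
  }
  check_scalar(dt, "dt")
  if (dt <= 0) stop_octdme("`dt` must be positive", "octdme_contract_error")
  check_scalar(sigma, "sigma", lo = 0)
  check_scalar(max_iter, "max_iter", lo = 1)
  check_scalar(conv_tol, "conv_tol", lo = 0)
  check_scalar(conv_window, "conv_window", lo = 1)
  structure(
    list(alpha = alpha, dt = dt, sigma = sigma,
         max_iter = as.integer(max_iter), conv_tol = conv_tol,
         conv_window = as.integer(conv_window)),
    class = "evolution_params"
  )
}

#' Mean intensities inside and outside the contour
#'
#' Binary-Heaviside region means: `c1` is the mean image intensity over
#' `{phi >= 0}`, `c2` over `{phi < 0}`.
#'
#' @param image Numeric matrix in `[0, 1]`.
#' @param phi Level set field of the same shape.
#' @return List with `c1` and `c2`.
#' @export
region_means <- function(image, phi) {
  check_image(image)
  check_same_shape(image, phi, "image and phi")
  inside <- phi >= 0
  n1 <- sum(inside)
  n2 <- length(phi) - n1
  if (n1 == 0L || n2 == 0L) {
    stop_octdme(
      sprintf("empty %s region: the contour has %s",
              if (n1 == 0L) "interior" else "exterior",
              if (n1 == 0L) "vanished" else "flooded the frame"),
      "octdme_empty_region_error"
    )
  }
  list(c1 = mean(image[inside]), c2 = mean(image[!inside]))
}

spf_normalize <- function(num) {
  m <- max(abs(num))
  if (m == 0) num else num / m
}

#' Conventional signed pressure force
#'
#' `spf = (I - (c1 + c2)/2) / max|I - (c1 + c2)/2|`: positive where the image
#' is brighter than the midpoint of the two region means, negative where
#' darker, normalized so the maximum absolute value is exactly 1 (an
#' identically-zero numerator returns the zero field).
#'
#' @param image Numeric matrix in `[0, 1]`.
#' @param c1,c2 Region mean intensities in `[0, 1]`.
#' @return Numeric matrix in `[-1, 1]`.
#' @export
spf_conventional <- function(image, c1, c2) {
  check_image(image)
  check_scalar(c1, "c1", 0, 1)
  check_scalar(c2, "c2", 0, 1)
  spf_normalize(image - (c1 + c2) / 2)
}

#' Modified signed pressure force with a fixed retinal reference
#'
#' Identical to [spf_conventional()] with the evolving exterior mean replaced
#' by the fixed Stage-1 retinal reference intensity `C`, so only the interior
#' mean `c1` is re-estimated during evolution.
#'
#' @param image Numeric matrix in `[0, 1]`.
#' @param c1 Interior mean intensity in `[0, 1]`.
#' @param C Stage-1 reference intensity in `[0, 1]` (see [extract_roi()]).
#' @return Numeric matrix in `[-1, 1]`.
#' @export
spf_modified <- function(image, c1, C) {
  check_image(image)
  check_scalar(c1, "c1", 0, 1)
  check_scalar(C, "C", 0, 1)
  spf_normalize(image - (c1 + C) / 2)
}

#' Gradient magnitude of a level set field
#'
#' Central differences in the interior, one-sided differences at the borders;
#' pointwise Euclidean norm of the two partials.
#'
#' @param phi Numeric matrix, at least 3x3.
#' @return Numeric matrix of the same shape, nonnegative.
#' @export
gradient_magnitude <- function(phi) {
  if (!is.matrix(phi) || nrow(phi) < 3L || ncol(phi) < 3L) {
    stop_octdme("`phi` must be a matrix of at least 3x3",
                "octdme_contract_error")
  }
  nr <- nrow(phi)
  nc <- ncol(phi)
  dr <- matrix(0, nr, nc)
  dr[2:(nr - 1L), ] <- (phi[3:nr, ] - phi[1:(nr - 2L), ]) / 2
  dr[1L, ] <- phi[2L, ] - phi[1L, ]
  dr[nr, ] <- phi[nr, ] - phi[nr - 1L, ]
  dc <- matrix(0, nr, nc)
  dc[, 2:(nc - 1L)] <- (phi[, 3:nc] - phi[, 1:(nc - 2L)]) / 2
  dc[, 1L] <- phi[, 2L] - phi[, 1L]
  dc[, nc] <- phi[, nc] - phi[, nc - 1L]
  sqrt(dr^2 + dc^2)
}

#' One explicit Euler balloon step
#'
#' `phi' = phi + dt * alpha * spf * |grad phi|` pointwise.
#'
#' @param phi Level set field.
#' @param spf Signed pressure force field of the same shape.
#' @param params An [evolution_params()] object.
#' @return Updated field.
#' @export
evolve_step <- function(phi, spf, params) {
  stopifnot(inherits(params, "evolution_params"))
  check_same_shape(phi, spf, "phi and spf")
  out <- phi + params$dt * params$alpha * spf * gradient_magnitude(phi)
  if (!all(is.finite(out))) {
    stop_octdme(
      sprintf("non-finite values after evolution step; dt * alpha = %g is likely too large",
              params$dt * params$alpha),
      "octdme_numeric_blowup_error"
    )
  }
  out
}

#' Selective binary + Gaussian regularization
#'
#' Replaces classical re-initialization: `phi` is mapped to its sign
#' (`+1` where `phi > 0`, `-1` elsewhere) and then convolved with a
#' truncated, normalized 2-D Gaussian. With `sigma = 0` the result is the
#' pure sign map.
#'
#' @param phi Level set field.
#' @param sigma Gaussian standard deviation in pixels (>= 0).
#' @param radius Kernel truncation radius in pixels; defaults to 4 sigma.
#' @return Field with values in `[-1, 1]`.
#' @export
regularize <- function(phi, sigma, radius = ceiling(4 * sigma)) {
  check_scalar(sigma, "sigma", lo = 0)
  s <- matrix(-1, nrow(phi), ncol(phi))
  s[phi > 0] <- 1
  out <- gaussian_smooth(s, sigma, radius)
  # FFT round-off can overshoot the sign-map range by machine epsilon
  pmin(pmax(out, -1), 1)
}
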