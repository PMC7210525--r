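# Stage 2 engines: the conventional SBGFRLS convergence loop and the
# OCT-adapted variant confined to the Stage-1 retinal region.
#
# Each iteration evaluates the force on the current field, takes one balloon
# step, records the interior area of the evolved field, and then applies the
# selective binary + Gaussian regularization that seeds the next iteration.
# The reported mask and area trace come from the evolved (force-balanced)
# field: the smoothing step can transiently clip single high-curvature
# boundary pixels that the very next force step restores, and sampling after
# the force step makes the converged mask coincide with the signed-pressure
# threshold set.

new_segmentation_result <- function(mask, iterations, converged, area_trace,
                                    c1 = NA_real_, c2 = NA_real_,
                                    note = NULL) {
  structure(
    list(mask = mask, iterations = iterations, converged = converged,
         area_trace = area_trace, c1 = c1, c2 = c2, note = note),
    class = "segmentation_result"
  )
}

#' @export
print.segmentation_result <- function(x, ...) {
  cat(sprintf("Level set segmentation: %d px interior, %d iteration%s, %s\n",
              sum(x$mask), x$iterations,
              if (x$iterations == 1L) "" else "s",
              if (x$converged) "converged" else "stopped at max_iter"))
  if (!is.null(x$note)) cat("  note:", x$note, "\n")
  invisible(x)
}

#' Initialize the DME level set inside the retina
#'
#' Seeds the contour on the hypo-reflective candidate pixels of the ROI:
#' `phi = +1` where the ROI intensity falls below `(c_dark + C)/2`, the
#' midpoint between the darker Stage-1 cluster center and the retinal
#' reference intensity, and `-1` elsewhere. If no ROI pixel qualifies (a
#' fluid-free retina), the single darkest ROI pixel (first in row-major
#' order on ties) is seeded so the interior mean is defined.
#'
#' @param image Numeric matrix in `[0, 1]`.
#' @param roi An [extract_roi()] result.
#' @return Level set field of `+1`/`-1` values.
#' @export
initialize_dme_phi <- function(image, roi) {
  check_image(image)
  if (!inherits(roi, "roi_result")) {
    stop_octdme("`roi` must be an roi_result", "octdme_contract_error")
  }
  check_same_shape(image, roi$mask, "image and roi mask")
  if (!any(roi$mask)) {
    stop_octdme("empty ROI: cannot initialize the DME contour",
                "octdme_empty_roi_error")
  }
  thr <- (min(roi$centers) + roi$C) / 2
  sel <- roi$mask & (image < thr)
  if (!any(sel)) {
    roi_px <- which_rowmajor(roi$mask)
    vals <- image[roi_px]
    seed <- roi_px[which.min(vals), , drop = FALSE]
    sel[seed] <- TRUE
  }
  phi <- matrix(-1, nrow(image), ncol(image))
  phi[sel] <- 1
  phi
}

converged_update <- function(area, area_prev, streak, conv_tol) {
  rel <- abs(area - area_prev) / max(area_prev, 1)
  if (rel <= conv_tol) streak + 1L else 0L
}

#' Conventional SBGFRLS segmentation
#'
#' Runs the balloon evolution with the conventional signed pressure force:
#' both region means are re-estimated from the current contour at every
#' iteration. Convergence is declared when the relative interior-area change
#' stays within `conv_tol` for `conv_window` consecutive iterations.
#'
#' @param image Numeric matrix in `[0, 1]`.
#' @param init Initial level set field (nonempty interior and exterior).
#' @param params An [evolution_params()] object.
#' @return A `segmentation_result`: `mask` (`phi > 0` at termination),
#'   `iterations`, `converged`, `area_trace` (interior pixel count per
#'   iteration), and the final `c1`, `c2`.
#' @export
run_sbgfrls <- function(image, init, params = evolution_params()) {
  check_image(image)
  check_same_shape(image, init, "image and init")
  stopifnot(inherits(params, "evolution_params"))
  if (sum(init >= 0) == 0L || sum(init < 0) == 0L) {
    stop_octdme("init must have a nonempty interior and exterior",
                "octdme_empty_region_error")
  }

  phi <- init
  area_prev <- sum(phi > 0)
  streak <- 0L
  trace <- integer(params$max_iter)
  for (it in seq_len(params$max_iter)) {
    rm <- tryCatch(
      region_means(image, phi),
      octdme_empty_region_error = function(e) {
        stop_octdme(sprintf("iteration %d: %s", it, conditionMessage(e)),
                    "octdme_empty_region_error")
      }
    )
    s <- spf_conventional(image, rm$c1, rm$c2)
    phi_e <- evolve_step(phi, s, params)
    area <- sum(phi_e > 0)
    trace[it] <- area
    streak <- converged_update(area, area_prev, streak, params$conv_tol)
    area_prev <- area
    if (streak >= params$conv_window || it == params$max_iter) {
      return(new_segmentation_result(
        mask = phi_e > 0, iterations = it,
        converged = streak >= params$conv_window,
        area_trace = trace[seq_len(it)], c1 = rm$c1, c2 = rm$c2
      ))
    }
    phi <- regularize(phi_e, params$sigma)
  }
}

#' OCT-adapted SBGFRLS segmentation of DME fluid
#'
#' The retina-confined variant: the exterior reference is frozen at the
#' Stage-1 retinal intensity `roi$C`, only the interior mean `c1` is
#' re-estimated (over `{phi >= 0}`), and outside the retina (the ROI eroded
#' by `confine_margin` pixels, so the blur-contaminated rim just inside the
#' retinal border is excluded too) the force is clamped to the contractive
#' sign so the contour cannot leak into the background, which shares the
#' fluid's intensity. The final mask is intersected with the full ROI.
#'
#' A vanished contour is not an error here: a retina without fluid is a
#' valid outcome and yields an all-`FALSE` mask with `converged = TRUE` and
#' an explanatory `note`.
#'
#' @param image Numeric matrix in `[0, 1]`.
#' @param roi An [extract_roi()] result.
#' @param params An [evolution_params()] object; the default uses
#'   `alpha = -20` because the fluid target is darker than the signed
#'   pressure threshold (see [evolution_params()]).
#' @param confine_margin Erosion radius (pixels) applied to the ROI before
#'   clamping the force outside it.
#' @return A `segmentation_result` (the `c2` slot holds the fixed `roi$C`).
#' @export
run_sbgfrls_oct <- function(image, roi, params = evolution_params(alpha = -20),
                            confine_margin = 3L) {
  check_image(image)
  if (!inherits(roi, "roi_result")) {
    stop_octdme("`roi` must be an roi_result", "octdme_contract_error")
  }
  check_same_shape(image, roi$mask, "image and roi mask")
  stopifnot(inherits(params, "evolution_params"))
  check_scalar(confine_margin, "confine_margin", lo = 0)
  if (!any(roi$mask)) {
    stop_octdme("empty ROI: nothing to segment", "octdme_empty_roi_error")
  }

  phi <- initialize_dme_phi(image, roi)
  allowed <- erode_mask(roi$mask, as.integer(confine_margin))
  contractive <- -sign(params$alpha)

  area_prev <- sum(phi > 0)
  streak <- 0L
  trace <- integer(params$max_iter)
  c1 <- NA_real_
  for (it in seq_len(params$max_iter)) {
    if (sum(phi >= 0) == 0L) {
      return(new_segmentation_result(
        mask = matrix(FALSE, nrow(image), ncol(image)),
        iterations = it - 1L, converged = TRUE,
        area_trace = trace[seq_len(it - 1L)], c1 = c1, c2 = roi$C,
        note = sprintf("contour vanished at iteration %d: retina segmented as fluid-free", it - 1L)
      ))
    }
    c1 <- mean(image[phi >= 0])
    s <- spf_modified(image, c1, roi$C)
    s[!allowed] <- contractive
    phi_e <- evolve_step(phi, s, params)
    area <- sum(phi_e > 0)
    trace[it] <- area
    streak <- converged_update(area, area_prev, streak, params$conv_tol)
    area_prev <- area
    if (streak >= params$conv_window || it == params$max_iter) {
      return(new_segmentation_result(
        mask = (phi_e > 0) & roi$mask, iterations = it,
        converged = streak >= params$conv_window,
        area_trace = trace[seq_len(it)], c1 = c1, c2 = roi$C
      ))
    }
    phi <- regularize(phi_e, params$sigma)
  }
}
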