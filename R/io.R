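# Raster input/output: grayscale B-scans, binary masks, contour overlays.
#
# png::readPNG and tiff::readTIFF both return intensities already divided by
# the container type maximum (255 or 65535), which is exactly the
# normalization rule used throughout: raw pixel order is preserved and a
# full-scale pixel maps to 1.0.

#' Read a grayscale OCT B-scan
#'
#' Reads an 8- or 16-bit PNG or TIFF image and returns a numeric matrix of
#' intensities in `[0, 1]` (row, column indexed, origin top-left).
#' Multi-channel images are accepted only when their color channels are
#' identical (gray stored as RGB); an alpha channel is ignored.
#'
#' @param path Path to a `.png`, `.tif` or `.tiff` file.
#' @return Numeric matrix with values in `[0, 1]`, at least 8x8 pixels.
#' @export
read_oct_image <- function(path) {
  raw <- read_raster(path)
  img <- collapse_gray(raw, path)
  if (nrow(img) < 8L || ncol(img) < 8L) {
    stop_octdme(
      sprintf("image '%s' is %dx%d; at least 8x8 pixels are required",
              path, nrow(img), ncol(img)),
      "octdme_contract_error"
    )
  }
  check_image(img, "image")
  img
}

read_raster <- function(path) {
  if (!file.exists(path)) {
    stop_octdme(sprintf("cannot read image: file '%s' does not exist", path),
                "octdme_io_error")
  }
  ext <- tolower(tools::file_ext(path))
  out <- tryCatch(
    switch(ext,
      png = png::readPNG(path),
      tif = ,
      tiff = tiff::readTIFF(path),
      stop_octdme(
        sprintf("unsupported image format '.%s' for '%s' (use PNG or TIFF)",
                ext, path),
        "octdme_format_error"
      )
    ),
    error = function(e) {
      if (inherits(e, "octdme_error")) stop(e)
      stop_octdme(sprintf("failed to decode '%s': %s", path,
                          conditionMessage(e)),
                  "octdme_io_error")
    }
  )
  out
}

collapse_gray <- function(raw, path) {
  if (is.matrix(raw)) return(raw)
  if (length(dim(raw)) != 3L) {
    stop_octdme(sprintf("'%s' has unsupported dimensions", path),
                "octdme_format_error")
  }
  nch <- dim(raw)[3L]
  if (nch == 2L) return(raw[, , 1L])       # gray + alpha
  if (nch %in% c(3L, 4L)) {
    for (ch in 2L:3L) {
      if (!isTRUE(all.equal(raw[, , 1L], raw[, , ch], tolerance = 0))) {
        stop_octdme(
          sprintf("'%s' is multi-channel with unequal channels (channel %d differs from channel 1); not a grayscale image",
                  path, ch),
          "octdme_format_error"
        )
      }
    }
    return(raw[, , 1L])
  }
  stop_octdme(sprintf("'%s' has %d channels; expected grayscale", path, nch),
              "octdme_format_error")
}

#' Write a binary mask as an 8-bit PNG
#'
#' Foreground pixels are written as 255, background as 0, so the file
#' round-trips bit-exactly through [read_mask()].
#'
#' @param mask Logical matrix.
#' @param path Output path; the parent directory must exist.
#' @return The path, invisibly.
#' @export
write_mask <- function(mask, path) {
  check_mask(mask)
  if (!dir.exists(dirname(path))) {
    stop_octdme(sprintf("cannot write mask: directory '%s' does not exist",
                        dirname(path)),
                "octdme_io_error")
  }
  tryCatch(png::writePNG(mask * 1, path),
           error = function(e) {
             stop_octdme(sprintf("failed to write '%s': %s", path,
                                 conditionMessage(e)),
                         "octdme_io_error")
           })
  invisible(path)
}

#' Read a binary mask from a 0/255 PNG
#'
#' @param path Path to a mask written by [write_mask()] (or any image whose
#'   pixels are pure black/white).
#' @return Logical matrix; pixels above half intensity are `TRUE`.
#' @export
read_mask <- function(path) {
  raw <- read_raster(path)
  img <- collapse_gray(raw, path)
  img > 0.5
}

#' Render a contour overlay for visual inspection
#'
#' Writes an RGB PNG showing the input image in grayscale with the 1-pixel
#' boundary of the retinal ROI in pure red and the boundary of the DME mask
#' in pure green (boundary = foreground pixels with at least one background
#' 4-neighbor; off-grid counts as background).
#'
#' @param image Numeric matrix in `[0, 1]`.
#' @param roi,dme Logical matrices of the same shape as `image`.
#' @param path Output PNG path.
#' @return The path, invisibly.
#' @export
render_overlay <- function(image, roi, dme, path) {
  check_image(image)
  check_mask(roi, "roi")
  check_mask(dme, "dme")
  check_same_shape(image, roi, "image and roi")
  check_same_shape(image, dme, "image and dme")
  rb <- mask_boundary(roi)
  gb <- mask_boundary(dme)
  r <- g <- b <- image
  r[rb] <- 1; g[rb] <- 0; b[rb] <- 0
  r[gb] <- 0; g[gb] <- 1; b[gb] <- 0
  arr <- array(c(r, g, b), dim = c(nrow(image), ncol(image), 3L))
  tryCatch(png::writePNG(arr, path),
           error = function(e) {
             stop_octdme(sprintf("failed to write '%s': %s", path,
                                 conditionMessage(e)),
                         "octdme_io_error")
           })
  invisible(path)
}
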