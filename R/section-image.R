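#' Section image container
#'
#' A single-channel integer-valued pixel grid with its physical pixel size and
#' an append-only provenance trail of the operations applied to it. Pixel
#' values live in the 16-bit range \code{[0, 65535]}; after inversion, darker
#' (more strongly stained) raw pixels carry larger values.
#'
#' @param pixels numeric matrix of non-negative integers (rows = y, top-left
#'   origin, consistent with image rasters).
#' @param pixel_size physical size of one pixel in micrometers (> 0).
#' @param provenance list of operation records; extended by each processing
#'   step.
#' @return An object of class \code{section_image}.
#' @export
section_image <- function(pixels, pixel_size = 1, provenance = list()) {
  stopifnot(is.matrix(pixels), pixel_size > 0)
  if (any(pixels < 0 | pixels > 65535, na.rm = TRUE))
    stop("pixel values must lie in [0, 65535]")
  structure(
    list(pixels = pixels, pixel_size = as.numeric(pixel_size),
         provenance = provenance),
    class = "section_image"
  )
}

#' @export
print.section_image <- function(x, ...) {
  cat(sprintf("<section_image> %d x %d px, %.3g um/px, range [%d, %d]\n",
              nrow(x$pixels), ncol(x$pixels), x$pixel_size,
              as.integer(min(x$pixels)), as.integer(max(x$pixels))))
  if (length(x$provenance))
    cat("  provenance:", paste(vapply(x$provenance, `[[`, "", "op"),
                               collapse = " -> "), "\n")
  invisible(x)
}

#' @export
dim.section_image <- function(x) dim(x$pixels)

add_provenance <- function(img, op, params = list()) {
  img$provenance <- c(img$provenance, list(c(list(op = op), params)))
  img
}

as_pixels <- function(image) {
  if (inherits(image, "section_image")) image$pixels else image
}

#' Convert to inverted 16-bit grayscale
#'
#' Reduces 1- or 3-channel input to grayscale, rescales it to the 16-bit
#' range, and inverts it so that stronger DAB staining (darker raw pixels)
#' maps to larger values: \code{out = 65535 - gray}. RGB input is reduced by
#' ITU-R 601 luminance weights (0.299, 0.587, 0.114). Applying the function
#' twice to an already 16-bit single-channel image returns the original.
#'
#' @param image 2-D matrix (grayscale) or 3-D array with 3 channels (RGB),
#'   integer-valued.
#' @param bits bit depth of the input values: \code{"auto"} (8-bit when the
#'   maximum is <= 255, 16-bit otherwise), \code{8} or \code{16}.
#' @param pixel_size micrometers per pixel for the returned
#'   \code{\link{section_image}}.
#' @return A \code{section_image} with inverted 16-bit values.
#' @export
to_inverted_gray <- function(image, bits = "auto", pixel_size = 1) {
  if (inherits(image, "section_image")) {
    pixel_size <- image$pixel_size
    prov <- image$provenance
    image <- image$pixels
  } else prov <- list()
  d <- dim(image)
  if (length(d) == 3) {
    if (d[3] != 3) stop("unsupported channel count: ", d[3])
    gray <- 0.299 * image[, , 1] + 0.587 * image[, , 2] + 0.114 * image[, , 3]
  } else if (length(d) == 2) {
    gray <- image
  } else stop("unsupported image shape")
  if (identical(bits, "auto")) bits <- if (max(gray) <= 255) 8 else 16
  if (bits == 8) gray <- gray * (65535 / 255)
  inv <- 65535 - round(gray)
  out <- section_image(clamp(inv, 0, 65535), pixel_size, prov)
  add_provenance(out, "to_inverted_gray", list(bits = bits))
}
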