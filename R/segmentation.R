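# Striosome/matrix segmentation by minimum cross-entropy (Li) thresholding,
# and exclusion of non-neuronal fiber via control-square thresholding.

#' Minimum cross-entropy (Li) threshold
#'
#' Returns the gray level that minimizes the Li & Tam minimum cross-entropy
#' criterion between the image and its two-level approximation,
#' \deqn{\eta(t) = -A_1(t)\log\mu_1(t) - A_2(t)\log\mu_2(t),}
#' where \eqn{A_i} is the summed gray mass and \eqn{\mu_i} the mean of the
#' pixels on either side of the candidate \eqn{t}. Values are binned to
#' \code{n_bins} levels over their observed range and the criterion is
#' minimized globally over all candidate splits; when several splits attain
#' the minimum (e.g. any split between the two modes of a two-level
#' histogram), the median candidate is taken, so the returned threshold sits
#' midway between the modes. The result is mapped back to the original gray
#' scale and rounded to an integer.
#'
#' Segmentation rule downstream: pixels strictly above the threshold are
#' striosome, pixels at or below it are matrix.
#'
#' @param values numeric vector of pixel gray values (>= 2 distinct values).
#' @param n_bins number of histogram bins for the search (default 256).
#' @return integer threshold on the scale of \code{values}.
#' @export
li_threshold <- function(values, n_bins = 256) {
  values <- values[is.finite(values)]
  rng <- range(values)
  if (length(values) < 2 || rng[1] == rng[2])
    stop("degenerate input: fewer than 2 distinct gray values", call. = FALSE)
  width <- (rng[2] - rng[1]) / n_bins
  bin <- pmin(floor((values - rng[1]) / width) + 1L, n_bins)
  h <- tabulate(bin, nbins = n_bins)
  mids <- rng[1] + (seq_len(n_bins) - 0.5) * width
  n1 <- cumsum(h)                 # counts at or below split k (bins 1..k)
  a1 <- cumsum(h * mids)          # gray mass below
  ntot <- n1[n_bins]; atot <- a1[n_bins]
  k <- seq_len(n_bins - 1)
  valid <- n1[k] > 0 & (ntot - n1[k]) > 0
  mu1 <- a1[k] / n1[k]
  mu2 <- (atot - a1[k]) / (ntot - n1[k])
  term <- function(a, mu) ifelse(a > 0, -a * log(mu), 0)
  eta <- term(a1[k], mu1) + term(atot - a1[k], mu2)
  eta[!valid] <- Inf
  if (!any(is.finite(eta)))
    stop("degenerate input: no valid threshold candidate", call. = FALSE)
  winners <- which(eta == min(eta))
  kstar <- winners[ceiling(length(winners) / 2)]  # median of tied splits
  as.integer(round(rng[1] + kstar * width))
}

#' Segment a sector into striosome and matrix
#'
#' Computes the Li threshold on the pixel values of the sector (each region is
#' thresholded independently; a whole-caudoputamen threshold is never reused
#' for its sectors) and splits the sector: pixels above the threshold form the
#' striosome mask, pixels at or below it the matrix mask.
#'
#' @param image \code{\link{section_image}} or numeric matrix (processed
#'   pixel values).
#' @param sector_mask logical matrix, nonempty.
#' @param region_id identifier recorded in the result.
#' @return object of class \code{compartment_result} with fields
#'   \code{li_threshold}, \code{striosome_mask}, \code{matrix_mask},
#'   \code{excluded_mask} (empty until fiber exclusion), \code{fiber_threshold}
#'   (NA until exclusion) and \code{region_id}.
#' @export
segment_sector <- function(image, sector_mask, region_id = "") {
  x <- as_pixels(image)
  stopifnot(identical(dim(x), dim(sector_mask)))
  if (!any(sector_mask)) stop("sector mask is empty", call. = FALSE)
  thr <- li_threshold(x[sector_mask])
  strio <- sector_mask & (x > thr)
  mat <- sector_mask & (x <= thr)
  structure(list(
    region_id = region_id,
    li_threshold = thr,
    striosome_mask = strio,
    matrix_mask = mat,
    excluded_mask = sector_mask & FALSE,
    fiber_threshold = NA_integer_
  ), class = "compartment_result")
}

#' @export
print.compartment_result <- function(x, ...) {
  cat(sprintf(
    "<compartment_result> %s: Li threshold %d; strio %d px, matrix %d px, excluded %d px\n",
    x$region_id, x$li_threshold, sum(x$striosome_mask), sum(x$matrix_mask),
    sum(x$excluded_mask)))
  invisible(x)
}

square_indices <- function(center, side_um, pixel_size, dims) {
  side_px <- max(1L, as.integer(round(side_um / pixel_size)))
  half_lo <- floor((side_px - 1) / 2)
  x0 <- round(center[1]) - half_lo
  y0 <- round(center[2]) - half_lo
  xs <- x0:(x0 + side_px - 1L)
  ys <- y0:(y0 + side_px - 1L)
  if (min(xs) < 1 || min(ys) < 1 || max(xs) > dims[2] || max(ys) > dims[1])
    stop("control square outside image bounds", call. = FALSE)
  list(rows = ys, cols = xs)
}

#' Fiber-exclusion threshold from control squares
#'
#' Averages the mean intensity of the control squares (50 um side by default,
#' placed on the corpus callosum and anterior commissure) and truncates the
#' result after the decimal point; the integral value is the threshold for
#' excluding non-neuronal fiber.
#'
#' @param image \code{\link{section_image}} or numeric matrix (the same
#'   processed image used for densitometry).
#' @param control_squares list of \code{list(center = c(x, y), side_um)}.
#' @param pixel_size micrometers per pixel; taken from \code{image} when it is
#'   a \code{section_image}.
#' @return integer threshold.
#' @export
fiber_threshold <- function(image, control_squares, pixel_size = NULL) {
  x <- as_pixels(image)
  if (is.null(pixel_size))
    pixel_size <- if (inherits(image, "section_image")) image$pixel_size else 1
  if (!length(control_squares)) stop("at least one control square required")
  means <- vapply(control_squares, function(sq) {
    ij <- square_indices(sq$center, sq$side_um %||% 50, pixel_size, dim(x))
    mean(x[ij$rows, ij$cols])
  }, numeric(1))
  as.integer(floor(mean(means)))
}

#' Apply fiber exclusion to a segmented sector
#'
#' Moves pixels whose value is at or below the fiber threshold from the
#' striosome/matrix masks into the excluded mask. The three masks always
#' partition the sector. Exclusion is applied after compartment segmentation,
#' so Li thresholds are computed on the unexcluded sector.
#'
#' @param result a \code{compartment_result} from \code{\link{segment_sector}}.
#' @param image the image the result was computed from.
#' @param threshold integer fiber threshold (>= 0), e.g. from
#'   \code{\link{fiber_threshold}}.
#' @return the updated \code{compartment_result}.
#' @export
apply_fiber_exclusion <- function(result, image, threshold) {
  stopifnot(threshold >= 0)
  x <- as_pixels(image)
  low <- x <= threshold
  result$excluded_mask <- result$excluded_mask |
    (low & (result$striosome_mask | result$matrix_mask))
  result$striosome_mask <- result$striosome_mask & !low
  result$matrix_mask <- result$matrix_mask & !low
  result$fiber_threshold <- as.integer(threshold)
  result
}
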