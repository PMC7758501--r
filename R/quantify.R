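# Per-region compartment metrics: striosome %area, compartment mean
# intensities, ISMP, and total (intensity x %area) striosome signal.

#' Striosome area fraction
#'
#' \code{|striosome| / (|sector| - |excluded|)}: striosome pixels over the
#' analyzable (fiber-excluded) sector area, as a fraction in [0, 1].
#'
#' @param striosome_mask,sector_mask,excluded_mask logical matrices.
#' @return fraction, or \code{NA} when the denominator is empty.
#' @export
percent_area <- function(striosome_mask, sector_mask, excluded_mask = NULL) {
  denom <- sum(sector_mask) - if (is.null(excluded_mask)) 0 else sum(excluded_mask)
  if (denom <= 0) return(NA_real_)
  sum(striosome_mask) / denom
}

#' Mean intensity under a mask
#'
#' @param image \code{\link{section_image}} or numeric matrix.
#' @param mask logical matrix.
#' @return arithmetic mean of the pixel values under the mask, \code{NA} when
#'   the mask is empty.
#' @export
mean_intensity <- function(image, mask) {
  x <- as_pixels(image)
  if (!any(mask)) return(NA_real_)
  mean(x[mask])
}

#' Index of striosome-to-matrix predominance (ISMP)
#'
#' Ratio of the striosome mean intensity to the matrix mean intensity;
#' values above 1 indicate striosome predominance.
#'
#' @param strio_intensity,matrix_intensity mean compartment intensities.
#' @return dimensionless ratio, \code{NA} when the matrix intensity is not
#'   positive (never infinity).
#' @export
ismp <- function(strio_intensity, matrix_intensity) {
  ifelse(is.na(matrix_intensity) | matrix_intensity <= 0,
         NA_real_, strio_intensity / matrix_intensity)
}

#' Total striosome signal
#'
#' Product of the striosome mean intensity and the striosome area fraction
#' ("intensity x %area").
#'
#' @param strio_intensity mean striosome intensity.
#' @param percent_area striosome area fraction (0..1).
#' @return product, on the intensity scale.
#' @export
total_intensity <- function(strio_intensity, percent_area) {
  strio_intensity * percent_area
}

#' Metrics for one segmented region
#'
#' Computes all per-region metrics from a \code{compartment_result}. The
#' record is marked invalid when either compartment mask is empty or the
#' analyzable area vanishes.
#'
#' @param image the processed image the segmentation was computed from.
#' @param result a \code{compartment_result}.
#' @return one-row \code{data.frame} with columns \code{region_id},
#'   \code{percent_area}, \code{strio_intensity}, \code{matrix_intensity},
#'   \code{ismp}, \code{total_intensity}, \code{li_threshold},
#'   \code{fiber_threshold}, \code{valid}.
#' @export
region_metrics <- function(image, result) {
  pa <- percent_area(result$striosome_mask,
                     result$striosome_mask | result$matrix_mask | result$excluded_mask,
                     result$excluded_mask)
  si <- mean_intensity(image, result$striosome_mask)
  mi <- mean_intensity(image, result$matrix_mask)
  r <- ismp(si, mi)
  ti <- total_intensity(si, pa)
  valid <- !is.na(pa) && !is.na(si) && !is.na(mi) && !is.na(r)
  data.frame(region_id = result$region_id,
             percent_area = pa, strio_intensity = si, matrix_intensity = mi,
             ismp = r, total_intensity = ti,
             li_threshold = result$li_threshold,
             fiber_threshold = result$fiber_threshold,
             valid = valid, stringsAsFactors = FALSE)
}

#' Group means and SEMs of a metrics table
#'
#' Summary in the reporting convention of the field (means +/- SEM) for each
#' metric by genotype within sector/age/level.
#'
#' @param metrics long-format metrics table (one row per section x sector).
#' @param metric_cols which metric columns to summarize.
#' @param by grouping columns.
#' @return data.frame of group means and SEMs.
#' @export
summarize_metrics <- function(metrics,
                              metric_cols = c("percent_area", "strio_intensity",
                                              "matrix_intensity", "ismp",
                                              "total_intensity"),
                              by = c("genotype", "age_months", "level", "sector")) {
  metrics <- metrics[metrics$valid, , drop = FALSE]
  by <- intersect(by, names(metrics))
  key <- interaction(metrics[by], drop = TRUE)
  out <- do.call(rbind, lapply(split(metrics, key), function(g) {
    row <- g[1, by, drop = FALSE]
    for (m in metric_cols) {
      v <- g[[m]]
      row[[paste0(m, "_mean")]] <- mean(v)
      row[[paste0(m, "_sem")]] <- stats::sd(v) / sqrt(length(v))
      row[[paste0(m, "_n")]] <- length(v)
    }
    row
  }))
  rownames(out) <- NULL
  out
}
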