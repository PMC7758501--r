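# End-to-end orchestration: simulate/read -> preprocess -> geometry ->
# segmentation -> quantification -> statistics, with per-section fault
# isolation and an audit trail. Genotype labels are never passed to the
# geometry or segmentation stages (analysis is blinded); they are joined to
# the metrics table afterwards.

#' Pipeline run configuration
#'
#' Defaults match the reference acquisition settings: rolling-ball radius 500
#' px, median radius 5 px, 256-bin Li histograms, 50 um control squares,
#' family-wise alpha 0.05 with Bonferroni family size 10. For small synthetic
#' images the rolling-ball radius must be reduced below the image size.
#'
#' @param rolling_ball_radius background-subtraction ball radius in pixels,
#'   or NULL to skip the stage.
#' @param median_radius median-filter disk radius in pixels, or NULL to skip.
#' @param li_bins histogram bins for Li thresholding.
#' @param control_square_um control-square side in micrometers.
#' @param alpha,family_m stats-plan parameters (see
#'   \code{\link{comparison_plan}}).
#' @param max_failure_fraction the run fails when more than this fraction of
#'   sections errors out.
#' @param write_masks write color-coded compartment masks as PNG when an
#'   output directory is given.
#' @return list of class \code{run_config}.
#' @export
run_config <- function(rolling_ball_radius = 500, median_radius = 5,
                       li_bins = 256, control_square_um = 50,
                       alpha = 0.05, family_m = 10,
                       max_failure_fraction = 0.2, write_masks = FALSE) {
  structure(list(rolling_ball_radius = rolling_ball_radius,
                 median_radius = median_radius, li_bins = li_bins,
                 control_square_um = control_square_um, alpha = alpha,
                 family_m = family_m,
                 max_failure_fraction = max_failure_fraction,
                 write_masks = write_masks),
            class = "run_config")
}

#' Preprocess a section image
#'
#' The conditioning chain applied after 16-bit conversion and inversion:
#' rolling-ball background subtraction, then median denoising. Stages with a
#' NULL radius are skipped; every applied stage is recorded in provenance.
#'
#' @param image a \code{\link{section_image}}.
#' @param config a \code{\link{run_config}}.
#' @return the processed \code{section_image}.
#' @export
preprocess_section <- function(image, config = run_config()) {
  if (!is.null(config$rolling_ball_radius))
    image <- rolling_ball_subtract(image, config$rolling_ball_radius)
  if (!is.null(config$median_radius))
    image <- median_denoise(image, config$median_radius)
  image
}

#' Analyze one section (blinded stages)
#'
#' Preprocesses the image, constructs the sector geometry from landmarks,
#' segments each region independently by the Li method, applies fiber
#' exclusion from the control squares, and computes per-region metrics.
#' Rostral sections are analyzed as whole + four sectors per hemisphere;
#' caudal sections whole-caudoputamen only. Genotype is unknown to this
#' function.
#'
#' @param image a \code{\link{section_image}} (inverted 16-bit values).
#' @param landmarks a \code{\link{landmark_set}}.
#' @param level "rostral" or "caudal".
#' @param config a \code{\link{run_config}}.
#' @return list with \code{metrics} (data.frame: hemisphere, sector, metric
#'   columns, valid flag), \code{fiber_threshold}, \code{regions},
#'   \code{results} (per-region \code{compartment_result}s) and
#'   \code{warnings}.
#' @export
analyze_section <- function(image, landmarks, level = "rostral",
                            config = run_config()) {
  image <- preprocess_section(image, config)
  regions <- construct_sectors(landmarks, dim(image$pixels))
  fth <- fiber_threshold(image, landmarks$fiber_control_squares)
  region_list <- if (level == "caudal") "whole" else c("whole", sector_names)
  rows <- list(); results <- list(); warns <- character()
  for (side in intersect(c("left", "right"), names(regions))) {
    for (sec in region_list) {
      rid <- paste(side, sec, sep = "/")
      res <- tryCatch(segment_sector(image, regions[[side]][[sec]], rid),
                      error = function(e) e)
      if (inherits(res, "error")) {
        warns <- c(warns, sprintf("%s unsegmentable: %s", rid,
                                  conditionMessage(res)))
        rows[[rid]] <- data.frame(
          hemisphere = side, sector = sec, percent_area = NA_real_,
          strio_intensity = NA_real_, matrix_intensity = NA_real_,
          ismp = NA_real_, total_intensity = NA_real_,
          li_threshold = NA_integer_, fiber_threshold = fth, valid = FALSE,
          stringsAsFactors = FALSE)
        next
      }
      res <- apply_fiber_exclusion(res, image, fth)
      met <- region_metrics(image, res)
      rows[[rid]] <- cbind(data.frame(hemisphere = side, sector = sec,
                                      stringsAsFactors = FALSE),
                           met[setdiff(names(met), "region_id")])
      results[[rid]] <- res
    }
  }
  metrics <- do.call(rbind, rows)
  rownames(metrics) <- NULL
  list(metrics = metrics, fiber_threshold = fth, regions = regions,
       results = results, warnings = warns)
}

#' Run the full pipeline on a cohort
#'
#' Takes a cohort (in-memory, from \code{\link{generate_cohort}}, or a
#' directory written by \code{\link{write_cohort}}), analyzes every section
#' blinded, joins cohort metadata, runs the comparison cascade, and
#' optionally writes metrics, comparisons, summary, audit log and config to
#' an output directory. Per-section failures are isolated and logged; the
#' run fails only when more than \code{max_failure_fraction} of the sections
#' fail.
#'
#' @param cohort cohort object or path to a cohort directory.
#' @param config a \code{\link{run_config}}.
#' @param out_dir optional output directory.
#' @param resume when TRUE and \code{out_dir} contains a metrics.csv from a
#'   previous run, the metrics stage is reused and only the statistics are
#'   recomputed.
#' @return list with \code{metrics}, \code{comparisons}, \code{summary} and
#'   \code{audit}.
#' @export
run_pipeline <- function(cohort, config = run_config(), out_dir = NULL,
                         resume = FALSE) {
  if (is.character(cohort)) cohort <- read_cohort(cohort)
  audit <- list(config = unclass(config), sections = list())
  metrics <- NULL
  metrics_path <- if (!is.null(out_dir)) file.path(out_dir, "metrics.csv")
  if (resume && !is.null(out_dir) && file.exists(metrics_path)) {
    metrics <- utils::read.csv(metrics_path, stringsAsFactors = FALSE)
    audit$resumed <- TRUE
  } else {
    all_rows <- list(); n_fail <- 0L
    for (sid in names(cohort$sections)) {
      sec <- cohort$sections[[sid]]
      res <- tryCatch(
        analyze_section(sec$image, sec$landmarks, sec$meta$level, config),
        error = function(e) e)
      if (inherits(res, "error")) {
        n_fail <- n_fail + 1L
        audit$sections[[sid]] <- list(status = "failed",
                                      error = conditionMessage(res))
        next
      }
      audit$sections[[sid]] <- list(status = "ok",
                                    fiber_threshold = res$fiber_threshold,
                                    warnings = res$warnings)
      all_rows[[sid]] <- cbind(sec$meta, res$metrics, row.names = NULL)
      if (!is.null(out_dir) && isTRUE(config$write_masks))
        write_mask_pngs(res$results, file.path(out_dir, "masks", sid))
    }
    if (n_fail > config$max_failure_fraction * length(cohort$sections))
      stop(sprintf("pipeline failed: %d of %d sections errored", n_fail,
                   length(cohort$sections)))
    metrics <- do.call(rbind, all_rows)
    rownames(metrics) <- NULL
  }
  plan <- comparison_plan(alpha = config$alpha, family_m = config$family_m)
  comparisons <- run_cascade(metrics, plan)
  summary <- summarize_metrics(metrics)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(metrics, metrics_path, row.names = FALSE)
    utils::write.csv(comparisons, file.path(out_dir, "comparisons.csv"),
                     row.names = FALSE)
    utils::write.csv(summary, file.path(out_dir, "summary.csv"),
                     row.names = FALSE)
    jsonlite::write_json(audit, file.path(out_dir, "audit.json"),
                         auto_unbox = TRUE, force = TRUE, digits = NA)
    yaml::write_yaml(unclass(config), file.path(out_dir, "config.yaml"))
  }
  list(metrics = metrics, comparisons = comparisons, summary = summary,
       audit = audit)
}

# --- file I/O ---------------------------------------------------------------

#' Write a section image as 16-bit single-channel TIFF
#' @param image a \code{\link{section_image}}.
#' @param path output path.
#' @export
write_section_tiff <- function(image, path) {
  tiff::writeTIFF(image$pixels / 65535, path, bits.per.sample = 16L)
  invisible(path)
}

#' Read a section image from TIFF (RGB accepted and converted + inverted)
#'
#' Single-channel TIFFs are returned as stored (values scaled back to the
#' 16-bit range); RGB TIFFs are converted to inverted 16-bit grayscale via
#' \code{\link{to_inverted_gray}}.
#'
#' @param path TIFF path.
#' @param pixel_size micrometers per pixel.
#' @param already_inverted whether a single-channel file already holds
#'   inverted values (TRUE for files written by \code{write_section_tiff}).
#' @return a \code{\link{section_image}}.
#' @export
read_section_tiff <- function(path, pixel_size = 1, already_inverted = TRUE) {
  x <- tiff::readTIFF(path)
  if (length(dim(x)) == 3) {
    return(to_inverted_gray(round(x * 255), bits = 8, pixel_size = pixel_size))
  }
  img <- section_image(round(x * 65535), pixel_size)
  if (!already_inverted) img <- to_inverted_gray(img, bits = 16)
  img
}

write_mask_pngs <- function(results, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (rid in names(results)) {
    res <- results[[rid]]
    rgb <- array(0, c(dim(res$striosome_mask), 3))
    rgb[, , 1][res$striosome_mask] <- 1   # red: striosome
    rgb[, , 2][res$matrix_mask] <- 1      # green: matrix
    rgb[, , 3][res$excluded_mask] <- 1    # blue: excluded fiber
    png::writePNG(rgb, file.path(dir, paste0(gsub("/", "_", rid), ".png")))
  }
}

#' Write a synthetic cohort to disk
#'
#' Images as 16-bit TIFF, landmarks as JSON, ground-truth striosome/fiber
#' masks as 8-bit PNG (0/255), metadata as CSV: the same file formats the
#' pipeline reads, so synthetic data exercise the real I/O path.
#'
#' @param cohort from \code{\link{generate_cohort}}.
#' @param dir output directory.
#' @param write_truth also write ground-truth masks.
#' @export
write_cohort <- function(cohort, dir, write_truth = TRUE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (sid in names(cohort$sections)) {
    sec <- cohort$sections[[sid]]
    write_section_tiff(sec$image, file.path(dir, paste0(sid, ".tif")))
    write_landmarks(sec$landmarks, file.path(dir, paste0(sid, ".landmarks.json")))
    if (write_truth) {
      png::writePNG(sec$truth$striosome_mask * 1,
                    file.path(dir, paste0(sid, ".striosome_truth.png")))
      png::writePNG(sec$truth$fiber_mask * 1,
                    file.path(dir, paste0(sid, ".fiber_truth.png")))
    }
  }
  meta <- cohort$metadata
  meta$pixel_size <- cohort$sections[[1]]$image$pixel_size
  utils::write.csv(meta, file.path(dir, "metadata.csv"), row.names = FALSE)
  invisible(dir)
}

#' Read a cohort directory written by \code{\link{write_cohort}}
#'
#' Sections whose image or landmark file is missing are skipped with a
#' warning (they appear in the pipeline audit as absent).
#'
#' @param dir cohort directory.
#' @return cohort object usable by \code{\link{run_pipeline}}.
#' @export
read_cohort <- function(dir) {
  metadata <- utils::read.csv(file.path(dir, "metadata.csv"),
                              stringsAsFactors = FALSE)
  sections <- list()
  for (sid in unique(metadata$section_id)) {
    img_path <- file.path(dir, paste0(sid, ".tif"))
    lm_path <- file.path(dir, paste0(sid, ".landmarks.json"))
    if (!file.exists(img_path) || !file.exists(lm_path)) {
      warning("skipping section with missing files: ", sid, call. = FALSE)
      next
    }
    meta <- metadata[metadata$section_id == sid, , drop = FALSE]
    img <- read_section_tiff(img_path,
                             pixel_size = meta$pixel_size[1] %||% 1)
    sections[[sid]] <- list(image = img, landmarks = read_landmarks(lm_path),
                            meta = meta[1, c("section_id", "animal_id",
                                             "genotype", "age_months", "level")])
  }
  metadata <- metadata[metadata$section_id %in% names(sections), ]
  list(sections = sections, metadata = metadata)
}
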