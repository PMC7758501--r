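#' Landmark set
#'
#' The anatomical points and outlines that drive the sector construction:
#' caudoputamen outlines per hemisphere, the lateral tips of the anterior
#' commissure, the upper tips of the nucleus accumbens shell, and the
#' fiber-tract control squares (50 um side by default) placed on the corpus
#' callosum and anterior commissure. All coordinates are pixels, origin
#' top-left, x rightward, y downward.
#'
#' @param cp_outline_left,cp_outline_right closed simple polygons as n x 2
#'   matrices (x, y); the last vertex is implicitly joined to the first.
#' @param ac_lateral_tip_left,ac_lateral_tip_right numeric length-2 points.
#' @param nacc_shell_upper_tip_left,nacc_shell_upper_tip_right numeric
#'   length-2 points.
#' @param fiber_control_squares list of squares, each
#'   \code{list(center = c(x, y), side_um = 50)}.
#' @return object of class \code{landmark_set}.
#' @export
landmark_set <- function(cp_outline_left = NULL, cp_outline_right = NULL,
                         ac_lateral_tip_left = NULL, ac_lateral_tip_right = NULL,
                         nacc_shell_upper_tip_left = NULL,
                         nacc_shell_upper_tip_right = NULL,
                         fiber_control_squares = list()) {
  structure(list(
    cp_outline_left = cp_outline_left,
    cp_outline_right = cp_outline_right,
    ac_lateral_tip_left = ac_lateral_tip_left,
    ac_lateral_tip_right = ac_lateral_tip_right,
    nacc_shell_upper_tip_left = nacc_shell_upper_tip_left,
    nacc_shell_upper_tip_right = nacc_shell_upper_tip_right,
    fiber_control_squares = fiber_control_squares
  ), class = "landmark_set")
}

#' @export
print.landmark_set <- function(x, ...) {
  have <- names(x)[!vapply(x, is.null, TRUE)]
  cat("<landmark_set>", length(x$fiber_control_squares), "control square(s);",
      "fields:", paste(setdiff(have, "fiber_control_squares"), collapse = ", "),
      "\n")
  invisible(x)
}

#' Write landmarks as JSON
#'
#' @param landmarks a \code{\link{landmark_set}}.
#' @param path output file path.
#' @export
write_landmarks <- function(landmarks, path) {
  doc <- list(
    points = list(
      ac_lateral_tip_left = landmarks$ac_lateral_tip_left,
      ac_lateral_tip_right = landmarks$ac_lateral_tip_right,
      nacc_shell_upper_tip_left = landmarks$nacc_shell_upper_tip_left,
      nacc_shell_upper_tip_right = landmarks$nacc_shell_upper_tip_right
    ),
    polygons = list(
      cp_outline_left = landmarks$cp_outline_left,
      cp_outline_right = landmarks$cp_outline_right
    ),
    fiber_control_squares = lapply(landmarks$fiber_control_squares, function(sq)
      list(center = sq$center, side_um = sq$side_um))
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read landmarks from JSON
#'
#' @param path path to a landmark JSON file written by
#'   \code{\link{write_landmarks}} (or following the same schema).
#' @return a \code{\link{landmark_set}}.
#' @export
read_landmarks <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  as_point <- function(p) if (is.null(p)) NULL else as.numeric(p)
  as_poly <- function(p) if (is.null(p)) NULL else {
    m <- as.matrix(p); storage.mode(m) <- "double"; m
  }
  squares <- list()
  if (!is.null(doc$fiber_control_squares)) {
    fcs <- doc$fiber_control_squares
    if (is.data.frame(fcs)) {
      squares <- lapply(seq_len(nrow(fcs)), function(i)
        list(center = as.numeric(fcs$center[[i]]), side_um = fcs$side_um[[i]]))
    } else {
      squares <- lapply(fcs, function(sq)
        list(center = as.numeric(sq$center), side_um = as.numeric(sq$side_um)))
    }
  }
  landmark_set(
    cp_outline_left = as_poly(doc$polygons$cp_outline_left),
    cp_outline_right = as_poly(doc$polygons$cp_outline_right),
    ac_lateral_tip_left = as_point(doc$points$ac_lateral_tip_left),
    ac_lateral_tip_right = as_point(doc$points$ac_lateral_tip_right),
    nacc_shell_upper_tip_left = as_point(doc$points$nacc_shell_upper_tip_left),
    nacc_shell_upper_tip_right = as_point(doc$points$nacc_shell_upper_tip_right),
    fiber_control_squares = squares
  )
}

#' Validate a landmark set
#'
#' Pure report: checks for missing landmarks, self-intersecting outlines, and
#' control squares overlapping a caudoputamen outline.
#'
#' @param landmarks a \code{\link{landmark_set}}.
#' @param pixel_size micrometers per pixel, used to size the control squares.
#' @return character vector of findings; empty when the set is valid.
#' @export
validate_landmarks <- function(landmarks, pixel_size = 1) {
  findings <- character()
  required <- c("cp_outline_left", "cp_outline_right", "ac_lateral_tip_left",
                "ac_lateral_tip_right", "nacc_shell_upper_tip_left",
                "nacc_shell_upper_tip_right")
  for (f in required)
    if (is.null(landmarks[[f]]))
      findings <- c(findings, paste0("missing landmark: ", f))
  for (side in c("left", "right")) {
    poly <- landmarks[[paste0("cp_outline_", side)]]
    if (!is.null(poly) && polygon_self_intersects(poly))
      findings <- c(findings, paste0("self-intersection: cp_outline_", side))
  }
  for (k in seq_along(landmarks$fiber_control_squares)) {
    sq <- landmarks$fiber_control_squares[[k]]
    half <- max(1, round(sq$side_um / pixel_size)) / 2
    corners <- rbind(sq$center + c(-half, -half), sq$center + c(half, -half),
                     sq$center + c(half, half), sq$center + c(-half, half),
                     sq$center)
    for (side in c("left", "right")) {
      poly <- landmarks[[paste0("cp_outline_", side)]]
      if (is.null(poly)) next
      if (any(point_in_polygon(corners[, 1], corners[, 2], poly)))
        findings <- c(findings,
                      paste0("control square ", k, " overlaps cp_outline_", side))
    }
  }
  findings
}
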