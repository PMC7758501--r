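# Landmark-driven construction of the caudoputamen sectors (whole, DM, DL,
# VM, VL) per hemisphere, following the ruler-and-compass recipe:
#   line 1: inter-hemispheric tangent between the two caudoputamen outlines
#   line 2: parallel to line 1 through the AC lateral tip
#   line 3: NAcc-shell upper tip -> dorsal crossing of line 2 with the outline
#   line 4: perpendicular to line 1 from the NAcc-shell upper tip (lateral)
#   line 5: parallel to line 3 through the midpoint of line 4
#   line 6: through the midpoints of the striatal chords of lines 3 and 5
# The outline is cut by line 5 (dorsal/ventral divider) and line 6
# (medial/lateral divider), both extended to the outline boundary.

# --- polygon helpers (pixel coords: x rightward, y downward) ----------------

# Vectorized even-odd (crossing-number) point-in-polygon test.
# Points outside the polygon's bounding box are rejected without edge tests.
point_in_polygon <- function(px, py, poly) {
  n <- nrow(poly)
  inside <- logical(length(px))
  box <- px >= min(poly[, 1]) & px <= max(poly[, 1]) &
    py >= min(poly[, 2]) & py <= max(poly[, 2])
  if (!any(box)) return(inside)
  qx <- px[box]; qy <- py[box]
  ins <- logical(length(qx))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    cross <- which((yi > qy) != (yj > qy))
    if (length(cross)) {
      xint <- xi + (qy[cross] - yi) * (xj - xi) / (yj - yi)
      flip <- cross[qx[cross] < xint]
      ins[flip] <- !ins[flip]
    }
    j <- i
  }
  inside[box] <- ins
  inside
}

segments_intersect <- function(p1, p2, p3, p4) {
  d <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
  d1 <- d(p3, p4, p1); d2 <- d(p3, p4, p2)
  d3 <- d(p1, p2, p3); d4 <- d(p1, p2, p4)
  (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
     ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0)))
}

polygon_self_intersects <- function(poly) {
  n <- nrow(poly)
  edges <- cbind(seq_len(n), c(seq_len(n)[-1], 1L))
  for (a in seq_len(n - 2)) {
    for (b in seq.int(a + 2, n)) {
      if (a == 1 && b == n) next  # adjacent through closure
      if (segments_intersect(poly[edges[a, 1], ], poly[edges[a, 2], ],
                             poly[edges[b, 1], ], poly[edges[b, 2], ]))
        return(TRUE)
    }
  }
  FALSE
}

# Intersections of the infinite line p0 + t*d with polygon edges.
# Returns sorted t values (may be empty).
line_polygon_ts <- function(p0, d, poly) {
  n <- nrow(poly)
  ts <- numeric()
  j <- n
  for (i in seq_len(n)) {
    a <- poly[j, ]; b <- poly[i, ]
    e <- b - a
    denom <- d[1] * e[2] - d[2] * e[1]
    if (abs(denom) > 1e-12) {
      # solve p0 + t d = a + u e
      t <- ((a[1] - p0[1]) * e[2] - (a[2] - p0[2]) * e[1]) / denom
      u <- ((a[1] - p0[1]) * d[2] - (a[2] - p0[2]) * d[1]) / denom
      if (u >= 0 && u < 1) ts <- c(ts, t)
    }
    j <- i
  }
  sort(ts)
}

normalize <- function(v) v / sqrt(sum(v^2))
perp <- function(v) c(-v[2], v[1])
cross2 <- function(u, v) u[1] * v[2] - u[2] * v[1]

polygon_centroid <- function(poly) colMeans(poly)

# --- sector construction ----------------------------------------------------

geom_error <- function(...) stop(paste0(...), call. = FALSE)

# Build the divider lines for one hemisphere. Returns list(line5, line6) with
# each line as list(p = point, d = unit direction), plus scaffold lines.
hemisphere_lines <- function(outline, ac_tip, nacc_tip, u1, lat_dir) {
  if (is.null(outline)) geom_error("missing landmark: cp_outline")
  if (is.null(ac_tip)) geom_error("missing landmark: ac_lateral_tip")
  if (is.null(nacc_tip)) geom_error("missing landmark: nacc_shell_upper_tip")
  # line 2 through the AC lateral tip, parallel to line 1
  ts2 <- line_polygon_ts(ac_tip, u1, outline)
  if (length(ts2) < 2)
    geom_error("degenerate geometry: line 2 does not cross the outline")
  pts2 <- t(vapply(ts2, function(t) ac_tip + t * u1, numeric(2)))
  p3 <- pts2[which.min(pts2[, 2]), ]       # dorsal-most crossing (min y)
  u3 <- normalize(p3 - nacc_tip)
  # line 4: perpendicular to line 1, from the NAcc tip toward lateral
  d4 <- normalize(lat_dir - sum(lat_dir * u1) * u1)
  ts4 <- line_polygon_ts(nacc_tip, d4, outline)
  ts4 <- ts4[ts4 > 1e-9]
  if (!length(ts4))
    geom_error("degenerate geometry: line 4 does not reach the outline")
  e4 <- nacc_tip + max(ts4) * d4
  m4 <- (nacc_tip + e4) / 2
  # striatal chord midpoints of lines 3 and 5
  chord_mid <- function(p, d) {
    ts <- line_polygon_ts(p, d, outline)
    if (length(ts) < 2)
      geom_error("degenerate geometry: divider line misses the outline")
    (p + min(ts) * d + p + max(ts) * d) / 2
  }
  m3c <- chord_mid(nacc_tip, u3)
  m5c <- chord_mid(m4, u3)
  if (sqrt(sum((m5c - m3c)^2)) < 1e-9)
    geom_error("degenerate geometry: lines 3 and 5 coincide")
  u6 <- normalize(m5c - m3c)
  list(line3 = list(p = nacc_tip, d = u3),
       line5 = list(p = m4, d = u3),
       line6 = list(p = m3c, d = u6))
}

sector_names <- c("dorsomedial", "dorsolateral", "ventromedial", "ventrolateral")

# Orientation sign of a divider line: the side containing the first
# reference point that does not lie on the line.
ref_sign <- function(line, refs) {
  for (q in refs) {
    s <- cross2(line$d, q - line$p)
    if (abs(s) > 1e-9) return(sign(s))
  }
  geom_error("degenerate geometry: cannot orient divider line")
}

#' Construct caudoputamen sectors from landmarks
#'
#' Builds, per hemisphere, pixel masks for the whole caudoputamen and its
#' dorsomedial, dorsolateral, ventromedial and ventrolateral sectors via the
#' six-line landmark construction (see the package vignette for the exact
#' recipe and the conventions adopted where the published description is
#' ambiguous). The four sector masks are pairwise disjoint and their union
#' equals the whole mask exactly; pixels falling exactly on a divider line are
#' assigned to the sector with the nearest centroid (ties resolved in the
#' order DM, DL, VM, VL).
#'
#' @param landmarks a \code{\link{landmark_set}}; both caudoputamen outlines
#'   are required (line 1 is inter-hemispheric), plus the AC and NAcc points
#'   of every hemisphere to be built.
#' @param image_shape integer vector \code{c(nrow, ncol)} of the image the
#'   masks refer to.
#' @param hemispheres which hemispheres to construct.
#' @return object of class \code{region_set}: a named list with one entry per
#'   hemisphere, each holding logical masks \code{whole}, \code{dorsomedial},
#'   \code{dorsolateral}, \code{ventromedial}, \code{ventrolateral}, plus the
#'   divider lines used.
#' @export
construct_sectors <- function(landmarks, image_shape,
                              hemispheres = c("left", "right")) {
  ol <- landmarks$cp_outline_left
  or <- landmarks$cp_outline_right
  if (is.null(ol)) geom_error("missing landmark: cp_outline_left")
  if (is.null(or)) geom_error("missing landmark: cp_outline_right")
  cl <- polygon_centroid(ol); cr <- polygon_centroid(or)
  if (cl[1] > cr[1]) geom_error("left outline lies right of right outline")
  # medial extreme points: toward the other hemisphere along the centroid
  # axis; ties (e.g. a flat medial edge) are averaged
  axis <- normalize(cr - cl)
  extreme <- function(poly, dir) {
    sc <- as.numeric(poly %*% dir)
    colMeans(poly[sc >= max(sc) - 1e-9, , drop = FALSE])
  }
  ml <- extreme(ol, axis)    # left outline, most medial
  mr <- extreme(or, -axis)   # right outline, most medial
  # line 1: inter-hemispheric tangent; direction perpendicular to the centroid
  # axis, through the midpoint of the medial extreme points
  u1 <- perp(axis)
  if (u1[2] < 0) u1 <- -u1
  p1 <- (ml + mr) / 2
  nr <- image_shape[1]; nc <- image_shape[2]
  px <- rep(seq_len(nc), each = nr)   # x = column
  py <- rep(seq_len(nr), times = nc)  # y = row
  out <- list()
  for (h in hemispheres) {
    outline <- if (h == "left") ol else or
    ac <- landmarks[[paste0("ac_lateral_tip_", h)]]
    na <- landmarks[[paste0("nacc_shell_upper_tip_", h)]]
    if (is.null(ac)) geom_error("missing landmark: ac_lateral_tip_", h)
    if (is.null(na)) geom_error("missing landmark: nacc_shell_upper_tip_", h)
    ctr <- polygon_centroid(outline)
    # lateral: perpendicular offset of the hemisphere centroid from line 1
    off <- (ctr - p1) - sum((ctr - p1) * u1) * u1
    lat_dir <- normalize(off)
    lines <- hemisphere_lines(outline, ac, na, u1, lat_dir)
    inside <- point_in_polygon(px, py, outline)
    idx <- which(inside)
    qx <- px[idx]; qy <- py[idx]
    s5 <- lines$line5$d[1] * (qy - lines$line5$p[2]) -
      lines$line5$d[2] * (qx - lines$line5$p[1])
    s6 <- lines$line6$d[1] * (qy - lines$line6$p[2]) -
      lines$line6$d[2] * (qx - lines$line6$p[1])
    # dorsal side of line 5: the side holding the dorsal-most outline points;
    # medial side of line 6: the side holding the midline anchor (fallbacks:
    # the NAcc tip, then the medial extreme of the outline)
    dorsal_refs <- lapply(order(outline[, 2])[1:3], function(i) outline[i, ])
    dorsal_sign <- ref_sign(lines$line5, dorsal_refs)
    medial_sign <- ref_sign(lines$line6,
                            list(p1, na, extreme(outline, -lat_dir)))
    dorsal <- s5 * dorsal_sign > 0
    medial <- s6 * medial_sign > 0
    sec <- integer(length(idx))  # 1 DM, 2 DL, 3 VM, 4 VL
    sec[dorsal & medial] <- 1L
    sec[dorsal & !medial] <- 2L
    sec[!dorsal & medial] <- 3L
    sec[!dorsal & !medial] <- 4L
    on_line <- abs(s5) < 1e-9 | abs(s6) < 1e-9
    if (any(on_line) && any(!on_line)) {
      cents <- vapply(1:4, function(k) {
        sel <- sec == k & !on_line
        if (!any(sel)) c(NA_real_, NA_real_) else c(mean(qx[sel]), mean(qy[sel]))
      }, numeric(2))
      for (i in which(on_line)) {
        d2 <- (cents[1, ] - qx[i])^2 + (cents[2, ] - qy[i])^2
        sec[i] <- which.min(d2)  # which.min takes the first on ties: DM first
      }
    }
    masks <- list(whole = matrix(FALSE, nr, nc))
    masks$whole[cbind(qy, qx)] <- TRUE
    for (k in 1:4) {
      m <- matrix(FALSE, nr, nc)
      sel <- sec == k
      m[cbind(qy[sel], qx[sel])] <- TRUE
      masks[[sector_names[k]]] <- m
    }
    out[[h]] <- c(masks, list(lines = lines))
  }
  structure(c(out, list(line1 = list(p = p1, d = u1))), class = "region_set")
}

#' @export
print.region_set <- function(x, ...) {
  for (h in intersect(c("left", "right"), names(x))) {
    areas <- vapply(c("whole", sector_names), function(s) sum(x[[h]][[s]]), 0)
    cat(sprintf("<region_set> %s: %s\n", h,
                paste(names(areas), areas, sep = "=", collapse = " ")))
  }
  invisible(x)
}
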