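# Synthetic striatal-section generator: cohort designs, effect models,
# striosome patterns, section rendering with landmarks and ground truth.

#' Cohort design
#'
#' Describes a cross-sectional cohort: animals per genotype x age cell, each
#' contributing one section per anteroposterior level with both hemispheres.
#' Defaults mirror the reference study design: two genotypes, ages 3/6/12/19
#' months, 8 animals per cell, two hemispheres (16 caudoputamen samples per
#' group), rostral and caudal levels.
#'
#' @param genotypes character vector, subset of c("WT", "MUT").
#' @param ages numeric vector of age labels in months (nonempty).
#' @param levels anteroposterior levels to simulate.
#' @param n_per_cell animals per genotype x age cell (>= 1).
#' @param hemispheres_per_animal 1 or 2.
#' @param seed integer; fixes the entire cohort byte-for-byte.
#' @return object of class \code{cohort_design}.
#' @export
cohort_design <- function(genotypes = c("WT", "MUT"),
                          ages = c(3, 6, 12, 19),
                          levels = c("rostral", "caudal"),
                          n_per_cell = 8, hemispheres_per_animal = 2,
                          seed = 1L) {
  if (n_per_cell < 1) stop("design error: n_per_cell must be >= 1")
  if (!length(ages)) stop("design error: ages must be nonempty")
  stopifnot(all(genotypes %in% c("WT", "MUT")),
            all(levels %in% c("rostral", "caudal")),
            hemispheres_per_animal %in% 1:2)
  structure(list(genotypes = genotypes, ages = ages, levels = levels,
                 n_per_cell = n_per_cell,
                 hemispheres_per_animal = hemispheres_per_animal,
                 seed = as.integer(seed)),
            class = "cohort_design")
}

#' Effect model for the synthetic generator
#'
#' Expected compartment intensities per genotype, age, level and sector, plus
#' the noise model. Defaults encode the qualitative progression the pipeline
#' is meant to detect: striosome intensity rises in mutants before matrix
#' intensity does (dorsolateral sector first), and caudal wildtype sections
#' carry essentially no striosome contrast while caudal mutants are strongly
#' labeled at every age.
#'
#' @param striosome_base,matrix_base expected striosome/matrix pixel values in
#'   a visible-striosome section (defaults 180/120; the 60-level gap).
#' @param strio_effect added to mutant striosome intensity in the sectors
#'   scheduled in \code{strio_effect_sectors}.
#' @param matrix_effect added to mutant matrix intensity per
#'   \code{matrix_effect_sectors}.
#' @param strio_effect_sectors,matrix_effect_sectors named lists (age label ->
#'   character vector of sectors) giving where mutant effects act at each age.
#' @param caudal_wt_striosome_gain,caudal_mut_striosome_gain multiplier on the
#'   striosome-matrix contrast in caudal sections (0 = invisible striosomes).
#' @param density_rostral,density_caudal_wt,density_caudal_mut striosome area
#'   fraction targets for the pattern generator.
#' @param density_rostral_mut_19 rostral mutant density at 19 months (areal
#'   expansion at the oldest age).
#' @param noise_sd additive Gaussian noise SD (gray levels).
#' @param shading_amplitude amplitude of the multiplicative low-frequency
#'   shading field (fraction of signal).
#' @param fiber_intensity expected value of intra-striatal fiber streaks.
#' @param control_fiber_intensity expected value of the large commissural
#'   bundles carrying the control squares (slightly above the streaks, so the
#'   truncated-mean control threshold sits above the streak distribution).
#' @param background_intensity expected value outside tissue structures.
#' @param animal_sd,section_sd SDs of per-animal and per-hemisphere-section
#'   random intercepts, applied per compartment.
#' @return object of class \code{effect_model}.
#' @export
effect_model <- function(striosome_base = 180, matrix_base = 120,
                         strio_effect = 40, matrix_effect = 25,
                         strio_effect_sectors = list(
                           "3" = "dorsolateral",
                           "6" = "dorsolateral",
                           "12" = c("dorsomedial", "dorsolateral", "ventrolateral"),
                           "19" = c("dorsomedial", "dorsolateral",
                                    "ventromedial", "ventrolateral")),
                         matrix_effect_sectors = list(
                           "12" = c("dorsolateral", "ventrolateral"),
                           "19" = c("dorsomedial", "dorsolateral",
                                    "ventromedial", "ventrolateral")),
                         caudal_wt_striosome_gain = 0,
                         caudal_mut_striosome_gain = 1,
                         density_rostral = 0.15,
                         density_rostral_mut_19 = 0.19,
                         density_caudal_wt = 0.12,
                         density_caudal_mut = 0.15,
                         noise_sd = 5, shading_amplitude = 0.05,
                         fiber_intensity = 50, control_fiber_intensity = 60,
                         background_intensity = 2,
                         animal_sd = 1.5, section_sd = 4) {
  stopifnot(striosome_base >= matrix_base, matrix_base >= 0,
            striosome_base + strio_effect <= 65535)
  structure(as.list(environment()), class = "effect_model")
}

# Expected compartment intensities for one section, before random intercepts.
resolve_intensities <- function(effects, genotype, age, level) {
  secs <- sector_names
  contrast <- effects$striosome_base - effects$matrix_base
  if (level == "rostral") {
    strio <- stats::setNames(rep(effects$striosome_base, 4), secs)
    matr <- stats::setNames(rep(effects$matrix_base, 4), secs)
    if (genotype == "MUT") {
      key <- as.character(age)
      strio[intersect(secs, effects$strio_effect_sectors[[key]])] <-
        strio[intersect(secs, effects$strio_effect_sectors[[key]])] +
        effects$strio_effect
      matr[intersect(secs, effects$matrix_effect_sectors[[key]])] <-
        matr[intersect(secs, effects$matrix_effect_sectors[[key]])] +
        effects$matrix_effect
    }
  } else {
    gain <- if (genotype == "WT") effects$caudal_wt_striosome_gain
            else effects$caudal_mut_striosome_gain
    strio <- stats::setNames(rep(effects$matrix_base + gain * contrast, 4), secs)
    matr <- stats::setNames(rep(effects$matrix_base, 4), secs)
  }
  list(strio = strio, matrix = matr)
}

pattern_density <- function(effects, genotype, age, level) {
  if (level == "rostral") {
    if (genotype == "MUT" && as.character(age) == "19")
      effects$density_rostral_mut_19 else effects$density_rostral
  } else {
    if (genotype == "WT") effects$density_caudal_wt else effects$density_caudal_mut
  }
}

# --- section geometry -------------------------------------------------------

# Jittered elliptical caudoputamen outline (simple closed polygon).
cp_outline_polygon <- function(center, a, b, n_vertices = 36, jitter = 0.03) {
  theta <- seq(0, 2 * pi, length.out = n_vertices + 1)[-(n_vertices + 1)]
  r <- rep(1, n_vertices)
  for (k in 2:4)
    r <- r + jitter * stats::rnorm(1) * cos(k * theta + stats::runif(1, 0, 2 * pi))
  cbind(center[1] + a * r * cos(theta), center[2] + b * r * sin(theta))
}

disk_mask <- function(shape, center, radius) {
  nr <- shape[1]; nc <- shape[2]
  xx <- matrix(rep(seq_len(nc), each = nr), nr, nc)
  yy <- matrix(rep(seq_len(nr), nc), nr, nc)
  (xx - center[1])^2 + (yy - center[2])^2 <= radius^2
}

# Thin fiber streak: points within distance `width` of a segment.
streak_mask <- function(shape, p0, p1, width = 1) {
  nr <- shape[1]; nc <- shape[2]
  xx <- matrix(rep(seq_len(nc), each = nr), nr, nc)
  yy <- matrix(rep(seq_len(nr), nc), nr, nc)
  d <- p1 - p0
  len2 <- sum(d^2)
  t <- clamp(((xx - p0[1]) * d[1] + (yy - p0[2]) * d[2]) / len2, 0, 1)
  (xx - (p0[1] + t * d[1]))^2 + (yy - (p0[2] + t * d[2]))^2 <= width^2
}

# Build landmarks + fiber structures for one synthetic section.
# Called inside an active RNG context.
section_geometry <- function(shape = c(140, 200), pixel_size = 10,
                             jitter = 0.03, n_fascicles = 6,
                             control_square_um = 50, max_retry = 10) {
  nr <- shape[1]; nc <- shape[2]
  a <- 0.21 * nc; b <- 0.24 * nr
  cy <- 0.47 * nr
  centers <- list(left = c(0.27 * nc, cy), right = c(0.73 * nc, cy))
  outlines <- lapply(centers, function(ctr) cp_outline_polygon(ctr, a, b,
                                                               jitter = jitter))
  lm <- landmark_set(
    cp_outline_left = outlines$left, cp_outline_right = outlines$right,
    ac_lateral_tip_left = c(centers$left[1] - 0.60 * a, cy + b + 0.10 * nr),
    ac_lateral_tip_right = c(centers$right[1] + 0.60 * a, cy + b + 0.10 * nr),
    nacc_shell_upper_tip_left = c(centers$left[1] + 0.81 * a, cy + 0.40 * b),
    nacc_shell_upper_tip_right = c(centers$right[1] - 0.81 * a, cy + 0.40 * b)
  )
  # corpus callosum band (dorsal strip) and anterior commissure blobs
  fiber <- matrix(FALSE, nr, nc)
  cc_rows <- seq(max(1L, round(0.05 * nr)), round(0.12 * nr))
  fiber[cc_rows, ] <- TRUE
  ac_center <- c(0.5 * nc + stats::rnorm(1, 0, 2), 0.84 * nr)
  fiber <- fiber | disk_mask(shape, ac_center, 0.05 * nc)
  # intra-striatal pencil fibers: small scattered fascicles (in coronal
  # section these appear as sparse puncta, ~1% of the caudoputamen area)
  if (n_fascicles > 0) {
    for (side in c("left", "right")) {
      ctr <- centers[[side]]
      for (s in seq_len(n_fascicles)) {
        pos <- ctr + c(stats::runif(1, -0.7, 0.7) * a, stats::runif(1, -0.7, 0.7) * b)
        fiber <- fiber | disk_mask(shape, pos, stats::runif(1, 0.8, 1.3))
      }
    }
  }
  # control squares centered on the fiber bundles; retried until fully inside
  side_px <- max(1L, round(control_square_um / pixel_size))
  place_square <- function(target) {
    for (k in seq_len(max_retry)) {
      cand <- target + if (k == 1) c(0, 0) else round(stats::rnorm(2, 0, 3))
      ij <- tryCatch(square_indices(cand, control_square_um, pixel_size, shape),
                     error = function(e) NULL)
      if (!is.null(ij) && all(fiber[ij$rows, ij$cols])) return(cand)
    }
    geom_error("could not place control square inside fiber mask")
  }
  sq1 <- place_square(c(round(0.5 * nc), round(mean(cc_rows))))
  sq2 <- place_square(round(ac_center))
  lm$fiber_control_squares <- list(
    list(center = sq1, side_um = control_square_um),
    list(center = sq2, side_um = control_square_um))
  list(landmarks = lm, fiber_mask = fiber, centers = centers, a = a, b = b)
}

# --- striosome pattern ------------------------------------------------------

#' Generate a striosome pattern inside an outline
#'
#' Union of Gaussian-smoothed random blobs clipped to the outline, thresholded
#' so the realized area fraction matches \code{density}; blob placement
#' probability increases linearly toward the dorsal rim of the outline.
#'
#' @param outline closed polygon (n x 2 matrix, pixel coordinates).
#' @param level level label ("rostral"/"caudal"); recorded only.
#' @param density target striosome area fraction in [0, 0.4].
#' @param seed integer seed; same inputs and seed give identical masks.
#' @param shape image shape \code{c(nrow, ncol)}.
#' @param sigma smoothing SD of the blob field in pixels.
#' @param dorsal_gain strength of the within-region dorsoventral placement
#'   gradient, in SD units of the smoothed field.
#' @param strata optional list of logical masks (e.g. sector masks); the
#'   density quantile is applied within each stratum, so each receives its
#'   target fraction exactly. Used by the cohort generator to guarantee
#'   striosome presence in every sector, with a dorsal density tilt.
#' @param strata_weights density multipliers per stratum (default 1).
#' @return logical matrix of shape \code{shape}.
#' @export
generate_striosome_pattern <- function(outline, level = "rostral", density,
                                       seed = 1L, shape = c(140, 200),
                                       sigma = 3, dorsal_gain = 0.25,
                                       strata = NULL, strata_weights = NULL) {
  stopifnot(density >= 0, density <= 0.4)
  nr <- shape[1]; nc <- shape[2]
  px <- rep(seq_len(nc), each = nr); py <- rep(seq_len(nr), times = nc)
  inside <- matrix(point_in_polygon(px, py, outline), nr, nc)
  n_in <- sum(inside)
  if (n_in == 0) geom_error("invalid geometry: outline encloses no pixels")
  if (density == 0) return(matrix(FALSE, nr, nc))
  with_seed(seed, {
    field <- gaussian_blur(matrix(stats::rnorm(nr * nc), nr, nc), sigma)
    field <- (field - mean(field[inside])) / stats::sd(field[inside])
    ys <- range(py[inside])
    dorsality <- (ys[2] - matrix(rep(seq_len(nr), nc), nr, nc)) / max(1, diff(ys))
    field <- field + dorsal_gain * (dorsality - 0.5)
    if (is.null(strata)) {
      q <- stats::quantile(field[inside], 1 - density, names = FALSE)
      inside & (field > q)
    } else {
      if (is.null(strata_weights)) strata_weights <- rep(1, length(strata))
      out <- matrix(FALSE, nr, nc)
      covered <- matrix(FALSE, nr, nc)
      for (k in seq_along(strata)) {
        m <- strata[[k]] & inside
        covered <- covered | m
        if (!any(m)) next
        dk <- clamp(density * strata_weights[k], 0, 0.4)
        if (dk == 0) next
        qk <- stats::quantile(field[m], 1 - dk, names = FALSE)
        out <- out | (m & field > qk)
      }
      rest <- inside & !covered
      if (any(rest)) {
        qr <- stats::quantile(field[rest], 1 - density, names = FALSE)
        out <- out | (rest & field > qr)
      }
      out
    }
  })
}

# --- ground truth + rendering ----------------------------------------------

# Assemble the ground truth for one section. `intercepts` is a list per
# hemisphere: list(strio = scalar, matrix = scalar) added to all sectors.
generate_section_truth <- function(genotype, age, level, effects, seed,
                                   shape = c(140, 200), pixel_size = 10) {
  with_seed(seed, {
    # pencil-fiber fascicles pepper the rostral caudoputamen; at the caudal
    # level the fiber structures are the commissural bundles outside it
    geo <- section_geometry(shape, pixel_size,
                            n_fascicles = if (level == "rostral") 6 else 0)
    regions <- construct_sectors(geo$landmarks, shape)
    dens <- pattern_density(effects, genotype, age, level)
    strio <- matrix(FALSE, shape[1], shape[2])
    pat_seeds <- sample.int(.Machine$integer.max - 1L, 2)
    # per-sector density strata with a dorsal tilt: guarantees striosome
    # presence in every sector (as in real anatomy) while keeping the
    # dorsal rim enriched
    tilt <- c(dorsomedial = 1.15, dorsolateral = 1.15,
              ventromedial = 0.85, ventrolateral = 0.85)
    for (i in 1:2) {
      side <- c("left", "right")[i]
      pat <- generate_striosome_pattern(
        geo$landmarks[[paste0("cp_outline_", side)]], level, dens,
        seed = pat_seeds[i], shape = shape,
        strata = lapply(sector_names, function(s) regions[[side]][[s]]),
        strata_weights = unname(tilt[sector_names]))
      strio <- strio | (pat & regions[[side]]$whole)
    }
    strio <- strio & !geo$fiber_mask
    base <- resolve_intensities(effects, genotype, age, level)
    intensity <- list()
    for (side in c("left", "right")) {
      intensity[[side]] <- list(
        strio = clamp(base$strio + stats::rnorm(1, 0, effects$animal_sd) +
                        stats::rnorm(1, 0, effects$section_sd), 0, 65535),
        matrix = clamp(base$matrix + stats::rnorm(1, 0, effects$animal_sd) +
                         stats::rnorm(1, 0, effects$section_sd), 0, 65535))
    }
    structure(list(
      genotype = genotype, age = age, level = level,
      shape = shape, pixel_size = pixel_size,
      landmarks = geo$landmarks, regions = regions,
      striosome_mask = strio, fiber_mask = geo$fiber_mask,
      intensity = intensity, density = dens,
      effects_digest = list(noise_sd = effects$noise_sd,
                            shading = effects$shading_amplitude)
    ), class = "section_truth")
  })
}

# Per-animal variant: intercepts drawn once per animal are passed in and the
# per-section draw only adds section-level variation.
apply_intercepts <- function(truth, animal_int, effects, seed) {
  with_seed(seed, {
    base <- resolve_intensities(effects, truth$genotype, truth$age, truth$level)
    for (side in c("left", "right")) {
      truth$intensity[[side]] <- list(
        strio = clamp(base$strio + animal_int$strio +
                        stats::rnorm(1, 0, effects$section_sd), 0, 65535),
        matrix = clamp(base$matrix + animal_int$matrix +
                         stats::rnorm(1, 0, effects$section_sd), 0, 65535))
    }
    truth
  })
}

# Expected (noise-free) pixel grid for a section truth.
expected_image <- function(truth, effects) {
  nr <- truth$shape[1]; nc <- truth$shape[2]
  img <- matrix(effects$background_intensity, nr, nc)
  img[truth$fiber_mask] <- effects$control_fiber_intensity
  for (side in c("left", "right")) {
    whole <- truth$regions[[side]]$whole
    for (sec in sector_names) {
      m <- truth$regions[[side]][[sec]]
      img[m] <- truth$intensity[[side]]$matrix[[sec]]
      img[m & truth$striosome_mask] <- truth$intensity[[side]]$strio[[sec]]
    }
    # intra-striatal streaks are dimmer than the commissural bundles
    img[whole & truth$fiber_mask] <- effects$fiber_intensity
  }
  img
}

#' Render a synthetic section
#'
#' Turns a ground truth into a 16-bit section image: expected compartment
#' intensity per pixel, multiplied by a low-frequency shading field and
#' perturbed by additive Gaussian noise, clipped to the 16-bit range. The
#' matching landmark file content is returned alongside.
#'
#' @param truth a \code{section_truth} (see \code{\link{generate_cohort}}).
#' @param effects an \code{\link{effect_model}} (noise and shading are read
#'   from it).
#' @param seed integer seed for noise and shading.
#' @return list with \code{image} (a \code{\link{section_image}}),
#'   \code{landmarks} (a \code{\link{landmark_set}}) and \code{truth}.
#' @export
render_section <- function(truth, effects, seed = 1L) {
  nr <- truth$shape[1]; nc <- truth$shape[2]
  img <- expected_image(truth, effects)
  with_seed(seed, {
    if (effects$shading_amplitude > 0) {
      sh <- gaussian_blur(matrix(stats::rnorm(nr * nc), nr, nc), min(nr, nc) / 4)
      sh <- sh / max(abs(sh))
      img <- img * (1 + effects$shading_amplitude * sh)
    }
    if (effects$noise_sd > 0)
      img <- img + stats::rnorm(nr * nc, 0, effects$noise_sd)
  })
  img <- clamp(round(img), 0, 65535)
  list(image = section_image(img, truth$pixel_size,
                             list(list(op = "render_section"))),
       landmarks = truth$landmarks, truth = truth)
}

#' Analytic ground-truth metrics for a section
#'
#' The noise-free per-sector metrics implied by the masks and programmed
#' intensities, using the same definitions as the measurement pipeline
#' (striosome fraction of the fiber-excluded sector area; programmed
#' compartment intensities; their ratio; intensity x fraction).
#'
#' @param truth a \code{section_truth}.
#' @return data.frame, one row per hemisphere x sector (whole + 4 sectors).
#' @export
true_metrics <- function(truth) {
  rows <- list()
  for (side in c("left", "right")) {
    regs <- truth$regions[[side]]
    secs <- c("whole", sector_names)
    for (sec in secs) {
      m <- regs[[sec]]
      n_fib <- sum(m & truth$fiber_mask)
      n_str <- sum(m & truth$striosome_mask)
      denom <- sum(m) - n_fib
      if (sec == "whole") {
        # area-weighted programmed intensities over the four sectors
        sv <- mv <- 0; ns <- nm <- 0
        for (s2 in sector_names) {
          m2 <- regs[[s2]]
          n2s <- sum(m2 & truth$striosome_mask)
          n2m <- sum(m2) - n2s - sum(m2 & truth$fiber_mask)
          sv <- sv + n2s * truth$intensity[[side]]$strio[[s2]]
          mv <- mv + n2m * truth$intensity[[side]]$matrix[[s2]]
          ns <- ns + n2s; nm <- nm + n2m
        }
        si <- if (ns > 0) sv / ns else NA_real_
        mi <- if (nm > 0) mv / nm else NA_real_
      } else {
        si <- truth$intensity[[side]]$strio[[sec]]
        mi <- truth$intensity[[side]]$matrix[[sec]]
        if (n_str == 0) si <- NA_real_
      }
      pa <- if (denom > 0) n_str / denom else NA_real_
      rows[[length(rows) + 1L]] <- data.frame(
        hemisphere = side, sector = sec, percent_area = pa,
        strio_intensity = si, matrix_intensity = mi,
        ismp = ismp(si, mi), total_intensity = si * pa,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Generate a synthetic cohort
#'
#' One section (image + landmarks + ground truth) per animal x level.
#' Per-animal random intercepts are drawn once per animal and shared by its
#' sections; hemisphere/section intercepts are drawn per section side. The
#' whole collection is a pure function of (design, effects, design$seed).
#'
#' @param design a \code{\link{cohort_design}}.
#' @param effects an \code{\link{effect_model}}.
#' @param shape image shape \code{c(nrow, ncol)} in pixels.
#' @param pixel_size micrometers per pixel.
#' @return list with \code{sections} (list of rendered sections, each as
#'   returned by \code{\link{render_section}} plus a \code{meta} row) and
#'   \code{metadata} (data.frame, one row per hemisphere sample).
#' @export
generate_cohort <- function(design, effects = effect_model(),
                            shape = c(140, 200), pixel_size = 10) {
  stopifnot(inherits(design, "cohort_design"), inherits(effects, "effect_model"))
  cells <- expand.grid(genotype = design$genotypes, age = design$ages,
                       idx = seq_len(design$n_per_cell),
                       stringsAsFactors = FALSE)
  n_animals <- nrow(cells)
  seeds <- derive_seeds(design$seed, 3 * n_animals * length(design$levels) +
                          n_animals)
  sections <- list()
  meta <- list()
  si <- 0L
  for (ai in seq_len(n_animals)) {
    genotype <- cells$genotype[ai]; age <- cells$age[ai]
    animal_id <- sprintf("%s_a%02d_%02d", genotype, age, cells$idx[ai])
    animal_int <- with_seed(seeds[ai], list(
      strio = stats::rnorm(1, 0, effects$animal_sd),
      matrix = stats::rnorm(1, 0, effects$animal_sd)))
    for (lv in design$levels) {
      si <- si + 1L
      s_truth <- seeds[n_animals + 3 * si - 2L]
      s_int <- seeds[n_animals + 3 * si - 1L]
      s_noise <- seeds[n_animals + 3 * si]
      truth <- generate_section_truth(genotype, age, lv, effects, s_truth,
                                      shape, pixel_size)
      truth <- apply_intercepts(truth, animal_int, effects, s_int)
      sec <- render_section(truth, effects, s_noise)
      section_id <- sprintf("%s_%s", animal_id, lv)
      sec$meta <- data.frame(section_id = section_id, animal_id = animal_id,
                             genotype = genotype, age_months = age, level = lv,
                             stringsAsFactors = FALSE)
      sections[[section_id]] <- sec
      hemis <- c("left", "right")[seq_len(design$hemispheres_per_animal)]
      for (h in hemis)
        meta[[length(meta) + 1L]] <- cbind(sec$meta, hemisphere = h)
    }
  }
  metadata <- do.call(rbind, meta)
  rownames(metadata) <- NULL
  list(sections = sections, metadata = metadata, design = design,
       effects = effects)
}
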