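# Power / type-I simulation harness around the comparison cascade.
#
# Effect detection runs the full image pipeline on replicate synthetic
# cohorts; type-I calibration simulates metric tables directly from the
# generator's statistical structure (intercepts + sampling noise), which is
# what the cascade consumes, at a fraction of the rendering cost.

#' Scaled study design for the detection harness
#'
#' The earliest and latest ages, 4 animals per genotype x age cell (8
#' hemisphere samples per group -- the smallest size at which the exact
#' Mann-Whitney test can cross the 0.005 per-test threshold), both levels,
#' on 140 x 200 px sections at 10 um/px with a 48 px rolling ball.
#'
#' @param seed cohort seed.
#' @param n_per_cell animals per genotype x age cell.
#' @return list with \code{design}, \code{effects}, \code{config},
#'   \code{shape}, \code{pixel_size}.
#' @export
harness_setup <- function(seed = 1L, n_per_cell = 4) {
  list(design = cohort_design(ages = c(3, 19), n_per_cell = n_per_cell,
                              seed = seed),
       effects = effect_model(),
       config = run_config(rolling_ball_radius = 48, median_radius = NULL),
       shape = c(140, 200), pixel_size = 10)
}

#' Check the qualitative effect pattern in a comparison table
#'
#' The three elements of the programmed progression:
#' \enumerate{
#'   \item rostral, earliest age: the dorsolateral striosome-intensity
#'     comparison is flagged while no rostral matrix-intensity comparison is;
#'   \item matrix effect only late: a rostral matrix-intensity comparison is
#'     flagged at the latest age and none at the earliest;
#'   \item caudal: the whole-caudoputamen striosome \%area and total-intensity
#'     comparisons are flagged at every age.
#' }
#'
#' @param comparisons output of \code{\link{run_cascade}}.
#' @param age_early,age_late the two ages in the design.
#' @return named logical vector with the three elements and \code{all}.
#' @export
check_effect_pattern <- function(comparisons, age_early = 3, age_late = 19) {
  flagged <- function(metric, level, age, sector = NULL) {
    sel <- comparisons$metric == metric & comparisons$level == level &
      comparisons$age_months == age
    if (!is.null(sector)) sel <- sel & comparisons$sector == sector
    any(comparisons$significant[sel])
  }
  dl_strio_early <- flagged("strio_intensity", "rostral", age_early,
                            "dorsolateral")
  matrix_quiet_early <- !flagged("matrix_intensity", "rostral", age_early)
  matrix_late <- flagged("matrix_intensity", "rostral", age_late)
  caudal_all_ages <- all(vapply(c(age_early, age_late), function(a)
    flagged("percent_area", "caudal", a, "whole") &&
      flagged("total_intensity", "caudal", a, "whole"), TRUE))
  out <- c(strio_dl_early = dl_strio_early && matrix_quiet_early,
           matrix_late_only = matrix_late && matrix_quiet_early,
           caudal_all_ages = caudal_all_ages)
  c(out, all = all(out))
}

#' Pipeline-level effect detection rate
#'
#' Generates \code{n_rep} replicate cohorts under the programmed effect
#' model, runs the full image pipeline and comparison cascade on each, and
#' reports the fraction of replicates reproducing the full qualitative
#' pattern (see \code{\link{check_effect_pattern}}).
#'
#' @param n_rep number of replicate cohorts.
#' @param seed master seed.
#' @param n_per_cell animals per genotype x age cell.
#' @return list with \code{rate}, per-element rates, and \code{n_rep}.
#' @export
effect_detection_rate <- function(n_rep = 100, seed = 1L, n_per_cell = 4) {
  seeds <- derive_seeds(seed, n_rep)
  hits <- matrix(NA, n_rep, 4,
                 dimnames = list(NULL, c("strio_dl_early", "matrix_late_only",
                                         "caudal_all_ages", "all")))
  for (r in seq_len(n_rep)) {
    hs <- harness_setup(seed = seeds[r], n_per_cell = n_per_cell)
    cohort <- generate_cohort(hs$design, hs$effects, hs$shape, hs$pixel_size)
    run <- run_pipeline(cohort, hs$config)
    hits[r, ] <- check_effect_pattern(run$comparisons)
  }
  rates <- colMeans(hits)
  list(rate = unname(rates["all"]), element_rates = rates, n_rep = n_rep)
}

#' Simulate a metrics table under the generator's statistical model
#'
#' Draws per-region metric values directly from the cohort variance
#' structure (per-animal and per-hemisphere intercepts plus measurement
#' noise) without rendering images. With \code{null = TRUE} all genotype
#' effects are zeroed, giving the null distribution of the cascade's inputs.
#'
#' @param design a \code{\link{cohort_design}}.
#' @param effects an \code{\link{effect_model}}.
#' @param seed integer seed.
#' @param null zero out all genotype effects.
#' @param measurement_sd SD of residual per-region measurement error on mean
#'   intensities (gray levels).
#' @return metrics data.frame consumable by \code{\link{run_cascade}}.
#' @export
simulate_metrics_table <- function(design, effects = effect_model(),
                                   seed = 1L, null = FALSE,
                                   measurement_sd = 0.3) {
  if (null)
    effects <- utils::modifyList(effects, list(
      strio_effect = 0, matrix_effect = 0,
      caudal_mut_striosome_gain = effects$caudal_wt_striosome_gain,
      density_rostral_mut_19 = effects$density_rostral,
      density_caudal_mut = effects$density_caudal_wt))
  class(effects) <- "effect_model"
  with_seed(seed, {
    rows <- list()
    cells <- expand.grid(genotype = design$genotypes, age = design$ages,
                         idx = seq_len(design$n_per_cell),
                         stringsAsFactors = FALSE)
    for (ai in seq_len(nrow(cells))) {
      genotype <- cells$genotype[ai]; age <- cells$age[ai]
      a_int <- stats::rnorm(2, 0, effects$animal_sd)  # strio, matrix
      for (lv in design$levels) {
        base <- resolve_intensities(effects, genotype, age, lv)
        dens <- pattern_density(effects, genotype, age, lv)
        secs <- if (lv == "caudal") "whole" else c("whole", sector_names)
        for (h in c("left", "right")[seq_len(design$hemispheres_per_animal)]) {
          s_int <- stats::rnorm(2, 0, effects$section_sd)
          for (sec in secs) {
            bsec <- if (sec == "whole") sector_names else sec
            si <- mean(base$strio[bsec]) + a_int[1] + s_int[1] +
              stats::rnorm(1, 0, measurement_sd)
            mi <- mean(base$matrix[bsec]) + a_int[2] + s_int[2] +
              stats::rnorm(1, 0, measurement_sd)
            pa <- clamp(dens + stats::rnorm(1, 0, 0.01), 0, 1)
            rows[[length(rows) + 1L]] <- data.frame(
              animal_id = sprintf("%s_a%02d_%02d", genotype, age, cells$idx[ai]),
              genotype = genotype, age_months = age, level = lv,
              hemisphere = h, sector = sec,
              percent_area = pa, strio_intensity = si, matrix_intensity = mi,
              ismp = ismp(si, mi), total_intensity = si * pa,
              valid = TRUE, stringsAsFactors = FALSE)
          }
        }
      }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}

#' Type-I flag rate of the cascade under the null
#'
#' Simulates \code{n_cohorts} null cohorts at the metrics level, runs the
#' cascade on each, and reports the fraction of pairwise comparisons flagged
#' significant (adjusted p below alpha), with its Monte-Carlo standard error.
#'
#' @param n_cohorts number of replicate null cohorts.
#' @param seed master seed.
#' @param design cohort design for each replicate.
#' @param plan a \code{\link{comparison_plan}}.
#' @return list with \code{rate}, \code{se}, \code{n_tests},
#'   \code{alpha}.
#' @export
null_flag_rate <- function(n_cohorts = 500, seed = 1L,
                           design = cohort_design(ages = c(3, 19),
                                                  n_per_cell = 4),
                           plan = comparison_plan()) {
  seeds <- derive_seeds(seed, n_cohorts)
  n_flag <- 0L; n_tests <- 0L
  for (r in seq_len(n_cohorts)) {
    tab <- simulate_metrics_table(design, seed = seeds[r], null = TRUE)
    cmp <- run_cascade(tab, plan)
    n_flag <- n_flag + sum(cmp$significant)
    n_tests <- n_tests + nrow(cmp)
  }
  rate <- n_flag / n_tests
  list(rate = rate, se = sqrt(rate * (1 - rate) / n_tests),
       n_tests = n_tests, alpha = plan$alpha)
}

#' Monotone power curve of the cascade
#'
#' Average count of flagged comparisons as a function of an effect-size
#' multiplier, at the metrics level.
#'
#' @param multipliers effect-size multipliers applied to the programmed
#'   striosome/matrix effects.
#' @param n_rep replicates per multiplier.
#' @param seed master seed.
#' @param design cohort design.
#' @return data.frame with \code{multiplier} and mean \code{n_flagged}.
#' @export
power_curve <- function(multipliers = c(0.5, 1, 2), n_rep = 50, seed = 1L,
                        design = cohort_design(ages = c(3, 19),
                                               n_per_cell = 4)) {
  base <- effect_model()
  seeds <- derive_seeds(seed, n_rep * length(multipliers))
  out <- data.frame(multiplier = multipliers, n_flagged = NA_real_)
  k <- 0L
  for (i in seq_along(multipliers)) {
    eff <- utils::modifyList(base, list(
      strio_effect = base$strio_effect * multipliers[i],
      matrix_effect = base$matrix_effect * multipliers[i]))
    class(eff) <- "effect_model"
    counts <- numeric(n_rep)
    for (r in seq_len(n_rep)) {
      k <- k + 1L
      tab <- simulate_metrics_table(design, eff, seed = seeds[k])
      cmp <- run_cascade(tab)
      counts[r] <- sum(cmp$significant)
    }
    out$n_flagged[i] <- mean(counts)
  }
  out
}
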