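# Inferential cascade: Kruskal-Wallis omnibus, pairwise Mann-Whitney U,
# Bonferroni correction. The rank tests are delegated to the standard
# implementations in the stats package; this module fixes the modes,
# two-sidedness, tie handling and family-size bookkeeping used throughout.

#' Kruskal-Wallis omnibus test
#'
#' Rank-based H with tie correction; p from the chi-square reference with
#' k - 1 degrees of freedom. When all pooled observations are identical the
#' test is degenerate and H = 0, p = 1 is returned.
#'
#' @param groups list of numeric samples (>= 2 groups, >= 3 observations in
#'   total, each group nonempty).
#' @return list with \code{H}, \code{df}, \code{p}, \code{n}.
#' @export
kruskal_wallis <- function(groups) {
  stopifnot(length(groups) >= 2, all(lengths(groups) >= 1))
  pooled <- unlist(groups, use.names = FALSE)
  stopifnot(length(pooled) >= 3)
  if (length(unique(pooled)) == 1)
    return(list(H = 0, df = length(groups) - 1L, p = 1, n = length(pooled)))
  g <- factor(rep(seq_along(groups), lengths(groups)))
  kt <- stats::kruskal.test(pooled, g)
  list(H = unname(kt$statistic), df = unname(kt$parameter),
       p = kt$p.value, n = length(pooled))
}

#' Mann-Whitney U test
#'
#' Two-sided throughout. In exact mode (the default whenever both samples
#' have at most 8 observations and the data are tie-free) the p-value comes
#' from the complete enumeration of rank assignments; otherwise the
#' tie-corrected normal approximation with continuity correction is used.
#' Requesting exact mode on tied data falls back to the normal approximation
#' with a notice recorded in the result.
#'
#' @param a,b numeric samples, both nonempty.
#' @param mode \code{"auto"}, \code{"exact"} or \code{"normal"}.
#' @param exact_max largest per-group size for which auto mode picks the
#'   exact test (default 8).
#' @return list with \code{U} (for sample \code{a}), \code{p},
#'   \code{mode_used}, \code{ties}, \code{n_a}, \code{n_b}, \code{note}.
#' @export
mann_whitney_u <- function(a, b, mode = c("auto", "exact", "normal"),
                           exact_max = 8) {
  mode <- match.arg(mode)
  stopifnot(length(a) >= 1, length(b) >= 1)
  ties <- anyDuplicated(c(a, b)) > 0
  note <- NA_character_
  use_exact <- switch(mode,
    auto = length(a) <= exact_max && length(b) <= exact_max && !ties,
    exact = TRUE,
    normal = FALSE)
  if (use_exact && ties) {
    use_exact <- FALSE
    note <- "exact mode refused: tied data; normal approximation used"
    message(note)
  }
  wt <- suppressWarnings(stats::wilcox.test(
    a, b, alternative = "two.sided", exact = use_exact, correct = TRUE))
  list(U = unname(wt$statistic), p = wt$p.value,
       mode_used = if (use_exact) "exact" else "normal",
       ties = ties, n_a = length(a), n_b = length(b), note = note)
}

#' Bonferroni adjustment with explicit family size
#'
#' Each adjusted p-value is \code{min(1, p * m)}. The default family size in
#' the analysis plan is 10 (five regions by two comparison structures per
#' metric panel), making the effective per-test threshold 0.005 at a
#' family-wise alpha of 0.05.
#'
#' @param p_values numeric vector of raw p-values.
#' @param m family size; must be at least the number of p-values and >= 1.
#' @return adjusted p-values.
#' @export
bonferroni_adjust <- function(p_values, m) {
  if (m < 1) stop("family size m must be >= 1")
  if (m < length(p_values)) stop("family size m smaller than number of tests")
  stats::p.adjust(p_values, method = "bonferroni", n = m)
}

#' Default comparison plan
#'
#' @param metrics metric columns to test.
#' @param group grouping column (default genotype).
#' @param alpha family-wise significance level.
#' @param family_m Bonferroni family size.
#' @param min_n minimum observations per group.
#' @return list describing the plan, for \code{\link{run_cascade}}.
#' @export
comparison_plan <- function(metrics = c("percent_area", "strio_intensity",
                                        "matrix_intensity", "ismp",
                                        "total_intensity"),
                            group = "genotype", alpha = 0.05, family_m = 10,
                            min_n = 2) {
  list(metrics = metrics, group = group, alpha = alpha, family_m = family_m,
       min_n = min_n)
}

#' Run the full group-comparison cascade
#'
#' For every panel cell (metric x level x age x sector) with at least two
#' groups: Kruskal-Wallis omnibus over the groups, then all pairwise
#' Mann-Whitney U tests, Bonferroni-adjusted with the plan's family size.
#' Pairwise tests are reported regardless of the omnibus outcome but carry a
#' flag when the omnibus is non-significant. Invalid metric records are
#' dropped; a planned comparison with a missing group is skipped with a
#' warning.
#'
#' @param metrics long-format metrics table with columns \code{level},
#'   \code{age_months}, \code{sector}, \code{valid}, the group column, and
#'   the metric columns named in the plan.
#' @param plan a \code{\link{comparison_plan}}.
#' @return data.frame, one row per pairwise comparison, with the omnibus H
#'   and p, U, raw and adjusted p, family size m, per-group sizes, tie and
#'   mode bookkeeping, and the significance flag at the adjusted alpha.
#' @export
run_cascade <- function(metrics, plan = comparison_plan()) {
  metrics <- metrics[metrics$valid, , drop = FALSE]
  panels <- unique(metrics[c("level", "age_months", "sector")])
  rows <- list()
  for (i in seq_len(nrow(panels))) {
    cell <- metrics[metrics$level == panels$level[i] &
                      metrics$age_months == panels$age_months[i] &
                      metrics$sector == panels$sector[i], , drop = FALSE]
    glab <- sort(unique(as.character(cell[[plan$group]])))
    for (metric in plan$metrics) {
      samples <- lapply(glab, function(g)
        cell[[metric]][cell[[plan$group]] == g])
      keep <- lengths(samples) >= plan$min_n
      if (sum(keep) < 2) {
        warning(sprintf("skipping %s / %s / age %s / %s: fewer than 2 groups",
                        metric, panels$level[i], panels$age_months[i],
                        panels$sector[i]), call. = FALSE)
        next
      }
      samples <- samples[keep]; labs <- glab[keep]
      kw <- kruskal_wallis(samples)
      prs <- utils::combn(seq_along(samples), 2)
      for (j in seq_len(ncol(prs))) {
        ia <- prs[1, j]; ib <- prs[2, j]
        mw <- mann_whitney_u(samples[[ia]], samples[[ib]])
        p_adj <- bonferroni_adjust(mw$p, plan$family_m)
        rows[[length(rows) + 1L]] <- data.frame(
          metric = metric, level = panels$level[i],
          age_months = panels$age_months[i], sector = panels$sector[i],
          group_a = labs[ia], group_b = labs[ib],
          n_a = mw$n_a, n_b = mw$n_b,
          H = kw$H, p_omnibus = kw$p,
          U = mw$U, p_raw = mw$p, p_adj = p_adj, m = plan$family_m,
          significant = p_adj < plan$alpha,
          omnibus_ns = kw$p >= plan$alpha,
          mode = mw$mode_used, ties = mw$ties,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) return(data.frame())
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
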