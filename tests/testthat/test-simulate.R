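outline_fixture <- function(seed = 5) {
  striodens:::with_seed(seed,
    striodens:::section_geometry(c(140, 200))$landmarks$cp_outline_left)
}

test_that("striosome patterns hit the target density and are reproducible", {
  outline <- outline_fixture()
  expect_equal(sum(generate_striosome_pattern(outline, "rostral", 0,
                                              seed = 1)), 0)
  inside <- matrix(point_in_polygon(rep(1:200, each = 140),
                                    rep(1:140, 200), outline), 140, 200)
  for (seed in c(1, 2, 3)) {
    pat <- generate_striosome_pattern(outline, "rostral", 0.15, seed = seed)
    frac <- sum(pat) / sum(inside)
    expect_gte(frac, 0.12); expect_lte(frac, 0.18)
    expect_true(all(pat[!inside] == FALSE))
  }
  expect_identical(generate_striosome_pattern(outline, "rostral", 0.15, seed = 4),
                   generate_striosome_pattern(outline, "rostral", 0.15, seed = 4))
  degenerate <- cbind(c(0, 0, 0), c(0, 0, 0))
  expect_error(generate_striosome_pattern(degenerate, "rostral", 0.1, seed = 1),
               "invalid geometry")
  expect_error(generate_striosome_pattern(outline, "rostral", 0.5, seed = 1))
})

test_that("blob placement is enriched toward the dorsal rim", {
  outline <- outline_fixture()
  fracs <- vapply(1:10, function(s) {
    pat <- generate_striosome_pattern(outline, "rostral", 0.15, seed = s)
    pts <- which(pat, arr.ind = TRUE)
    mean(pts[, 1])  # mean row of striosome pixels (smaller = more dorsal)
  }, numeric(1))
  inside <- which(matrix(point_in_polygon(rep(1:200, each = 140),
                                          rep(1:140, 200), outline),
                         140, 200), arr.ind = TRUE)
  expect_lt(mean(fracs), mean(inside[, 1]))  # dorsal of the outline centroid
})

test_that("noise-free rendering reproduces programmed values exactly", {
  sec <- make_test_section("MUT", 3, "rostral", seed = 2)
  truth <- sec$truth
  for (side in c("left", "right")) {
    for (s in striodens:::sector_names) {
      m <- truth$regions[[side]][[s]] & truth$striosome_mask
      if (!any(m)) next
      expect_true(all(sec$image$pixels[m] ==
                        round(truth$intensity[[side]]$strio[[s]])))
    }
  }
})

test_that("forced-null caudal wildtype compartments are indistinguishable", {
  sec <- make_test_section("WT", 6, "caudal", seed = 4, noise_sd = 5)
  m <- sec$truth$regions$left$whole
  strio <- sec$image$pixels[m & sec$truth$striosome_mask]
  matr <- sec$image$pixels[m & !sec$truth$striosome_mask &
                             !sec$truth$fiber_mask]
  expect_lt(abs(mean(strio) - mean(matr)),
            3 * 5 * sqrt(1 / length(strio) + 1 / length(matr)))
})

test_that("rendered compartment means match programmed values within 3 SE", {
  sec <- make_test_section("WT", 3, "rostral", seed = 7, noise_sd = 5)
  m <- sec$truth$regions$left$whole
  strio <- sec$image$pixels[m & sec$truth$striosome_mask]
  matr <- sec$image$pixels[m & !sec$truth$striosome_mask &
                             !sec$truth$fiber_mask]
  expect_lt(abs(mean(strio) - 180), 3 * 5 / sqrt(length(strio)) + 0.5)
  expect_lt(abs(mean(matr) - 120), 3 * 5 / sqrt(length(matr)) + 0.5)
})

test_that("cohort generation yields the designed sample counts and reproduces", {
  design <- cohort_design(genotypes = c("WT", "MUT"), ages = 3,
                          n_per_cell = 4, levels = c("rostral", "caudal"),
                          seed = 99)
  cohort <- generate_cohort(design)
  expect_length(cohort$sections, 8 * 2)  # 8 animals x 2 levels
  md <- cohort$metadata
  expect_equal(nrow(md[md$level == "rostral", ]), 16)  # 16 caudoputamen samples
  expect_equal(nrow(md[md$level == "caudal", ]), 16)
  expect_equal(length(unique(md$animal_id)), 8)

  expect_error(cohort_design(n_per_cell = 0), "design error")
  expect_error(cohort_design(ages = numeric()), "design error")

  cohort2 <- generate_cohort(design)
  expect_identical(cohort$metadata, cohort2$metadata)
  sid <- names(cohort$sections)[1]
  expect_identical(cohort$sections[[sid]]$image$pixels,
                   cohort2$sections[[sid]]$image$pixels)
  expect_identical(cohort$sections[[sid]]$truth$striosome_mask,
                   cohort2$sections[[sid]]$truth$striosome_mask)
})

test_that("stored ground-truth metrics match recomputation from the noise-free render", {
  sec <- make_test_section("MUT", 19, "rostral", seed = 6,
                           animal_sd = 0, section_sd = 0)
  tm <- true_metrics(sec$truth)
  truth <- sec$truth
  img <- sec$image$pixels
  for (i in seq_len(nrow(tm))) {
    side <- tm$hemisphere[i]; s <- tm$sector[i]
    m <- truth$regions[[side]][[s]]
    strio <- m & truth$striosome_mask
    matr <- m & !truth$striosome_mask & !truth$fiber_mask
    expect_equal(tm$strio_intensity[i], mean(img[strio]), tolerance = 1e-9)
    expect_equal(tm$matrix_intensity[i], mean(img[matr]), tolerance = 1e-9)
    expect_equal(tm$percent_area[i],
                 sum(strio) / (sum(m) - sum(m & truth$fiber_mask)),
                 tolerance = 1e-12)
  }
})

test_that("ground-truth masks respect the generator invariants", {
  for (seed in c(1, 8)) {
    sec <- make_test_section("MUT", 3, "rostral", seed = seed, noise_sd = 5)
    truth <- sec$truth
    expect_equal(sum(truth$striosome_mask & truth$fiber_mask), 0)
    whole <- truth$regions$left$whole | truth$regions$right$whole
    expect_true(all(whole[truth$striosome_mask]))
  }
})

test_that("null-effect cohorts center the true-mask ISMP on 1", {
  # identical striosome/matrix expectations, noise on; ISMP measured over
  # ground-truth masks across many sections
  eff <- effect_model(noise_sd = 5, shading_amplitude = 0,
                      animal_sd = 0, section_sd = 0,
                      caudal_wt_striosome_gain = 0)
  vals <- vapply(1:100, function(s) {
    truth <- striodens:::generate_section_truth("WT", 3, "caudal", eff, s)
    img <- render_section(truth, eff, s + 5000L)$image$pixels
    m <- truth$regions$left$whole
    strio <- m & truth$striosome_mask
    matr <- m & !truth$striosome_mask & !truth$fiber_mask
    mean(img[strio]) / mean(img[matr])
  }, numeric(1))
  se <- stats::sd(vals) / sqrt(length(vals))
  expect_lt(abs(mean(vals) - 1), 2 * se + 1e-4)
})
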