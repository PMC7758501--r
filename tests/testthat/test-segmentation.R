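test_that("Li threshold equals the exhaustive cross-entropy minimizer", {
  # two-level histogram: any split between the modes is optimal; the median
  # tie rule puts the threshold midway, strictly between the levels
  v2 <- c(rep(100, 500), rep(200, 500))
  thr <- li_threshold(v2)
  expect_gt(thr, 100); expect_lt(thr, 200)
  expect_equal(thr, li_oracle(v2))

  # bimodal Gaussian mixture
  set.seed(42)
  vb <- c(stats::rnorm(5e4, 80, 10), stats::rnorm(5e4, 180, 10))
  thr_b <- li_threshold(vb)
  expect_gte(thr_b, 110); expect_lte(thr_b, 150)
  expect_equal(thr_b, li_oracle(vb))

  # random 8-bit histograms
  set.seed(7)
  for (i in 1:40) {
    v <- sample(0:255, 3000, replace = TRUE,
                prob = stats::runif(256)^stats::runif(1, 0.5, 3))
    expect_equal(li_threshold(v), li_oracle(v))
  }
})

test_that("constant input is rejected as degenerate", {
  expect_error(li_threshold(rep(120, 100)), "degenerate")
  expect_error(segment_sector(matrix(7, 10, 10),
                              matrix(TRUE, 10, 10)), "degenerate")
})

test_that("noise-free synthetic sectors are segmented exactly", {
  sec <- make_test_section("WT", 3, "rostral", seed = 3)
  for (side in c("left", "right")) {
    for (s in striodens:::sector_names) {
      m <- sec$truth$regions[[side]][[s]]
      res <- segment_sector(sec$image, m)
      expect_identical(res$striosome_mask, sec$truth$striosome_mask & m)
      expect_identical(res$striosome_mask | res$matrix_mask, m)
    }
  }
})

test_that("noisy sectors recover ground truth with Jaccard >= 0.95", {
  sec <- make_test_section("MUT", 3, "rostral", seed = 5, noise_sd = 5)
  for (side in c("left", "right")) {
    for (s in striodens:::sector_names) {
      m <- sec$truth$regions[[side]][[s]]
      res <- segment_sector(sec$image, m)
      expect_gte(jaccard(res$striosome_mask, sec$truth$striosome_mask & m),
                 0.95)
    }
  }
})

test_that("forced-null caudal wildtype sections are flagged as unsegmentable", {
  # noise-free, zero striosome gain: the sector is constant-valued
  sec <- make_test_section("WT", 12, "caudal", seed = 8)
  m <- sec$truth$regions$left$whole
  expect_error(segment_sector(sec$image, m), "degenerate")
})

test_that("fiber threshold applies the truncated-mean rule", {
  img <- matrix(0, 40, 40)
  img[1:10, 1:10] <- 40.6   # first square region
  img[1:10, 21:30] <- 41.0  # second square region
  squares <- list(list(center = c(5, 5), side_um = 100),
                  list(center = c(25, 5), side_um = 100))
  expect_equal(fiber_threshold(img, squares, pixel_size = 10), 40L)
  zero <- matrix(0, 40, 40)
  expect_equal(fiber_threshold(zero, squares, pixel_size = 10), 0L)
  off <- list(list(center = c(38, 38), side_um = 100))
  expect_error(fiber_threshold(img, off, pixel_size = 10), "outside image")
})

test_that("fiber exclusion preserves the partition and is monotone", {
  sec <- make_test_section("MUT", 3, "rostral", seed = 9, noise_sd = 5)
  m <- sec$truth$regions$right$whole
  res <- segment_sector(sec$image, m)

  r0 <- apply_fiber_exclusion(res, sec$image, 0)
  expect_identical(r0$striosome_mask, res$striosome_mask)  # all values >= 1
  expect_equal(sum(r0$excluded_mask), 0)

  prev <- 0
  for (th in c(20, 40, 60, 120)) {
    rt <- apply_fiber_exclusion(res, sec$image, th)
    expect_identical(rt$striosome_mask | rt$matrix_mask | rt$excluded_mask, m)
    expect_gte(sum(rt$excluded_mask), prev)
    prev <- sum(rt$excluded_mask)
  }

  rmax <- apply_fiber_exclusion(res, sec$image, max(sec$image$pixels))
  expect_equal(sum(rmax$striosome_mask) + sum(rmax$matrix_mask), 0)
  expect_false(region_metrics(sec$image, rmax)$valid)
})

test_that("control-square exclusion recovers the fiber mask", {
  sec <- make_test_section("MUT", 3, "rostral", seed = 10, noise_sd = 5)
  fth <- fiber_threshold(sec$image, sec$landmarks$fiber_control_squares)
  for (side in c("left", "right")) {
    m <- sec$truth$regions[[side]]$whole
    res <- apply_fiber_exclusion(segment_sector(sec$image, m), sec$image, fth)
    expect_gte(jaccard(res$excluded_mask, sec$truth$fiber_mask & m), 0.9)
  }
})

test_that("excluding a dim fiber streak raises compartment mean intensities", {
  sec <- make_test_section("WT", 3, "rostral", seed = 12, noise_sd = 5)
  img <- sec$image
  m <- sec$truth$regions$left$dorsolateral
  pts <- which(m, arr.ind = TRUE)
  ctr <- colMeans(pts)
  streak <- striodens:::streak_mask(dim(img$pixels),
                                    rev(ctr) + c(-12, 0), rev(ctr) + c(12, 0),
                                    width = 1.2) & m
  img$pixels[streak] <- round(stats::rnorm(sum(streak), 30, 5))
  res <- segment_sector(img, m)
  before <- region_metrics(img, res)
  after <- region_metrics(img, apply_fiber_exclusion(res, img, 40))
  expect_gt(after$matrix_intensity, before$matrix_intensity)
})
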