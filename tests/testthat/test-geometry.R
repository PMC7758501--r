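shape <- c(140, 200)

random_landmarks <- function(seed) {
  striodens:::with_seed(seed, striodens:::section_geometry(shape)$landmarks)
}

test_that("the four sectors exactly partition the whole caudoputamen", {
  for (seed in c(1, 2, 3, 4, 5)) {
    rs <- construct_sectors(random_landmarks(seed), shape)
    for (h in c("left", "right")) {
      secs <- lapply(striodens:::sector_names, function(s) rs[[h]][[s]])
      counts <- vapply(secs, sum, 0L)
      expect_true(all(counts > 0))
      expect_equal(sum(counts), sum(rs[[h]]$whole))
      expect_equal(Reduce(`|`, secs), rs[[h]]$whole)
      expect_equal(sum(Reduce(`+`, lapply(secs, `+`, 0L)) > 1), 0)  # disjoint
    }
  }
})

test_that("sector construction is deterministic", {
  lm <- random_landmarks(7)
  expect_identical(construct_sectors(lm, shape), construct_sectors(lm, shape))
})

test_that("rectangular outline with symmetric landmarks matches analytic face areas", {
  big <- c(840, 1280)
  rect <- function(x0, x1, y0, y1)
    cbind(c(x0, x1, x1, x0), c(y0, y0, y1, y1))
  left <- rect(80, 560, 200, 680)
  right <- rect(720, 1200, 200, 680)
  lm <- landmark_set(
    cp_outline_left = left, cp_outline_right = right,
    ac_lateral_tip_left = c(220, 800), ac_lateral_tip_right = c(1060, 800),
    nacc_shell_upper_tip_left = c(559, 580),
    nacc_shell_upper_tip_right = c(721, 580))
  rs <- construct_sectors(lm, big)
  # analytic faces: clip each rectangle by its divider lines and shoelace
  for (h in c("left", "right")) {
    poly <- if (h == "left") left else right
    l5 <- rs[[h]]$lines$line5; l6 <- rs[[h]]$lines$line6
    dorsal_ref <- poly[which.min(poly[, 2]), ]
    medial_ref <- if (h == "left") c(560, 440) else c(720, 440)
    sgn <- function(line, q) sign(line$d[1] * (q[2] - line$p[2]) -
                                    line$d[2] * (q[1] - line$p[1]))
    s5 <- sgn(l5, dorsal_ref); s6 <- sgn(l6, medial_ref)
    combos <- list(dorsomedial = c(s5, s6), dorsolateral = c(s5, -s6),
                   ventromedial = c(-s5, s6), ventrolateral = c(-s5, -s6))
    for (nm in names(combos)) {
      face <- clip_halfplane(poly, l5$p, l5$d, combos[[nm]][1])
      face <- clip_halfplane(face, l6$p, l6$d, combos[[nm]][2])
      analytic <- shoelace(face)
      measured <- sum(rs[[h]][[nm]])
      expect_lt(abs(measured - analytic) / analytic, 0.01)
    }
  }
})

test_that("mirroring all landmarks mirrors the sector masks", {
  lm <- random_landmarks(12)
  nc <- shape[2]
  flipx <- function(p) { p[1] <- nc + 1 - p[1]; p }
  flippoly <- function(m) { m[, 1] <- nc + 1 - m[, 1]; m }
  lm2 <- landmark_set(
    cp_outline_left = flippoly(lm$cp_outline_right),
    cp_outline_right = flippoly(lm$cp_outline_left),
    ac_lateral_tip_left = flipx(lm$ac_lateral_tip_right),
    ac_lateral_tip_right = flipx(lm$ac_lateral_tip_left),
    nacc_shell_upper_tip_left = flipx(lm$nacc_shell_upper_tip_right),
    nacc_shell_upper_tip_right = flipx(lm$nacc_shell_upper_tip_left))
  rs <- construct_sectors(lm, shape)
  rs2 <- construct_sectors(lm2, shape)
  for (s in c("whole", striodens:::sector_names)) {
    a <- rs$left[[s]]
    b <- rs2$right[[s]][, rev(seq_len(nc))]
    expect_lt(sum(xor(a, b)) / max(1, sum(a)), 0.005)
  }
})

test_that("translating landmarks and image together translates the masks", {
  lm <- random_landmarks(4)
  dx <- 6; dy <- -4
  shift_pt <- function(p) p + c(dx, dy)
  shift_poly <- function(m) sweep(m, 2, c(dx, dy), `+`)
  lm2 <- landmark_set(
    cp_outline_left = shift_poly(lm$cp_outline_left),
    cp_outline_right = shift_poly(lm$cp_outline_right),
    ac_lateral_tip_left = shift_pt(lm$ac_lateral_tip_left),
    ac_lateral_tip_right = shift_pt(lm$ac_lateral_tip_right),
    nacc_shell_upper_tip_left = shift_pt(lm$nacc_shell_upper_tip_left),
    nacc_shell_upper_tip_right = shift_pt(lm$nacc_shell_upper_tip_right))
  rs <- construct_sectors(lm, shape)
  rs2 <- construct_sectors(lm2, shape)
  ys <- (1 - dy):shape[1]; xs <- 1:(shape[2] - dx)
  for (s in c("whole", striodens:::sector_names)) {
    a <- rs2$left[[s]][ys + dy, xs + dx]
    b <- rs$left[[s]][ys, xs]
    # equivariant up to rasterization at the divider lines
    expect_lt(sum(xor(a, b)) / max(1, sum(b)), 0.005)
  }
})

test_that("missing landmarks raise errors naming the landmark", {
  lm <- random_landmarks(2)
  lm$ac_lateral_tip_left <- NULL
  expect_error(construct_sectors(lm, shape), "ac_lateral_tip_left")
  lm2 <- random_landmarks(2)
  lm2$cp_outline_right <- NULL
  expect_error(construct_sectors(lm2, shape), "cp_outline_right")
})

test_that("landmark validation reports missing points, crossings and overlaps", {
  lm <- random_landmarks(3)
  expect_length(validate_landmarks(lm, pixel_size = 10), 0)

  lm_missing <- lm
  lm_missing$nacc_shell_upper_tip_left <- NULL
  expect_match(validate_landmarks(lm_missing, 10), "missing landmark",
               all = FALSE)

  bowtie <- cbind(c(10, 40, 40, 10), c(10, 40, 10, 40))
  lm_cross <- lm
  lm_cross$cp_outline_left <- bowtie
  expect_match(validate_landmarks(lm_cross, 10), "self-intersection",
               all = FALSE)

  lm_overlap <- lm
  ctr <- colMeans(lm$cp_outline_left)
  lm_overlap$fiber_control_squares <- list(list(center = ctr, side_um = 50))
  expect_match(validate_landmarks(lm_overlap, 10), "overlaps", all = FALSE)
})

test_that("landmark JSON round-trips exactly", {
  lm <- random_landmarks(6)
  path <- tempfile(fileext = ".json")
  on.exit(unlink(path))
  write_landmarks(lm, path)
  lm2 <- read_landmarks(path)
  expect_equal(lm2$cp_outline_left, lm$cp_outline_left)
  expect_equal(lm2$ac_lateral_tip_right, lm$ac_lateral_tip_right)
  expect_equal(length(lm2$fiber_control_squares),
               length(lm$fiber_control_squares))
  expect_equal(lm2$fiber_control_squares[[1]]$center,
               as.numeric(lm$fiber_control_squares[[1]]$center))
})
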