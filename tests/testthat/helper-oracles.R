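# Independent oracles used across the suite. Each reimplements the checked
# quantity from first principles, by a different route than the package.

# Naive minimum cross-entropy threshold: per-candidate direct sums over the
# binned histogram, median of tied minimizers (ties detected with a relative
# tolerance since equal partitions must agree only up to float noise).
li_oracle <- function(values, n_bins = 256) {
  rng <- range(values)
  width <- (rng[2] - rng[1]) / n_bins
  bin <- pmin(floor((values - rng[1]) / width) + 1L, n_bins)
  h <- tabulate(bin, nbins = n_bins)
  mids <- rng[1] + (seq_len(n_bins) - 0.5) * width
  eta <- rep(Inf, n_bins - 1)
  for (k in seq_len(n_bins - 1)) {
    lo <- seq_len(k); hi <- seq.int(k + 1, n_bins)
    n1 <- sum(h[lo]); n2 <- sum(h[hi])
    if (n1 == 0 || n2 == 0) next
    a1 <- sum(h[lo] * mids[lo]); a2 <- sum(h[hi] * mids[hi])
    t1 <- if (a1 > 0) -a1 * log(a1 / n1) else 0
    t2 <- if (a2 > 0) -a2 * log(a2 / n2) else 0
    eta[k] <- t1 + t2
  }
  lowest <- min(eta)
  winners <- which(eta <= lowest + abs(lowest) * 1e-12)
  kstar <- winners[ceiling(length(winners) / 2)]
  as.integer(round(rng[1] + kstar * width))
}

# Brute-force grayscale opening by a hemispherical element: for every pixel,
# min/max over explicitly enumerated in-bounds neighbours.
ball_opening_oracle <- function(x, radius) {
  r <- floor(radius)
  offs <- expand.grid(di = -r:r, dj = -r:r)
  offs <- offs[offs$di^2 + offs$dj^2 <= radius^2, ]
  hgt <- sqrt(radius^2 - offs$di^2 - offs$dj^2)
  nr <- nrow(x); nc <- ncol(x)
  pass <- function(img, erode) {
    out <- matrix(NA_real_, nr, nc)
    for (j in seq_len(nc)) for (i in seq_len(nr)) {
      ii <- i + offs$di; jj <- j + offs$dj
      ok <- ii >= 1 & ii <= nr & jj >= 1 & jj <= nc
      v <- img[cbind(ii[ok], jj[ok])]
      out[i, j] <- if (erode) min(v - hgt[ok]) else max(v + hgt[ok])
    }
    out
  }
  pass(pass(x, TRUE), FALSE)
}

# Per-pixel sort-and-middle median over a Euclidean disk, edge replication.
median_oracle <- function(x, radius) {
  r <- floor(radius)
  offs <- expand.grid(di = -r:r, dj = -r:r)
  offs <- offs[offs$di^2 + offs$dj^2 <= radius^2, ]
  nr <- nrow(x); nc <- ncol(x)
  out <- matrix(NA_real_, nr, nc)
  for (j in seq_len(nc)) for (i in seq_len(nr)) {
    ii <- pmin(pmax(i + offs$di, 1L), nr)
    jj <- pmin(pmax(j + offs$dj, 1L), nc)
    out[i, j] <- stats::median(x[cbind(ii, jj)])
  }
  out
}

# Exact two-sided Mann-Whitney p by complete enumeration of group
# assignments (no ties assumed).
mw_exact_oracle <- function(a, b) {
  pooled <- c(a, b)
  n <- length(pooled); na <- length(a)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  idx <- utils::combn(n, na)
  us <- apply(idx, 2, function(sel) sum(rank(pooled)[sel]) - na * (na + 1) / 2)
  p_le <- mean(us <= u_obs)
  p_ge <- mean(us >= u_obs)
  list(U = u_obs, p = min(1, 2 * min(p_le, p_ge)))
}

jaccard <- function(a, b) {
  u <- sum(a | b)
  if (u == 0) return(NA_real_)
  sum(a & b) / u
}

# Clip a convex-ish polygon against the half-plane on the `keep` side of the
# line through p with direction d (Sutherland-Hodgman), for the analytic
# sector-area oracle.
clip_halfplane <- function(poly, p, d, keep_sign) {
  side <- function(q) sign(d[1] * (q[2] - p[2]) - d[2] * (q[1] - p[1]))
  out <- NULL
  n <- nrow(poly)
  for (i in seq_len(n)) {
    cur <- poly[i, ]; prv <- poly[if (i == 1) n else i - 1, ]
    sc <- side(cur) * keep_sign; sp <- side(prv) * keep_sign
    if (sp >= 0 && sc >= 0) out <- rbind(out, cur)
    else if (sp >= 0 || sc >= 0) {
      e <- cur - prv
      denom <- d[1] * e[2] - d[2] * e[1]
      t <- ((prv[1] - p[1]) * d[2] - (prv[2] - p[2]) * d[1]) / denom
      inter <- prv + t * e
      out <- rbind(out, inter)
      if (sc >= 0) out <- rbind(out, cur)
    }
  }
  out
}

shoelace <- function(poly) {
  n <- nrow(poly)
  j <- c(n, seq_len(n - 1))
  abs(sum(poly[, 1] * poly[j, 2] - poly[j, 1] * poly[, 2])) / 2
}

# Rendered synthetic section with controllable noise, for segmentation and
# metric tests.
make_test_section <- function(genotype = "WT", age = 3, level = "rostral",
                              seed = 1, noise_sd = 0, shading = 0,
                              animal_sd = 0, section_sd = 0, ...) {
  eff <- effect_model(noise_sd = noise_sd, shading_amplitude = shading,
                      animal_sd = animal_sd, section_sd = section_sd, ...)
  truth <- striodens:::generate_section_truth(genotype, age, level, eff, seed)
  sec <- render_section(truth, eff, seed + 1000L)
  sec$effects <- eff
  sec
}
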