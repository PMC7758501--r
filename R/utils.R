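# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Derive reproducible sub-seeds (< 2^31) from a master seed.
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n, replace = FALSE))
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Separable Gaussian blur with edge replication, implemented as two
# band-matrix products. Small images only; used by the synthetic generator.
gaussian_blur <- function(x, sigma) {
  if (sigma <= 0) return(x)
  k1 <- function(n) {
    half <- max(1L, as.integer(ceiling(3 * sigma)))
    w <- stats::dnorm(-half:half, sd = sigma)
    w <- w / sum(w)
    m <- matrix(0, n, n)
    for (d in -half:half) {
      idx <- seq_len(n)
      src <- clamp(idx + d, 1L, n)  # edge replication
      m[cbind(idx, src)] <- m[cbind(idx, src)] + w[d + half + 1L]
    }
    m
  }
  k1(nrow(x)) %*% x %*% t(k1(ncol(x)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
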