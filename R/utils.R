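# internal helpers shared across modules

# Evaluate `expr` with the RNG seeded to `seed`, restoring the caller's RNG
# state afterwards, so every generator is a pure function of (config, seed).
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1 || !is.finite(seed)) {
    stop("seed must be a single finite number")
  }
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Spatially smooth standard-normal-ish random field on an nx x ny grid:
# white noise convolved with a separable Gaussian kernel (sd `scale` cells),
# re-standardised to unit marginal variance.
smooth_field <- function(nx, ny, scale = 4) {
  w <- matrix(stats::rnorm(nx * ny), nx, ny)
  if (scale <= 0) return(w)
  k1 <- function(n) {
    d <- outer(seq_len(n), seq_len(n), function(a, b) (a - b)^2)
    exp(-d / (2 * scale^2))
  }
  f <- k1(nx) %*% w %*% k1(ny)
  f <- f - mean(f)
  s <- stats::sd(as.vector(f))
  if (s > 0) f <- f / s
  f
}

# clamp to [lo, hi]
clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# day-of-year -> Date within scenario year
doy_date <- function(year, doy) as.Date(sprintf("%d-01-01", year)) + (doy - 1)

`%||%` <- function(a, b) if (is.null(a)) b else a
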