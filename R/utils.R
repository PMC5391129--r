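# Internal helpers: seeded evaluation, stable hashing, truncated normals.

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards so library code never perturbs user
# randomness.
local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  expr
}

# Deterministic 31-bit hash of a string combined with a master seed.
# Used to derive per-cell RNG streams from lineage identifiers, so that a
# cell's private randomness does not depend on how many other cells exist.
stable_hash <- function(id, seed = 0L) {
  h <- as.double(seed %% 2147483647)
  for (code in utf8ToInt(as.character(id))) {
    h <- (h * 31 + code) %% 2147483647
  }
  as.integer(h)
}

# One draw from a normal truncated to [lo, hi] (rejection with qnorm
# fallback for tight bounds). sd = 0 returns the clamped mean.
rtruncnorm1 <- function(mean, sd, lo = 0, hi = 1) {
  if (sd <= 0) return(min(max(mean, lo), hi))
  for (i in 1:50) {
    x <- rnorm(1, mean, sd)
    if (x >= lo && x <= hi) return(x)
  }
  # inverse-cdf fallback, exact for arbitrarily tight truncation
  p <- runif(1, stats::pnorm(lo, mean, sd), stats::pnorm(hi, mean, sd))
  qnorm(p, mean, sd)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)
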