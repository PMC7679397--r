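# Shared internal helpers: z-scoring conventions, clipped Fisher transforms,
# and the lower-triangle <-> square-matrix mapping used by every similarity
# routine.  The triangle traversal is R's native column-major `lower.tri()`
# order; all similarity vectors in the package share it.

# Correlations are clipped to +/- (1 - .r_clip_eps) before arctanh so that
# perfectly correlated inputs stay finite.
.r_clip_eps <- 1e-7

.clip_r <- function(r) pmin(pmax(r, -1 + .r_clip_eps), 1 - .r_clip_eps)

.fisher_z <- function(r) atanh(.clip_r(r))

# Population-SD z-score (divide by sqrt(mean squared deviation)).  `sd_type`
# switches to the sample convention where a caller exposes the choice.
.zscore <- function(x, sd_type = "population") {
  mu <- mean(x)
  s <- if (sd_type == "population") {
    sqrt(mean((x - mu)^2))
  } else {
    stats::sd(x)
  }
  if (!is.finite(s) || s == 0) {
    return(rep(0, length(x)))
  }
  (x - mu) / s
}

.zscore_cols <- function(m, sd_type = "population") {
  apply(m, 2L, .zscore, sd_type = sd_type)
}

# Number of scenarios implied by a similarity-vector length L = S(S-1)/2.
.n_from_tri <- function(len) {
  s <- (1 + sqrt(1 + 8 * len)) / 2
  if (abs(s - round(s)) > 1e-9) {
    stop("length ", len, " is not a valid lower-triangle size S(S-1)/2")
  }
  as.integer(round(s))
}

# Lower triangle (column-major, excluding diagonal) of a square matrix.
.tri_vec <- function(m) m[lower.tri(m)]

# Inverse: place a similarity vector back into a symmetric S x S matrix.
# The diagonal is NA; it never re-enters any triangle extraction because
# simultaneous row/column permutation maps the diagonal onto itself.
.tri_mat <- function(v, n = .n_from_tri(length(v))) {
  m <- matrix(NA_real_, n, n)
  m[lower.tri(m)] <- v
  m[upper.tri(m)] <- t(m)[upper.tri(m)]
  m
}

# Evaluate `expr` under `seed` when given, leaving the caller's RNG state
# untouched; with seed = NULL the current RNG stream is used directly.
.with_seed <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(seed, expr)
}

.is_count <- function(x, min = 1L) {
  length(x) == 1L && is.numeric(x) && is.finite(x) && x >= min &&
    abs(x - round(x)) < 1e-9
}
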