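# Internal helpers shared across modules.

# Round half away from zero (printed tables use half-up, not banker's).
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Moment-based sample skewness (g1). Returns 0 for degenerate input.
sample_skewness <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 3L) return(0)
  m <- mean(x)
  s2 <- mean((x - m)^2)
  if (s2 <= 0) return(0)
  mean((x - m)^3) / s2^1.5
}

# Deterministic per-stage seed derived from a master seed; keeps every
# value inside 32-bit integer range.
derive_seed <- function(master, stage) {
  m <- as.numeric(master) %% 1000003
  as.integer((m * 2011 + as.numeric(stage) * 7919) %% 2147483647 + 1)
}

# Row-wise log-sum-exp of a matrix, vectorised over columns.
row_logsumexp <- function(m) {
  mx <- m[, 1L]
  k <- ncol(m)
  if (k > 1L) for (j in 2:k) mx <- pmax(mx, m[, j])
  mx + log(rowSums(exp(m - mx)))
}

assert_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  invisible(x)
}
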