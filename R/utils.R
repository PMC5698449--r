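# Internal helpers shared across modules.

# Run `code` under a fixed RNG seed without disturbing the caller's stream.
with_rng <- function(seed, code) {
  withr::with_seed(seed, code)
}

# Truncated-normal draws: mass outside mean +/- 3 SD is excluded by inverse-CDF
# sampling, and values are floored at `floor` (pixel quantities cannot vanish).
rtruncnorm3 <- function(n, mean, sd, floor = 1) {
  lo <- pnorm(-3)
  hi <- pnorm(3)
  x <- qnorm(runif(n, lo, hi)) * sd + mean
  pmax(x, floor)
}

#' @importFrom stats pnorm
NULL

# Half-up rounding (round() is banker's).
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

stopifnot_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
}
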