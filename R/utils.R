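# Internal numerical helpers.

# Solve trigamma(y) = x for y > 0 by Newton iteration on a convexified scale.
# Used when moment-matching the scaled-inverse-chi-square prior of the
# moderated t-test. x must be positive; large x maps to small y.
trigammaInverse <- function(x) {
  stopifnot(all(is.finite(x)), all(x > 0))
  y <- 0.5 + 1 / x
  for (i in 1:75) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, deriv = 2L)
    y <- y + dif
    if (max(abs(dif) / y) < 1e-10) break
  }
  y
}

.checkCount <- function(x, name, min = 1L) {
  if (length(x) != 1L || !is.finite(x) || x != round(x) || x < min)
    stop(sprintf("%s must be a single integer >= %d", name, min))
  as.integer(x)
}

.checkFraction <- function(x, name, maxOpen = TRUE) {
  ok <- length(x) == 1L && is.finite(x) && x >= 0 && (if (maxOpen) x < 1 else x <= 1)
  if (!ok) stop(sprintf("%s must lie in [0, 1%s", name, if (maxOpen) ")" else "]"))
  as.numeric(x)
}

# Rank-based normal quantile scores used by the regulon-enrichment statistic:
# ascending ranks (average ties) mapped through the standard normal quantile.
.quantileScores <- function(v) {
  n <- length(v)
  stats::qnorm(rank(v, ties.method = "average") / (n + 1))
}

# Signed z-score from a two-sided p-value and the sign of the statistic.
.signedZ <- function(p, sgn) {
  p <- pmax(p, 1e-320)
  sgn * stats::qnorm(p / 2, lower.tail = FALSE)
}
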