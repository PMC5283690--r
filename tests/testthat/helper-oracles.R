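# Independent straight-line oracles used to validate the package's
# implementations. These deliberately avoid the package's own code paths.

# Moderated t derived step by step: pooled variances, moment-matched
# scaled-inverse-chi-square prior (trigamma inversion by uniroot), posterior
# variances, t statistics.
oracleModeratedT <- function(xRef, xCase) {
  n1 <- ncol(xRef); n2 <- ncol(xCase)
  dg <- n1 + n2 - 2
  m1 <- rowMeans(xRef); m2 <- rowMeans(xCase)
  s2 <- (rowSums((xRef - m1)^2) + rowSums((xCase - m2)^2)) / dg
  e <- log(s2) - digamma(dg / 2) + log(dg / 2)
  evar <- stats::var(e) - trigamma(dg / 2)
  if (is.finite(evar) && evar > 0) {
    half <- stats::uniroot(function(y) trigamma(y) - evar,
                           c(1e-8, 1e8), tol = 1e-14)$root
    d0 <- 2 * half
    s02 <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
    s2post <- (d0 * s02 + dg * s2) / (d0 + dg)
  } else {
    d0 <- Inf
    s2post <- rep(exp(mean(e)), length(s2))
  }
  t <- (m2 - m1) / sqrt(s2post * (1 / n1 + 1 / n2))
  list(t = t, d0 = d0)
}

# Classical partial correlation from the inverse correlation matrix.
oraclePartialCor <- function(X) {   # X: genes x samples
  R <- stats::cor(t(X))
  Om <- solve(R)
  P <- -stats::cov2cor(Om)
  diag(P) <- 1
  P
}

# k-group log-rank chi-square by direct summation over distinct event times.
oracleLogrank <- function(time, event, group) {
  group <- as.factor(group)
  k <- nlevels(group)
  O <- E <- rep(0, k)
  V <- matrix(0, k, k)
  for (t0 in sort(unique(time[event == 1]))) {
    atRisk <- time >= t0
    n <- sum(atRisk)
    d <- sum(time == t0 & event == 1)
    nj <- vapply(levels(group), function(g) sum(atRisk & group == g), numeric(1))
    dj <- vapply(levels(group), function(g)
      sum(time == t0 & event == 1 & group == g), numeric(1))
    O <- O + dj
    E <- E + d * nj / n
    if (n > 1)
      V <- V + d * (n - d) / (n - 1) * (diag(nj / n) - outer(nj / n, nj / n))
  }
  u <- (O - E)[-1]
  drop(t(u) %*% solve(V[-1, -1, drop = FALSE]) %*% u)
}

# Efron-ties Cox log partial likelihood for a single covariate.
oracleCoxLogLik <- function(beta, time, event, x) {
  ll <- 0
  for (t0 in unique(time[event == 1])) {
    D <- which(time == t0 & event == 1)
    R <- which(time >= t0)
    d <- length(D)
    ll <- ll + beta * sum(x[D])
    sR <- sum(exp(beta * x[R]))
    sD <- sum(exp(beta * x[D]))
    for (l in seq_len(d) - 1) ll <- ll - log(sR - (l / d) * sD)
  }
  ll
}
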