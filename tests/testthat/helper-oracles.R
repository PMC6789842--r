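# Independent oracles, deliberately written as plain direct-formula code
# (loops, closed forms) so they share no implementation path with the
# package functions they check.

options(wpcna.quiet = TRUE)

# biweight midcorrelation of one vector pair, straight from the definition
oracle_bicor <- function(x, y) {
  bw <- function(v) {
    med <- median(v)
    m <- median(abs(v - med))
    if (m == 0) return(v - mean(v))
    u <- (v - med) / (9 * m)
    w <- ifelse(abs(u) < 1, (1 - u^2)^2, 0)
    (v - med) * w
  }
  a <- bw(x); b <- bw(y)
  sum(a * b) / sqrt(sum(a^2) * sum(b^2))
}

# topological overlap by triple loop
oracle_tom <- function(A, denom = "mean") {
  n <- nrow(A)
  out <- diag(1, n)
  for (i in seq_len(n)) for (j in seq_len(n)) if (i != j) {
    l <- 0
    for (u in seq_len(n)) if (u != i && u != j) l <- l + A[i, u] * A[u, j]
    ki <- sum(A[i, -i]); kj <- sum(A[j, -j])
    D <- if (denom == "mean") (ki + kj) / 2 else min(ki, kj)
    out[i, j] <- (l + A[i, j]) / (D + 1 - A[i, j])
  }
  out
}

# hypergeometric upper tail by explicit enumeration of binomial coefficients
oracle_hyper_upper <- function(k, K, n, N) {
  js <- k:min(K, n)
  if (k > min(K, n)) return(0)
  sum(choose(K, js) * choose(N - K, n - js)) / choose(N, n)
}

# Benjamini-Hochberg step-up by hand
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  for (i in (m - 1):1) q[i] <- min(q[i], q[i + 1])
  out <- numeric(m)
  out[o] <- pmin(q, 1)
  out
}

# studentized-range CDF by direct numeric double integration:
# P(Q <= q) = int f_s(s) * k int phi(z) (Phi(z) - Phi(z - q s))^(k-1) dz ds
# with s = sqrt(chi^2_df / df)
oracle_ptukey_cdf <- function(q, k, df) {
  inner <- function(s) {
    vapply(s, function(si) {
      f <- function(z) k * dnorm(z) * (pnorm(z) - pnorm(z - q * si))^(k - 1)
      integrate(f, -8, 8, rel.tol = 1e-10)$value
    }, numeric(1))
  }
  dens <- function(s) exp((df / 2) * log(df) - lgamma(df / 2) -
                            (df / 2 - 1) * log(2) +
                            (df - 1) * log(s) - df * s^2 / 2)
  integrate(function(s) dens(s) * inner(s), 0, 5, rel.tol = 1e-8)$value
}

# Tukey-Kramer q statistics for all three pairs of a 3-group vector
oracle_qstats <- function(y, g) {
  ms <- tapply(y, g, mean)
  ns <- tabulate(g)
  mse <- sum((y - ms[g])^2) / (length(y) - length(ms))
  vapply(list(c(1, 2), c(1, 3), c(2, 3)), function(pr) {
    se <- sqrt(mse / 2 * (1 / ns[pr[1]] + 1 / ns[pr[2]]))
    abs(ms[pr[1]] - ms[pr[2]]) / se
  }, numeric(1))
}

adjusted_rand <- function(a, b) mclust::adjustedRandIndex(a, b)
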