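# Independent oracles used across the suite.

# Exhaustive dynamic-time-warping oracle: enumerates every monotone warping
# path (with branch-and-bound pruning) for short sequences.
brute_dtw <- function(A, B) {
  n <- nrow(A); m <- nrow(B)
  loc <- function(i, j) sqrt(sum((A[i, ] - B[j, ])^2))
  best <- Inf
  rec <- function(i, j, acc) {
    acc <- acc + loc(i, j)
    if (acc >= best) return(invisible())
    if (i == n && j == m) {
      best <<- min(best, acc)
      return(invisible())
    }
    if (i < n) rec(i + 1, j, acc)
    if (j < m) rec(i, j + 1, acc)
    if (i < n && j < m) rec(i + 1, j + 1, acc)
  }
  rec(1, 1, 0)
  best
}

# Restricted/unrestricted OLS route to the Granger F statistic, built on lm()
# rather than the package's own regression code.
granger_oracle <- function(x, y, m) {
  T <- length(y)
  idx <- (m + 1):T
  own <- sapply(1:m, function(i) y[idx - i])
  oth <- sapply(1:m, function(i) x[idx - i])
  fit_r <- stats::lm(y[idx] ~ own)
  fit_u <- stats::lm(y[idx] ~ own + oth)
  ssr_r <- sum(stats::resid(fit_r)^2)
  ssr_u <- sum(stats::resid(fit_u)^2)
  df2 <- length(idx) - (2 * m + 1)
  f <- ((ssr_r - ssr_u) / m) / (ssr_u / df2)
  list(f = f, p = stats::pf(f, m, df2, lower.tail = FALSE))
}

# Simulate a bivariate VAR(2) with oscillatory (complex-root) dynamics:
# persistent cycles that a fitted VAR forecasts far better than a
# last-value hold.
sim_var2_oscillatory <- function(T, sd = 0.3) {
  A1 <- matrix(c(1.4, 0.6, -0.6, 0.5), 2, 2, byrow = TRUE)
  A2 <- matrix(c(-0.7, -0.1, 0.3, -0.5), 2, 2, byrow = TRUE)
  Y <- matrix(0, T, 2)
  for (t in 3:T) Y[t, ] <- A1 %*% Y[t - 1, ] + A2 %*% Y[t - 2, ] + rnorm(2, 0, sd)
  colnames(Y) <- c("a", "b")
  Y
}

# A clearly class-separable cohort: the only systematic class difference is
# the opposite multiplicative sCD31 trend (no oxygenation confound).
separable_config <- function(seed, ...) {
  generator_config(seed = seed, acr_trend = 0.7, nonacr_trend = 1.3,
                   noise_sd = 0.03, pf_mean_acr = 350, pf_mean_nonacr = 350,
                   ...)
}
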