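# independent oracles used to freeze expected values

# OLS via R's QR fitter, independent of the package's normal-equations path
ols_oracle <- function(X, y, contrast) {
  fit <- stats::lm.fit(X, y)
  beta <- fit$coefficients
  df <- length(y) - ncol(X)
  s2 <- sum(fit$residuals^2) / df
  XtXi <- solve(crossprod(X))
  se <- sqrt(s2 * as.numeric(t(contrast) %*% XtXi %*% contrast))
  list(beta = as.numeric(contrast %*% beta), t = as.numeric(contrast %*% beta) / se)
}

# two-sided Fisher exact p by exhaustive enumeration of all tables with the
# observed margins, using only choose()
fisher_enum_oracle <- function(a, b, c_, d) {
  K <- a + c_; n_dec <- a + b; N <- a + b + c_ + d
  xs <- max(0L, n_dec - (N - K)):min(K, n_dec)
  pr <- choose(K, xs) * choose(N - K, n_dec - xs) / choose(N, n_dec)
  p_obs <- choose(K, a) * choose(N - K, n_dec - a) / choose(N, n_dec)
  sum(pr[pr <= p_obs * (1 + 1e-7)])
}

# analytic mean of a normal truncated to [lo, hi]
trunc_norm_mean <- function(mu, sigma, lo, hi) {
  a <- (lo - mu) / sigma; b <- (hi - mu) / sigma
  mu + sigma * (stats::dnorm(a) - stats::dnorm(b)) /
    (stats::pnorm(b) - stats::pnorm(a))
}

# per-group samples with exactly the requested mean and SD
exact_summary_sample <- function(n, mean, sd) {
  z <- stats::rnorm(n)
  z <- (z - base::mean(z)) / stats::sd(z)
  mean + sd * z
}
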