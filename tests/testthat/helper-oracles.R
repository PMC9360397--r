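# Independent oracles and fixture builders shared across the suite.

# brute-force OLS through the explicit normal equations (never via ols_fit)
oracle_ols <- function(x, y) {
  A <- cbind(1, x)
  coef <- solve(t(A) %*% A, t(A) %*% y)
  list(intercept = coef[1], slope = coef[2])
}

# central-difference numerical gradient of f at x
numerical_gradient <- function(f, x, h = 1e-6) {
  vapply(seq_along(x), function(i) {
    xp <- x; xp[i] <- xp[i] + h
    xm <- x; xm[i] <- xm[i] - h
    (f(xp) - f(xm)) / (2 * h)
  }, numeric(1))
}

# membership of (beta0, beta1) in the joint confidence region, computed via
# explicit residual sums of squares (independent of the X'X quadratic form):
# RSS(beta) - RSS(bhat) <= 2 s^2 F(1-alpha; 2, n-2)
oracle_ejcr_inside <- function(x, y, beta0, beta1, alpha = 0.05) {
  n <- length(x)
  co <- oracle_ols(x, y)
  rss_hat <- sum((y - co$intercept - co$slope * x)^2)
  rss_b <- sum((y - beta0 - beta1 * x)^2)
  s2 <- rss_hat / (n - 2)
  (rss_b - rss_hat) <= 2 * s2 * qf(1 - alpha, 2, n - 2)
}

# small study-sized synthetic sample table
make_sample_table <- function(n_animals = 10, seed = 42) {
  simulate_samples(generate_design(n_animals, seed = seed))
}

# predictor matrix of a sample table
table_X <- function(samples) {
  as.matrix(samples[, c("r_mean", "g_mean", "b_mean", "intensity")])
}
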