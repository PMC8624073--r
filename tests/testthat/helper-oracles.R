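# Independent brute-force oracles, deliberately written as plain loops so
# they share no code path with the implementation they check.

# Two-way sums-of-squares decomposition, cell by cell.
oracle_anova <- function(x) {
  x <- unclass(as.matrix(x))
  n <- nrow(x); k <- ncol(x); gm <- mean(x)
  ssr <- 0
  for (i in seq_len(n)) ssr <- ssr + k * (mean(x[i, ]) - gm)^2
  ssc <- 0
  for (j in seq_len(k)) ssc <- ssc + n * (mean(x[, j]) - gm)^2
  sse <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(k)) {
      sse <- sse + (x[i, j] - mean(x[i, ]) - mean(x[, j]) + gm)^2
    }
  }
  list(MSR = ssr / (n - 1), MSC = ssc / (k - 1),
       MSE = sse / ((n - 1) * (k - 1)), n = n, k = k)
}

oracle_icc_a1 <- function(x) {
  ms <- oracle_anova(x)
  (ms$MSR - ms$MSE) /
    (ms$MSR + (ms$k - 1) * ms$MSE + (ms$k / ms$n) * (ms$MSC - ms$MSE))
}

# REML log-likelihood of the random-intercept model at given variance
# components, via the full n x n covariance matrix.
oracle_reml_loglik <- function(y, X, id, s2b, s2e) {
  nn <- length(y)
  V <- diag(s2e, nn)
  for (g in unique(id)) {
    idx <- which(id == g)
    V[idx, idx] <- V[idx, idx] + s2b
  }
  Vi <- solve(V)
  XtViX <- t(X) %*% Vi %*% X
  beta <- solve(XtViX, t(X) %*% Vi %*% y)
  r <- y - X %*% beta
  as.numeric(
    -0.5 * (determinant(V, logarithm = TRUE)$modulus +
            determinant(XtViX, logarithm = TRUE)$modulus +
            t(r) %*% Vi %*% r +
            (nn - ncol(X)) * log(2 * pi))
  )
}

# Closed-form REML for balanced one-way data (n participants x k repeats,
# intercept-only): sigma_e^2 = MSW, sigma_b^2 = (MSB - MSW)/k truncated at 0.
oracle_oneway_reml <- function(x) {
  x <- unclass(as.matrix(x))
  n <- nrow(x); k <- ncol(x); gm <- mean(x)
  msb <- k * sum((rowMeans(x) - gm)^2) / (n - 1)
  msw <- sum((x - rowMeans(x))^2) / (n * (k - 1))
  list(sigma2_between = max((msb - msw) / k, 0), sigma2_residual = msw)
}

# Small simulated paired matrix with a participant effect.
random_reliable_pairs <- function(n, icc = 0.8, seed = 1) {
  set.seed(seed)
  b <- rnorm(n, 0, sqrt(icc))
  paired_matrix(cbind(b + rnorm(n, 0, sqrt(1 - icc)),
                      b + rnorm(n, 0, sqrt(1 - icc))))
}
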