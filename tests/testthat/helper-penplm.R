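# Shared helpers: brute-force univariate oracles for the thresholding
# operators and small random problem generators.

# Two-stage grid minimizer of (1/2)(z - b)^2 + pen(b).
grid_minimize <- function(z, pen) {
  lim <- abs(z) + 2
  b <- seq(-lim, lim, by = 1e-3)
  b0 <- b[which.min(0.5 * (z - b)^2 + pen(b))]
  b <- seq(b0 - 2e-3, b0 + 2e-3, by = 1e-6)
  b[which.min(0.5 * (z - b)^2 + pen(b))]
}

scad_penalty_value <- function(b, lam, alpha) {
  ab <- abs(b)
  ifelse(ab <= lam, lam * ab,
         ifelse(ab <= alpha * lam,
                (2 * alpha * lam * ab - ab^2 - lam^2) / (2 * (alpha - 1)),
                lam^2 * (alpha + 1) / 2))
}

mcp_penalty_value <- function(b, lam, alpha) {
  ab <- abs(b)
  ifelse(ab < alpha * lam, lam * ab - ab^2 / (2 * alpha),
         alpha * lam^2 / 2)
}

# Random regression problem with a sparse truth.
random_problem <- function(n, k, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  X <- matrix(rnorm(n * k), n, k)
  beta <- rnorm(k) * rbinom(k, 1, 0.6)
  y <- as.numeric(X %*% beta) + rnorm(n)
  list(X = X, y = y, beta = beta)
}

# Random censored sample with continuous times (no ties a.s.).
random_censored_sample <- function(n) {
  y <- rexp(n) + runif(n, 0, 0.1)
  delta <- rbinom(n, 1, 0.7)
  if (all(delta == 1)) delta[1] <- 0
  censored_sample(y, delta)
}
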