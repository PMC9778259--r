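test_that("AICc follows the corrected formula with guards", {
  expect_equal(aicc_score(rss = 10, df = 2, n = 10), 2)  # log(1)+1+6/6
  expect_equal(aicc_score(rss = 100 * exp(1), df = 0, n = 100),
               2 + 2 / 98)
  expect_identical(aicc_score(rss = 1, df = 8, n = 10), Inf)
  expect_identical(aicc_score(rss = 0, df = 1, n = 10), Inf)
})

test_that("uncensored flat-curve fit recovers the OLS solution", {
  set.seed(51)
  n <- 120
  X <- matrix(rnorm(n * 4), n, 4)
  beta <- c(2, -1, 0.5, 0)
  t <- runif(n)
  y <- as.numeric(X %*% beta) + rnorm(n)  # f identically zero
  s <- censored_sample(y, rep(1, n))
  fit <- fit_plm(s, X, t, penalty_spec("lasso", 0),
                 lp_config(1, 100, "uniform"))
  ols <- as.numeric(qr.solve(X, y))
  # large-h smoother only removes a global line; estimates stay close
  expect_lt(max(abs(fit$beta - ols)), 0.05)
  expect_equal(fit$fitted, as.numeric(X %*% fit$beta + fit$fhat))
})

test_that("a zero design matrix yields a pure nonparametric fit", {
  set.seed(52)
  n <- 50
  t <- sort(runif(n))
  y <- t * sin(t * 4) + rnorm(n, 0, 0.1)
  s <- censored_sample(y, rep(1, n))
  X <- matrix(0, n, 3)
  fit <- fit_plm(s, X, t, penalty_spec("lasso", 1), lp_config(1, 0.2))
  expect_equal(fit$beta, c(0, 0, 0))
  S <- smoother_matrix(t, lp_config(1, 0.2))
  expect_equal(fit$fhat, as.numeric(S$S %*% fit$ystar$ystar))
})

test_that("nonparametric component recovers a known curve", {
  # noiseless data at the true beta: fhat tracks f
  n <- 500
  tc <- true_curve(n)
  set.seed(53)
  X <- matrix(rnorm(n * 3), n, 3)
  beta <- c(1, -1, 0.5)
  ystar <- as.numeric(X %*% beta) + tc$f
  S <- smoother_matrix(tc$t, lp_config(1, 0.05))
  fhat <- nonparametric_component(S, ystar, X, beta)
  expect_lt(max(abs(fhat - tc$f)), 0.1)

  # exact identities
  expect_equal(nonparametric_component(S, as.numeric(X %*% beta), X, beta),
               rep(0, n))
  expect_equal(nonparametric_component(diag(n), ystar, X, beta),
               ystar - as.numeric(X %*% beta))
})

test_that("singleton grids are returned as selected values", {
  set.seed(54)
  d <- generate_scenario(scenario_config(2, n = 60, k = 15, cl = 0.1,
                                         seed = 54))
  s <- censored_sample(d$y, d$delta)
  fit <- tune_plm(s, d$X, d$t, "lasso", lam_grid = 12, h_grid = 0.4)
  expect_equal(fit$lambda, 12)
  expect_equal(fit$h, 0.4)
  expect_equal(nrow(fit$score_table), 1L)
})

test_that("sparsity along the lambda path is near-monotone at fixed bandwidth", {
  # the lasso active set is not theorem-monotone in lambda (coefficients
  # can re-enter); require a non-increasing count up to at most one
  # single-unit re-entry per path
  set.seed(55)
  d <- generate_scenario(scenario_config(2, n = 80, k = 15, cl = 0.1,
                                         seed = 55))
  s <- censored_sample(d$y, d$delta)
  fit <- tune_plm(s, d$X, d$t, "lasso", n_lambda = 25, n_h = 3)
  tab <- fit$score_table
  for (h in unique(tab$h)) {
    sub <- tab[tab$h == h, ]
    sub <- sub[order(sub$lambda), ]
    steps <- diff(sub$df)
    expect_true(all(steps <= 1))
    expect_lte(sum(steps > 0), 1)
    expect_lt(sub$df[nrow(sub)], sub$df[1])  # globally decreasing
  }
})

test_that("pure-noise designs stay sparse under the tuned lasso", {
  set.seed(56)
  kept <- replicate(20, {
    n <- 60
    k <- 8
    X <- matrix(rnorm(n * k), n, k)
    t <- runif(n)
    y <- t * sin(t^2) + rnorm(n)  # all true beta are zero
    s <- censored_sample(y, rep(1, n))
    fit <- tune_plm(s, X, t, "lasso", n_lambda = 20, n_h = 4)
    sum(fit$beta != 0)
  })
  expect_lte(mean(kept), 4)  # at most k/2 on average
})

test_that("prediction reproduces training fits and interpolates lines", {
  set.seed(57)
  d <- generate_scenario(scenario_config(2, n = 60, k = 15, cl = 0.1,
                                         seed = 57))
  s <- censored_sample(d$y, d$delta)
  fit <- fit_plm(s, d$X, d$t, penalty_spec("lasso", 10), lp_config(1, 0.5))
  expect_equal(predict(fit), fit$fitted)
  expect_equal(predict(fit, Xnew = d$X, tnew = d$t), fit$fitted,
               tolerance = 1e-10)

  # zero parametric rows return the nonparametric part alone
  expect_equal(predict(fit, Xnew = matrix(0, 3, 15), tnew = d$t[1:3]),
               fit$fhat[1:3], tolerance = 1e-10)

  expect_warning(predict(fit, Xnew = matrix(0, 1, 15), tnew = 10),
                 "outside the training range")

  # noiseless linear truth interpolates exactly with a local linear fit
  n <- 40
  t <- seq(0, 1, length.out = n)
  y <- 2 + 3 * t
  s2 <- censored_sample(y, rep(1, n))
  X2 <- matrix(0, n, 2)
  f2 <- fit_plm(s2, X2, t, penalty_spec("lasso", 0), lp_config(1, 0.3))
  mid <- (t[10] + t[11]) / 2
  expect_equal(predict(f2, Xnew = matrix(0, 1, 2), tnew = mid),
               2 + 3 * mid, tolerance = 1e-6)
})

test_that("ridge never zeroes a coefficient across tuned fits", {
  set.seed(58)
  for (i in 1:5) {
    d <- generate_scenario(scenario_config(1, n = 50, k = 15, cl = 0.1,
                                           seed = 580 + i))
    s <- censored_sample(d$y, d$delta)
    fit <- tune_plm(s, d$X, d$t, "ridge", n_lambda = 20, n_h = 4)
    expect_true(all(fit$beta != 0))
  }
})

test_that("adaptive lasso recovers Scenario-2 signals at n = 300", {
  st <- run_study(scenario_config(2, n = 300, k = 15, cl = 0.1),
                  reps = 50, families = "adaptive_lasso", seed = 59)
  expect_lt(st$table$rmse, 0.15)
  # true signals are retained almost always: mean sensitivity above 95%
  # and the full set of 10 recovered in the large majority of replicates
  expect_gt(mean(st$replicates$sens), 0.95)
  expect_gt(mean(st$replicates$sens == 1), 0.8)
})

test_that("fits are deterministic given the scenario seed", {
  d1 <- generate_scenario(scenario_config(2, n = 50, k = 15, cl = 0.1,
                                          seed = 60))
  d2 <- generate_scenario(scenario_config(2, n = 50, k = 15, cl = 0.1,
                                          seed = 60))
  expect_identical(d1$X, d2$X)
  expect_identical(d1$y, d2$y)
  f1 <- tune_plm(censored_sample(d1$y, d1$delta), d1$X, d1$t, "scad",
                 n_lambda = 10, n_h = 3)
  f2 <- tune_plm(censored_sample(d2$y, d2$delta), d2$X, d2$t, "scad",
                 n_lambda = 10, n_h = 3)
  expect_identical(f1$beta, f2$beta)
})
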