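test_that("thresholding operators match the brute-force 1-D minimizer", {
  # worked examples
  expect_equal(soft_threshold(3, 1), 2)
  expect_equal(soft_threshold(-0.5, 1), 0)
  expect_equal(soft_threshold(1.7, 0), 1.7)
  expect_equal(scad_threshold(1, 2, 3.7), 0)
  expect_equal(scad_threshold(3, 1, 3.7), (2.7 * 3 - 3.7) / 1.7)
  expect_equal(scad_threshold(5, 1, 3.7), 5)
  expect_equal(mcp_threshold(2, 1, 3), 1.5)
  expect_equal(mcp_threshold(4, 1, 3), 4)
  expect_equal(mcp_threshold(0.5, 1, 3), 0)

  set.seed(31)
  for (i in 1:30) {
    z <- runif(1, -5, 5)
    lam <- runif(1, 0, 2)
    expect_equal(soft_threshold(z, lam),
                 grid_minimize(z, function(b) lam * abs(b)),
                 tolerance = 1e-4)
    a_s <- runif(1, 2.1, 6)
    expect_equal(scad_threshold(z, lam, a_s),
                 grid_minimize(z, function(b)
                   scad_penalty_value(b, lam, a_s)),
                 tolerance = 1e-4)
    a_m <- runif(1, 1.1, 6)
    expect_equal(mcp_threshold(z, lam, a_m),
                 grid_minimize(z, function(b)
                   mcp_penalty_value(b, lam, a_m)),
                 tolerance = 1e-4)
  }
})

test_that("adaptive weights follow the pilot rule with a floor", {
  expect_equal(adaptive_weights(c(1, 2), q = 1), c(1, 0.5))
  expect_equal(adaptive_weights(c(0, 1), q = 1, floor = 1e-8), c(1e8, 1))
  expect_equal(adaptive_weights(2, q = 2), 0.25)
})

test_that("penalty specifications validate their constants", {
  expect_error(penalty_spec("scad", 1, alpha = 2), "alpha.*> 2")
  expect_error(penalty_spec("mcp", 1, alpha = 1), "alpha.*> 1")
  expect_error(penalty_spec("lasso", -1), "non-negative")
  expect_error(penalty_spec("adaptive_lasso", 1, weights = c(1, 0)),
               "strictly positive")
  expect_error(penalty_spec("lasso", 1, lam2 = 1), "elasticnet")
  expect_equal(penalty_spec("scad", 1)$alpha, 3.7)
  expect_equal(penalty_spec("mcp", 1)$alpha, 3)
  expect_error(scad_threshold(1, 1, 2), "> 2")
  expect_error(mcp_threshold(1, 1, 1), "> 1")
})

test_that("closed-form ridge solves the penalized normal equations", {
  expect_equal(ridge_closed_form(diag(2), 1, y = c(2, 4))$beta, c(1, 2))

  set.seed(32)
  pb <- random_problem(40, 5)
  f0 <- ridge_closed_form(pb$X, 0, y = pb$y)
  expect_equal(f0$beta, as.numeric(qr.solve(pb$X, pb$y)),
               tolerance = 1e-10)
  fbig <- ridge_closed_form(pb$X, 1e9, y = pb$y)
  expect_lt(sqrt(sum(fbig$beta^2)),
            1e-6 * sqrt(sum(crossprod(pb$X, pb$y)^2)))
  Xc <- cbind(pb$X, pb$X[, 1])  # collinear
  expect_error(ridge_closed_form(Xc, 0, y = pb$y), "singular")
})

test_that("coordinate descent reduces to least squares at lambda zero", {
  set.seed(33)
  pb <- random_problem(50, 6)
  f <- coordinate_descent(pb$X, penalty_spec("lasso", 0), y = pb$y,
                          tol = 1e-12)
  expect_equal(f$beta, as.numeric(qr.solve(pb$X, pb$y)),
               tolerance = 1e-6)
  expect_true(f$converged)
})

test_that("orthonormal-design lasso is exact coordinatewise soft-thresholding", {
  set.seed(34)
  n <- 64
  k <- 4
  Q <- qr.Q(qr(matrix(rnorm(n * k), n, k))) * sqrt(n)  # X'X = n I
  y <- rnorm(n, sd = 2)
  lam_user <- 40
  f <- coordinate_descent(Q, penalty_spec("lasso", lam_user), y = y,
                          tol = 1e-12)
  z <- as.numeric(crossprod(Q, y)) / n
  expect_equal(f$beta, soft_threshold(z, lam_user / (2 * n)),
               tolerance = 1e-8)
})

test_that("unit-weight adaptive lasso coincides with the lasso", {
  set.seed(35)
  pb <- random_problem(40, 6)
  fl <- coordinate_descent(pb$X, penalty_spec("lasso", 25), y = pb$y,
                           tol = 1e-12)
  fa <- coordinate_descent(
    pb$X, penalty_spec("adaptive_lasso", 25, weights = rep(1, 6)),
    y = pb$y, tol = 1e-12)
  expect_equal(fa$beta, fl$beta, tolerance = 1e-10)
})

test_that("the penalized objective is non-increasing for convex families", {
  set.seed(36)
  for (i in 1:50) {
    pb <- random_problem(sample(20:60, 1), sample(2:10, 1))
    fam <- sample(c("lasso", "elasticnet", "adaptive_lasso", "ridge"), 1)
    spec <- if (fam == "adaptive_lasso") {
      penalty_spec(fam, runif(1, 1, 40),
                   weights = runif(ncol(pb$X), 0.5, 2))
    } else {
      penalty_spec(fam, runif(1, 1, 40))
    }
    f <- coordinate_descent(pb$X, spec, y = pb$y, trace = TRUE)
    expect_true(all(diff(f$obj_trace) <= 1e-12))
  }
})

test_that("lasso satisfies the KKT conditions at convergence", {
  set.seed(37)
  for (i in 1:10) {
    pb <- random_problem(50, 8)
    lam <- runif(1, 5, 60)
    f <- coordinate_descent(pb$X, penalty_spec("lasso", lam), y = pb$y,
                            tol = 1e-12)
    # internal scale: standardized columns, threshold lam/(2n)
    n <- nrow(pb$X)
    s <- sqrt(colMeans(pb$X^2))
    Xs <- sweep(pb$X, 2, s, `/`)
    b <- f$beta * s
    grad <- as.numeric(crossprod(Xs, pb$y - Xs %*% b)) / n
    l1 <- lam / (2 * n)
    expect_true(all(abs(grad[b == 0]) <= l1 + 1e-6))
    if (any(b != 0)) {
      expect_lt(max(abs(abs(grad[b != 0]) - l1)), 1e-6)
    }
  }
})

test_that("SCAD and MCP approach the lasso as alpha grows", {
  set.seed(38)
  for (i in 1:5) {
    pb <- random_problem(50, 6)
    lam <- runif(1, 10, 50)
    fl <- coordinate_descent(pb$X, penalty_spec("lasso", lam), y = pb$y,
                             tol = 1e-12)
    fs <- coordinate_descent(pb$X, penalty_spec("scad", lam, alpha = 1e6),
                             y = pb$y, tol = 1e-12)
    fm <- coordinate_descent(pb$X, penalty_spec("mcp", lam, alpha = 1e6),
                             y = pb$y, tol = 1e-12)
    expect_lt(max(abs(fs$beta - fl$beta)), 1e-4)
    expect_lt(max(abs(fm$beta - fl$beta)), 1e-4)
  }
})

test_that("elasticnet recovers its ridge and lasso limits", {
  set.seed(39)
  pb <- random_problem(45, 5)
  fr <- ridge_closed_form(pb$X, 7, y = pb$y)
  fe_l2 <- coordinate_descent(
    pb$X, penalty_spec("elasticnet", lam = 7, lam2 = 0), y = pb$y,
    standardize = FALSE, tol = 1e-13)
  expect_lt(max(abs(fe_l2$beta - fr$beta)), 1e-6)

  fl <- coordinate_descent(pb$X, penalty_spec("lasso", 30), y = pb$y,
                           tol = 1e-13)
  fe_l1 <- coordinate_descent(
    pb$X, penalty_spec("elasticnet", lam = 0, lam2 = 30), y = pb$y,
    tol = 1e-13)
  expect_lt(max(abs(fe_l1$beta - fl$beta)), 1e-6)
})

test_that("lasso and elasticnet agree with the glmnet oracle", {
  library(glmnet)
  set.seed(40)
  for (i in 1:20) {
    n <- sample(30:60, 1)
    k <- sample(3:8, 1)
    pb <- random_problem(n, k)
    # align objective scaling: zero-mean, unit 1/n-variance response so
    # glmnet's internal response standardization is a no-op
    y <- pb$y - mean(pb$y)
    y <- y / sqrt(mean(y^2))
    l1 <- runif(1, 0.02, 0.3)
    fl <- coordinate_descent(pb$X, penalty_spec("lasso", 2 * n * l1),
                             y = y, standardize = FALSE, tol = 1e-12)
    gl <- glmnet(pb$X, y, alpha = 1, lambda = c(4, 2, 1) * l1,
                 standardize = FALSE, intercept = FALSE, thresh = 1e-14)
    expect_lt(max(abs(fl$beta - coef(gl)[-1, 3])), 1e-4)

    l2 <- runif(1, 0.02, 0.3)
    fe <- coordinate_descent(
      pb$X, penalty_spec("elasticnet", lam = n * l2, lam2 = 2 * n * l1),
      y = y, standardize = FALSE, tol = 1e-12)
    ltot <- l1 + l2
    ge <- glmnet(pb$X, y, alpha = l1 / ltot, lambda = c(4, 2, 1) * ltot,
                 standardize = FALSE, intercept = FALSE, thresh = 1e-14)
    expect_lt(max(abs(fe$beta - coef(ge)[-1, 3])), 1e-4)
  }
})

test_that("solver failure modes are graceful", {
  set.seed(41)
  pb <- random_problem(30, 4)
  Xn <- pb$X
  Xn[1, 1] <- NA
  expect_error(coordinate_descent(Xn, penalty_spec("lasso", 1), y = pb$y),
               "NaN/NA")
  expect_warning(
    f <- coordinate_descent(pb$X, penalty_spec("lasso", 1), y = pb$y,
                            tol = 1e-15, max_iter = 2L),
    "did not converge")
  expect_false(f$converged)
  expect_error(
    coordinate_descent(pb$X, penalty_spec("scad", 1), y = pb$y,
                       standardize = FALSE),
    "standardize")
})
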