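#' Corrected AIC for a fitted candidate
#'
#' `AICc = log(sigma2) + 1 + 2 (df + 1) / (n - df - 2)` with
#' `sigma2 = rss / n`. The residual sum of squares is taken on the
#' partial-residual scale (`||ytilde - Xtilde beta||^2`), the quantity the
#' penalized estimators actually minimize. For the sparse families `df` is
#' the number of nonzero coefficients; for ridge it is the trace of the
#' ridge hat matrix on `Xtilde`. A degenerate denominator
#' (`n - df - 2 <= 0`) or a non-positive `rss` yields `+Inf`, excluding the
#' candidate rather than raising an error.
#'
#' @param rss residual sum of squares.
#' @param df effective number of parameters.
#' @param n sample size.
#' @return The AICc score (possibly `Inf`).
#' @examples
#' aicc_score(rss = 10, df = 2, n = 10)  # log(1) + 1 + 6/6 = 2
#' @export
aicc_score <- function(rss, df, n) {
  if (n - df - 2 <= 0) return(Inf)
  sigma2 <- rss / n
  if (!is.finite(sigma2) || sigma2 <= 0) return(Inf)
  log(sigma2) + 1 + 2 * (df + 1) / (n - df - 2)
}

#' Default bandwidth grid
#'
#' Log-spaced grid of `n_h` bandwidths spanning `[0.5, 2] * h_ref` with the
#' reference bandwidth `h_ref = n^(-1/5) * range(t)`, the usual
#' one-dimensional smoothing rate.
#'
#' @param t nonparametric covariate vector.
#' @param n_h number of grid points.
#' @export
default_h_grid <- function(t, n_h = 10L) {
  h_ref <- length(t)^(-1 / 5) * diff(range(t))
  exp(seq(log(0.5), log(2), length.out = n_h)) * h_ref
}

# Largest criterion-scale lambda that zeroes every coefficient for the
# L1-type families (standardized columns, optional weights), and the grid
# below it.
.default_lambda_grid <- function(Xs, yt, family, w, n_lambda) {
  n <- nrow(Xs)
  m <- max(abs(crossprod(Xs, yt)) / (n * w))
  fac <- if (family == "elasticnet") 4 * n else 2 * n
  lam_max <- fac * m
  if (!is.finite(lam_max) || lam_max <= 0) lam_max <- 1
  sort(lam_max * 10^seq(-3, 0, length.out = n_lambda), decreasing = TRUE)
}

# Pilot estimate for adaptive-lasso weights: OLS on the partial residuals
# when the design has full column rank, otherwise the AICc-selected ridge.
.alasso_pilot <- function(Xt, yt, n_lambda = 25L) {
  qrX <- qr(Xt)
  if (qrX$rank == ncol(Xt)) {
    return(qr.coef(qrX, yt))
  }
  sv <- svd(Xt)
  uy <- crossprod(sv$u, yt)
  n <- nrow(Xt)
  lams <- 10^seq(-4, 4, length.out = n_lambda) * max(sv$d^2)
  best <- NULL
  best_score <- Inf
  for (lam in lams) {
    shr <- sv$d^2 / (sv$d^2 + lam)
    fitted <- sv$u %*% (shr * uy)
    rss <- sum((yt - fitted)^2)
    score <- aicc_score(rss, sum(shr), n)
    if (score < best_score) {
      best_score <- score
      best <- as.numeric(sv$v %*% ((sv$d / (sv$d^2 + lam)) * uy))
    }
  }
  best
}

# Shared pipeline state reused across bandwidths and penalty families:
# censoring fit, synthetic response, and per-h smoother/partial residuals.
.prepare_plm <- function(sample, X, t, config, h_grid) {
  X <- as.matrix(X)
  t <- as.numeric(t)
  if (nrow(X) != sample$n || length(t) != sample$n) {
    stop("dimensions of `sample`, `X` and `t` do not conform",
         call. = FALSE)
  }
  G <- fit_censoring_km(sample)
  sr <- synthetic_response(sample, G)
  per_h <- lapply(h_grid, function(h) {
    cfg <- lp_config(config$degree, h, config$kernel)
    S <- smoother_matrix(t, cfg)
    pr <- partial_residuals(S, X, sr)
    list(h = h, S = S, pr = pr)
  })
  list(sample = sample, X = X, t = t, config = config, G = G, sr = sr,
       per_h = per_h)
}

# Coordinate-descent path (warm-started, lambda descending) for one family.
# Returns per-lambda beta (original scale), df (nonzero count) and rss.
.cd_path <- function(Xt, yt, family, lam_grid, alpha, w, tol, maxit) {
  n <- nrow(Xt)
  k <- ncol(Xt)
  s <- sqrt(colMeans(Xt^2))
  s[s <= 0] <- 1
  Xs <- sweep(Xt, 2L, s, `/`)
  if (is.null(w)) w <- rep(1, k)
  fam_int <- switch(family, scad = 2L, mcp = 3L, 1L)
  b_warm <- rep(0, k)      # convex (or lasso pilot) path state
  out <- vector("list", length(lam_grid))
  for (i in seq_along(lam_grid)) {
    lam <- lam_grid[i]
    if (family == "elasticnet") {
      l1 <- lam / (4 * n)
      l2 <- lam / (2 * n)
    } else {
      l1 <- lam / (2 * n)
      l2 <- 0
    }
    if (fam_int == 1L) {
      res <- cd_solve(Xs, yt, w, l1, l2, 0, 1L, b_warm, tol, maxit, FALSE)
      b_warm <- as.numeric(res$beta)
      b <- b_warm
    } else {
      # convex warm start: lasso solution at the same lambda
      resL <- cd_solve(Xs, yt, w, l1, 0, 0, 1L, b_warm, tol, maxit, FALSE)
      b_warm <- as.numeric(resL$beta)
      res <- cd_solve(Xs, yt, w, l1, 0, alpha, fam_int, b_warm, tol,
                      maxit, FALSE)
      b <- as.numeric(res$beta)
    }
    rss <- sum((yt - Xs %*% b)^2)
    out[[i]] <- list(lam = lam, beta = b / s, df = sum(b != 0), rss = rss)
  }
  out
}

#' Fit the right-censored partially linear model at fixed tuning values
#'
#' Runs the full pipeline at a given shrinkage parameter and bandwidth:
#' reversed Kaplan-Meier censoring fit, synthetic-data transform, local
#' polynomial smoother, partial residuals, penalized estimation of `beta`
#' (closed-form ridge or coordinate descent), and the plug-in nonparametric
#' component `fhat = S (ystar - X beta)`.
#'
#' @param sample a [censored_sample()].
#' @param X n x k design matrix for the parametric component.
#' @param t nonparametric covariate vector (length n).
#' @param spec a [penalty_spec()] with `lam` set. For the adaptive lasso,
#'   missing `weights` are computed from an OLS pilot on the partial
#'   residuals (ridge pilot if rank deficient) with exponent `spec$q`.
#' @param config an [lp_config()] with a set bandwidth.
#' @param cd_tol,cd_maxit coordinate-descent convergence controls.
#' @return An object of class `penplm_fit` with elements `beta`, `fhat`,
#'   `fitted` (`X beta + fhat`), `df`, `sigma2` (partial-residual RSS / n),
#'   `lambda`, `h`, `spec`, `config`, the censoring fit `G`, the synthetic
#'   response `ystar`, and the training data.
#' @examples
#' d <- generate_scenario(scenario_config(2, n = 60, k = 15, cl = 0.1,
#'                                        seed = 1))
#' f <- fit_plm(censored_sample(d$y, d$delta), d$X, d$t,
#'              penalty_spec("lasso", lam = 20),
#'              lp_config(bandwidth = 0.5))
#' f$beta
#' @export
fit_plm <- function(sample, X, t, spec, config,
                    cd_tol = 1e-7, cd_maxit = 100000L) {
  stopifnot(inherits(spec, "penalty_spec"), inherits(config, "lp_config"))
  if (is.null(config$bandwidth)) {
    stop("`config` needs a bandwidth; use tune_plm() to select one",
         call. = FALSE)
  }
  if (is.null(spec$lam)) {
    stop("`spec` needs a lambda; use tune_plm() to select one",
         call. = FALSE)
  }
  prep <- .prepare_plm(sample, X, t, config, config$bandwidth)
  .fit_from_prep(prep, 1L, spec, cd_tol, cd_maxit)
}

# Build a penplm_fit from a prepared pipeline at per_h entry `hi`.
.fit_from_prep <- function(prep, hi, spec, cd_tol = 1e-7,
                           cd_maxit = 100000L, score_table = NULL) {
  entry <- prep$per_h[[hi]]
  pr <- entry$pr
  n <- prep$sample$n
  spec_use <- spec
  if (spec$family == "adaptive_lasso" && is.null(spec$weights)) {
    pilot <- .alasso_pilot(pr$Xtilde, pr$ytilde)
    spec_use <- penalty_spec("adaptive_lasso", lam = spec$lam,
                             weights = adaptive_weights(pilot, spec$q),
                             q = spec$q)
  }
  if (spec$family == "ridge") {
    est <- ridge_closed_form(pr, spec$lam)
    sv <- svd(pr$Xtilde)
    df <- sum(sv$d^2 / (sv$d^2 + spec$lam))
  } else {
    est <- coordinate_descent(pr, spec_use, tol = cd_tol,
                              max_iter = cd_maxit)
    df <- sum(est$beta != 0)
  }
  beta <- est$beta
  fhat <- nonparametric_component(entry$S, prep$sr, prep$X, beta)
  rss <- sum((pr$ytilde - pr$Xtilde %*% beta)^2)
  structure(list(beta = beta,
                 fhat = fhat,
                 fitted = as.numeric(prep$X %*% beta + fhat),
                 df = df,
                 sigma2 = rss / n,
                 lambda = spec$lam,
                 h = entry$h,
                 spec = spec_use,
                 config = entry$S$config,
                 G = prep$G,
                 ystar = prep$sr,
                 sample = prep$sample,
                 X = prep$X,
                 t = prep$t,
                 converged = est$converged,
                 n_iter = est$n_iter,
                 score_table = score_table),
            class = "penplm_fit")
}

#' Nonparametric component estimate
#'
#' `fhat = S (ystar - X beta)`: the smoother applied to the synthetic
#' response after removing the fitted parametric part.
#'
#' @param S a [smoother_matrix()] (or plain matrix).
#' @param ystar a [synthetic_response()] or numeric vector.
#' @param X design matrix.
#' @param beta coefficient vector.
#' @return Numeric vector of fitted values of f at the observed t.
#' @export
nonparametric_component <- function(S, ystar, X, beta) {
  Sm <- if (inherits(S, "smoother_matrix")) S$S else as.matrix(S)
  y <- if (inherits(ystar, "synthetic_response")) ystar$ystar
       else as.numeric(ystar)
  as.numeric(Sm %*% (y - as.matrix(X) %*% beta))
}

# Score every (lambda, h) pair for one family over a prepared pipeline.
# Returns list(table = data.frame, paths = per-h list of per-lambda fits).
.tune_family <- function(prep, family, lam_grid = NULL, alpha = NULL,
                         q = 1, n_lambda = 50L, cd_tol = 1e-7,
                         cd_maxit = 100000L) {
  n <- prep$sample$n
  spec0 <- penalty_spec(family, lam = 0, alpha = alpha, q = q)
  alpha <- spec0$alpha
  if (is.null(lam_grid)) {
    ref <- prep$per_h[[ceiling(length(prep$per_h) / 2)]]
    Xt <- ref$pr$Xtilde
    s <- sqrt(colMeans(Xt^2))
    s[s <= 0] <- 1
    Xs <- sweep(Xt, 2L, s, `/`)
    w <- rep(1, ncol(Xt))
    if (family == "adaptive_lasso") {
      pilot <- .alasso_pilot(Xt, ref$pr$ytilde)
      w <- adaptive_weights(pilot, q)
    }
    lam_grid <- .default_lambda_grid(Xs, ref$pr$ytilde, family, w,
                                     n_lambda)
  }
  lam_grid <- sort(as.numeric(lam_grid), decreasing = TRUE)
  rows <- list()
  paths <- vector("list", length(prep$per_h))
  weights_h <- vector("list", length(prep$per_h))
  for (hi in seq_along(prep$per_h)) {
    entry <- prep$per_h[[hi]]
    Xt <- entry$pr$Xtilde
    yt <- entry$pr$ytilde
    if (family == "ridge") {
      sv <- svd(Xt)
      uy <- as.numeric(crossprod(sv$u, yt))
      path <- lapply(lam_grid, function(lam) {
        shr <- sv$d^2 / (sv$d^2 + lam)
        beta <- as.numeric(sv$v %*% ((sv$d / (sv$d^2 + lam)) * uy))
        fitted <- as.numeric(sv$u %*% (shr * uy))
        list(lam = lam, beta = beta, df = sum(shr),
             rss = sum((yt - fitted)^2))
      })
    } else {
      w <- NULL
      if (family == "adaptive_lasso") {
        pilot <- .alasso_pilot(Xt, yt)
        w <- adaptive_weights(pilot, q)
        weights_h[[hi]] <- w
      }
      path <- .cd_path(Xt, yt, family, lam_grid, alpha, w, cd_tol,
                       cd_maxit)
    }
    paths[[hi]] <- path
    rows[[hi]] <- data.frame(
      h = entry$h,
      lambda = vapply(path, `[[`, numeric(1), "lam"),
      df = vapply(path, `[[`, numeric(1), "df"),
      sigma2 = vapply(path, `[[`, numeric(1), "rss") / n,
      aicc = vapply(path, function(p) aicc_score(p$rss, p$df, n),
                    numeric(1)))
  }
  table <- do.call(rbind, rows)
  list(table = table, paths = paths, weights_h = weights_h,
       lam_grid = lam_grid, alpha = alpha, q = q)
}

# Pick the AICc-minimizing (lambda, h); ties -> smaller lambda, then
# smaller h.
.select_best <- function(table) {
  if (all(!is.finite(table$aicc))) {
    stop("no feasible model: every (lambda, h) candidate has infinite AICc",
         call. = FALSE)
  }
  ord <- order(table$aicc, table$lambda, table$h)
  table[ord[1L], ]
}

#' Joint AICc selection of the shrinkage parameter and the bandwidth
#'
#' Fits every (lambda, h) pair on the grids for one penalty family and
#' returns the fit at the AICc-minimizing pair (ties resolved toward the
#' smaller lambda, then the smaller bandwidth). The smoother matrix and
#' partial residuals are computed once per bandwidth and shared across the
#' whole lambda path, which is warm-started in descending lambda.
#'
#' @inheritParams fit_plm
#' @param family penalty family name (see [penalty_spec()]).
#' @param lam_grid optional lambda grid (criterion scale). By default a
#'   50-point log-spaced grid over `[1e-3, 1] * lam_max`, with `lam_max`
#'   the smallest value that zeroes every coefficient at the reference
#'   bandwidth.
#' @param h_grid optional bandwidth grid; defaults to [default_h_grid()].
#' @param config an [lp_config()]; its bandwidth, if any, is ignored in
#'   favor of `h_grid`.
#' @param alpha SCAD/MCP concavity (defaults 3.7 and 3).
#' @param q adaptive-lasso weight exponent.
#' @param n_lambda,n_h default grid sizes.
#' @return A `penplm_fit` (see [fit_plm()]) whose `score_table` holds the
#'   full AICc table over the grids.
#' @export
tune_plm <- function(sample, X, t, family = "lasso", lam_grid = NULL,
                     h_grid = NULL, config = lp_config(), alpha = NULL,
                     q = 1, n_lambda = 50L, n_h = 10L, cd_tol = 1e-7,
                     cd_maxit = 100000L) {
  if (is.null(h_grid)) h_grid <- default_h_grid(t, n_h)
  h_grid <- sort(as.numeric(h_grid))
  prep <- .prepare_plm(sample, X, t, config, h_grid)
  tun <- .tune_family(prep, family, lam_grid, alpha, q, n_lambda,
                      cd_tol, cd_maxit)
  best <- .select_best(tun$table)
  hi <- match(best$h, h_grid)
  spec <- if (family == "adaptive_lasso") {
    penalty_spec(family, lam = best$lambda,
                 weights = tun$weights_h[[hi]], q = q)
  } else {
    penalty_spec(family, lam = best$lambda, alpha = tun$alpha, q = q)
  }
  .fit_from_prep(prep, hi, spec, cd_tol, cd_maxit,
                 score_table = tun$table)
}

#' @export
print.penplm_fit <- function(x, ...) {
  cat("Right-censored partially linear model fit\n")
  cat(sprintf("  n = %d, k = %d, censored = %.1f%%\n", x$sample$n,
              length(x$beta), 100 * mean(x$sample$delta == 0)))
  cat(sprintf("  penalty = %s, lambda = %.4g, h = %.4g\n",
              x$spec$family, x$lambda, x$h))
  cat(sprintf("  df = %.2f, sigma2 = %.4g, nonzero = %d\n", x$df,
              x$sigma2, sum(x$beta != 0)))
  invisible(x)
}

#' Predict from a fitted right-censored partially linear model
#'
#' `Xnew beta + fhat(tnew)`, where the nonparametric component at new
#' points re-applies the local polynomial solve against the training
#' residuals `ystar - X beta`. Evaluation outside the training range of `t`
#' warns about extrapolation.
#'
#' @param object a `penplm_fit`.
#' @param Xnew design matrix for the parametric part (defaults to the
#'   training design).
#' @param tnew nonparametric covariate values (defaults to the training
#'   values, returning `object$fitted`).
#' @param ... unused.
#' @return Numeric vector of predictions.
#' @export
predict.penplm_fit <- function(object, Xnew = NULL, tnew = NULL, ...) {
  if (is.null(Xnew) && is.null(tnew)) return(object$fitted)
  if (is.null(Xnew)) Xnew <- object$X
  if (is.null(tnew)) tnew <- object$t
  Xnew <- as.matrix(Xnew)
  tnew <- as.numeric(tnew)
  if (any(tnew < min(object$t)) || any(tnew > max(object$t))) {
    warning("some `tnew` values lie outside the training range of t; ",
            "local polynomial extrapolation is unreliable", call. = FALSE)
  }
  r <- object$ystar$ystar - object$X %*% object$beta
  cfg <- object$config
  kern <- .kernel_fun(cfg$kernel)
  fnew <- vapply(tnew, function(t0) {
    w <- kern((object$t - t0) / cfg$bandwidth) / cfg$bandwidth
    if (all(w == 0)) {
      stop(sprintf("degenerate neighborhood at tnew = %g", t0),
           call. = FALSE)
    }
    sum(.smoother_row(object$t, t0, cfg$degree, w) * r)
  }, numeric(1))
  as.numeric(Xnew %*% object$beta + fnew)
}
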