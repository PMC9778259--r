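#' Penalty specification
#'
#' Bundles a penalty family with its tuning constants. All shrinkage
#' parameters are on the unnormalized sum-of-squares scale of the penalized
#' criterion `||ytilde - Xtilde beta||^2 + P(beta)`; internally the solver
#' works with the per-observation objective `(1/(2n)) RSS + P(beta)/(2n)`,
#' so results are identical and lambda values are directly comparable with
#' the criterion as written.
#'
#' For the elasticnet the pair is `lam` (the quadratic term weight, lambda1)
#' and `lam2` (the absolute term weight, lambda2), matching the labeling of
#' the penalized criterion `lambda1 sum beta_j^2 + lambda2 sum |beta_j|`.
#' When only `lam` is supplied for the elasticnet (single-parameter tuning),
#' the two are split equally: `lambda1 = lambda2 = lam / 2`.
#'
#' @param family one of `"ridge"`, `"lasso"`, `"adaptive_lasso"`, `"scad"`,
#'   `"mcp"`, `"elasticnet"`.
#' @param lam main shrinkage parameter, >= 0 (may be `NULL` when the value
#'   is to be selected on a grid).
#' @param alpha concavity parameter: must exceed 2 for SCAD (default 3.7)
#'   and exceed 1 for MCP (default 3) so the firm threshold is well defined.
#' @param lam2 second elasticnet parameter (absolute-term weight).
#' @param weights strictly positive per-coefficient weights
#'   (adaptive lasso only); see [adaptive_weights()].
#' @param q pilot exponent for adaptive weights, > 0 (default 1).
#' @return An object of class `penalty_spec`.
#' @export
penalty_spec <- function(family = c("ridge", "lasso", "adaptive_lasso",
                                    "scad", "mcp", "elasticnet"),
                         lam = NULL, alpha = NULL, lam2 = NULL,
                         weights = NULL, q = 1) {
  family <- match.arg(family)
  if (!is.null(lam)) {
    lam <- as.numeric(lam)
    if (!is.finite(lam) || lam < 0) {
      stop("`lam` must be a finite non-negative number", call. = FALSE)
    }
  }
  if (family == "scad") {
    if (is.null(alpha)) alpha <- 3.7
    if (alpha <= 2) stop("SCAD requires `alpha` > 2", call. = FALSE)
  } else if (family == "mcp") {
    if (is.null(alpha)) alpha <- 3
    if (alpha <= 1) {
      stop("MCP requires `alpha` > 1 for a well-defined firm threshold",
           call. = FALSE)
    }
  }
  if (!is.null(lam2)) {
    if (family != "elasticnet") {
      stop("`lam2` is only meaningful for the elasticnet", call. = FALSE)
    }
    lam2 <- as.numeric(lam2)
    if (!is.finite(lam2) || lam2 < 0) {
      stop("`lam2` must be a finite non-negative number", call. = FALSE)
    }
  }
  if (!is.null(weights)) {
    if (family != "adaptive_lasso") {
      stop("`weights` are only meaningful for the adaptive lasso",
           call. = FALSE)
    }
    if (any(!is.finite(weights)) || any(weights <= 0)) {
      stop("adaptive weights must be strictly positive and finite",
           call. = FALSE)
    }
  }
  if (q <= 0) stop("`q` must be positive", call. = FALSE)
  structure(list(family = family, lam = lam, alpha = alpha, lam2 = lam2,
                 weights = weights, q = q),
            class = "penalty_spec")
}

#' @export
print.penalty_spec <- function(x, ...) {
  cat(sprintf("Penalty: %s", x$family))
  if (!is.null(x$lam)) cat(sprintf(", lambda = %g", x$lam))
  if (!is.null(x$lam2)) cat(sprintf(", lambda2 = %g", x$lam2))
  if (!is.null(x$alpha)) cat(sprintf(", alpha = %g", x$alpha))
  cat("\n")
  invisible(x)
}

#' Soft-thresholding operator
#'
#' `sign(z) * max(|z| - lam, 0)`: the minimizer of
#' `(1/2)(z - b)^2 + lam |b|`. Vectorized in `z`.
#'
#' @param z numeric input.
#' @param lam threshold level, >= 0.
#' @export
soft_threshold <- function(z, lam) {
  stopifnot(all(lam >= 0))
  sign(z) * pmax(abs(z) - lam, 0)
}

#' SCAD thresholding operator
#'
#' Minimizer of `(1/2)(z - b)^2 + P_scad(|b|; lam, alpha)`: soft threshold
#' for `|z| <= 2 lam`, the interpolating rule
#' `((alpha - 1) z - sign(z) alpha lam)/(alpha - 2)` for
#' `2 lam < |z| <= alpha lam`, and the identity beyond `alpha lam` (large
#' coefficients escape the penalty entirely).
#'
#' @param z numeric input (vectorized).
#' @param lam threshold level, >= 0.
#' @param alpha concavity parameter, must be > 2.
#' @export
scad_threshold <- function(z, lam, alpha) {
  if (alpha <= 2) stop("SCAD requires `alpha` > 2", call. = FALSE)
  stopifnot(all(lam >= 0))
  az <- abs(z)
  out <- soft_threshold(z, lam)
  mid <- az > 2 * lam & az <= alpha * lam
  out[mid] <- ((alpha - 1) * z[mid] - sign(z[mid]) * alpha * lam) /
    (alpha - 2)
  out[az > alpha * lam] <- z[az > alpha * lam]
  out
}

#' MCP (firm) thresholding operator
#'
#' Minimizer of `(1/2)(z - b)^2 + P_mcp(|b|; lam, alpha)` with the penalty
#' `int_0^{|b|} (lam - x/alpha)_+ dx`: zero for `|z| <= lam`, the firm rule
#' `sign(z)(|z| - lam)/(1 - 1/alpha)` for `lam < |z| <= alpha lam`, and the
#' identity beyond.
#'
#' @param z numeric input (vectorized).
#' @param lam threshold level, >= 0.
#' @param alpha concavity parameter, must be > 1.
#' @export
mcp_threshold <- function(z, lam, alpha) {
  if (alpha <= 1) stop("MCP firm threshold requires `alpha` > 1",
                       call. = FALSE)
  stopifnot(all(lam >= 0))
  az <- abs(z)
  out <- rep(0, length(z))
  mid <- az > lam & az <= alpha * lam
  out[mid] <- sign(z[mid]) * (az[mid] - lam) / (1 - 1 / alpha)
  out[az > alpha * lam] <- z[az > alpha * lam]
  out
}

#' Adaptive lasso weights from a pilot estimate
#'
#' `w_j = 1 / max(|pilot_j|, floor)^q`. The floor keeps weights finite when
#' the pilot estimate has exact zeros.
#'
#' @param pilot_beta pilot coefficient vector (typically OLS on the partial
#'   residuals).
#' @param q weight exponent, > 0.
#' @param floor small positive lower bound on `|pilot|`.
#' @export
adaptive_weights <- function(pilot_beta, q = 1, floor = 1e-8) {
  stopifnot(q > 0, floor > 0)
  1 / pmax(abs(pilot_beta), floor)^q
}

#' Closed-form ridge estimate on partial residuals
#'
#' `(Xtilde' Xtilde + lam I)^{-1} Xtilde' ytilde`, the minimizer of
#' `||ytilde - Xtilde b||^2 + lam ||b||^2`. With `lam = 0` this is the
#' ordinary least-squares solution on the partial residuals.
#'
#' @param pr a [partial_residuals()] object, or a design matrix (then
#'   supply `y`).
#' @param lam ridge parameter, >= 0.
#' @param y response vector when `pr` is a plain matrix.
#' @return A list of class `cd_fit` with `beta`, `n_iter = 0`,
#'   `converged = TRUE` and the penalized `objective`.
#' @export
ridge_closed_form <- function(pr, lam, y = NULL) {
  if (inherits(pr, "partial_residuals")) {
    X <- pr$Xtilde
    y <- pr$ytilde
  } else {
    X <- as.matrix(pr)
    if (is.null(y)) stop("supply `y` when `pr` is a matrix", call. = FALSE)
  }
  stopifnot(lam >= 0)
  k <- ncol(X)
  A <- crossprod(X) + lam * diag(k)
  beta <- tryCatch(solve(A, crossprod(X, y)),
                   error = function(e) NULL)
  if (is.null(beta)) {
    stop(paste("singular system in the ridge solve; the partial-residual",
               "design is collinear - use lam > 0"), call. = FALSE)
  }
  beta <- as.numeric(beta)
  r <- y - X %*% beta
  structure(list(beta = beta, n_iter = 0L, converged = TRUE,
                 objective = sum(r^2) + lam * sum(beta^2),
                 obj_trace = numeric(0)),
            class = "cd_fit")
}

# Penalty value at b (standardized scale) on the internal per-observation
# scale, matching what cd_solve minimizes.
.penalty_value <- function(ip, b) {
  if (ip$family == 1L) {
    return(ip$l1 * sum(ip$w * abs(b)) + 0.5 * ip$l2 * sum(b^2))
  }
  lam <- ip$l1 * ip$w
  ab <- abs(b)
  a <- ip$alpha
  if (ip$family == 2L) { # SCAD
    v <- ifelse(ab <= lam, lam * ab,
                ifelse(ab <= a * lam,
                       (2 * a * lam * ab - ab^2 - lam^2) / (2 * (a - 1)),
                       lam^2 * (a + 1) / 2))
  } else {               # MCP
    v <- ifelse(ab < a * lam, lam * ab - ab^2 / (2 * a), a * lam^2 / 2)
  }
  sum(v)
}

# Map a penalty_spec (criterion scale) to the internal per-observation
# solver parameters: l1 multiplies sum w|b|, l2 multiplies (1/2)||b||^2.
.internal_penalty <- function(spec, n, k) {
  fam <- spec$family
  lam <- spec$lam
  if (is.null(lam)) stop("`spec$lam` is not set", call. = FALSE)
  w <- rep(1, k)
  alpha <- if (is.null(spec$alpha)) 0 else spec$alpha
  if (fam == "lasso") {
    list(l1 = lam / (2 * n), l2 = 0, w = w, family = 1L, alpha = alpha)
  } else if (fam == "adaptive_lasso") {
    if (is.null(spec$weights)) {
      stop("adaptive lasso needs `weights` in the penalty spec",
           call. = FALSE)
    }
    list(l1 = lam / (2 * n), l2 = 0, w = spec$weights, family = 1L,
         alpha = alpha)
  } else if (fam == "elasticnet") {
    lam1 <- if (is.null(spec$lam2)) lam / 2 else lam       # quadratic term
    lam2 <- if (is.null(spec$lam2)) lam / 2 else spec$lam2 # absolute term
    list(l1 = lam2 / (2 * n), l2 = lam1 / n, w = w, family = 1L,
         alpha = alpha)
  } else if (fam == "ridge") {
    list(l1 = 0, l2 = lam / n, w = w, family = 1L, alpha = alpha)
  } else if (fam == "scad") {
    list(l1 = lam / (2 * n), l2 = 0, w = w, family = 2L, alpha = alpha)
  } else { # mcp
    list(l1 = lam / (2 * n), l2 = 0, w = w, family = 3L, alpha = alpha)
  }
}

#' Coordinate descent for penalized least squares on partial residuals
#'
#' Cyclic coordinate descent for
#' `||ytilde - Xtilde b||^2 + P(b)` with the penalty given by `spec`,
#' applying the family's univariate thresholding operator to each
#' per-coordinate least-squares solution in turn. Columns are internally
#' rescaled to unit root-mean-square (no centering: the partial-residual
#' transform has already removed constants, and the model carries no
#' intercept); coefficients are returned on the original covariate scale.
#'
#' SCAD and MCP require `standardize = TRUE`: their closed-form univariate
#' rules assume unit column scale.
#'
#' @param pr a [partial_residuals()] object, or a design matrix (then
#'   supply `y`).
#' @param spec a [penalty_spec()] with `lam` set.
#' @param init optional warm-start coefficients (original scale).
#' @param tol convergence tolerance on the maximum absolute coefficient
#'   change (standardized scale) in one sweep.
#' @param max_iter maximum number of full sweeps; reaching it yields a
#'   warning and `converged = FALSE`, never an error.
#' @param standardize rescale columns to unit RMS before descent.
#' @param y response vector when `pr` is a plain matrix.
#' @param trace record the penalized objective after every sweep (in
#'   `obj_trace`, on the internal per-observation scale).
#' @return A list of class `cd_fit`: `beta` (original scale), `n_iter`,
#'   `converged`, `objective` (criterion scale,
#'   `RSS + P(beta)` evaluated at the solution) and `obj_trace`.
#' @export
coordinate_descent <- function(pr, spec, init = NULL, tol = 1e-7,
                               max_iter = 100000L, standardize = TRUE,
                               y = NULL, trace = FALSE) {
  if (inherits(pr, "partial_residuals")) {
    X <- pr$Xtilde
    y <- pr$ytilde
  } else {
    X <- as.matrix(pr)
    if (is.null(y)) stop("supply `y` when `pr` is a matrix", call. = FALSE)
  }
  stopifnot(inherits(spec, "penalty_spec"))
  if (anyNA(X) || anyNA(y)) {
    stop("NaN/NA values in the penalized regression inputs", call. = FALSE)
  }
  n <- nrow(X)
  k <- ncol(X)
  ip <- .internal_penalty(spec, n, k)
  if (ip$family %in% c(2L, 3L) && !standardize) {
    stop("SCAD/MCP coordinate descent requires `standardize = TRUE`",
         call. = FALSE)
  }
  s <- if (standardize) sqrt(colMeans(X^2)) else rep(1, k)
  s[s <= 0] <- 1
  Xs <- sweep(X, 2L, s, `/`)
  b0 <- if (is.null(init)) rep(0, k) else as.numeric(init) * s
  res <- cd_solve(Xs, as.numeric(y), as.numeric(ip$w), ip$l1, ip$l2,
                  ip$alpha, ip$family, b0, tol, as.integer(max_iter),
                  isTRUE(trace))
  if (!res$converged) {
    warning(sprintf(
      "coordinate descent did not converge in %d sweeps (family %s)",
      max_iter, spec$family), call. = FALSE)
  }
  beta <- as.numeric(res$beta) / s
  r <- y - X %*% beta
  pen <- 2 * n * .penalty_value(ip, as.numeric(res$beta))
  structure(list(beta = beta, n_iter = res$n_iter,
                 converged = res$converged,
                 objective = sum(r^2) + pen,
                 obj_trace = as.numeric(res$obj_trace)),
            class = "cd_fit")
}
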