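#' Local polynomial smoother configuration
#'
#' @param degree polynomial order p >= 0 (integer). Degree 1 (local linear)
#'   is the default: it has the usual automatic boundary-bias correction.
#' @param bandwidth kernel bandwidth h > 0, in the units of the
#'   nonparametric covariate. May be `NULL` when the bandwidth is to be
#'   selected later on a grid.
#' @param kernel one of `"gaussian"`, `"epanechnikov"`, `"uniform"`.
#'   Gaussian (the default) has unbounded support and so never produces an
#'   empty neighborhood.
#' @return An object of class `lp_config`.
#' @export
lp_config <- function(degree = 1L, bandwidth = NULL,
                      kernel = c("gaussian", "epanechnikov", "uniform")) {
  kernel <- match.arg(kernel)
  degree <- as.integer(degree)
  if (is.na(degree) || degree < 0L) {
    stop("`degree` must be a non-negative integer", call. = FALSE)
  }
  if (!is.null(bandwidth)) {
    bandwidth <- as.numeric(bandwidth)
    if (!is.finite(bandwidth) || bandwidth <= 0) {
      stop("`bandwidth` must be a positive number", call. = FALSE)
    }
  }
  structure(list(degree = degree, bandwidth = bandwidth, kernel = kernel),
            class = "lp_config")
}

.kernel_fun <- function(kernel) {
  switch(kernel,
         gaussian = function(u) dnorm(u),
         epanechnikov = function(u) 0.75 * pmax(1 - u^2, 0),
         uniform = function(u) 0.5 * (abs(u) <= 1))
}

#' Local polynomial design matrix
#'
#' Powers of the centered covariate: entry (i, j) is `(t_i - t0)^(j - 1)`
#' for j = 1, ..., p + 1.
#'
#' @param t covariate vector.
#' @param t0 local center.
#' @param p polynomial degree (>= 0).
#' @return n x (p + 1) matrix.
#' @export
local_design <- function(t, t0, p) {
  p <- as.integer(p)
  stopifnot(p >= 0L)
  outer(as.numeric(t) - t0, 0:p, `^`)
}

#' Kernel weights around a local center
#'
#' Diagonal of the local weight matrix `W = diag(K((t_i - t0)/h))`,
#' returned as a vector. Compact-support kernels give exact zeros outside
#' `|t - t0| <= h`; if every weight is zero the neighborhood is degenerate
#' and an error asks for a larger bandwidth.
#'
#' @param t covariate vector.
#' @param t0 local center.
#' @param config an [lp_config()] with a set bandwidth.
#' @return Non-negative numeric vector of length `length(t)`.
#' @export
kernel_weights <- function(t, t0, config) {
  stopifnot(inherits(config, "lp_config"))
  h <- config$bandwidth
  if (is.null(h)) stop("`config` has no bandwidth set", call. = FALSE)
  w <- .kernel_fun(config$kernel)((as.numeric(t) - t0) / h) / h
  if (all(w == 0)) {
    stop(sprintf(paste("degenerate neighborhood at t0 = %g: all kernel",
                       "weights are zero; increase the bandwidth"), t0),
         call. = FALSE)
  }
  w
}

# One row of the smoother: first row of (T'WT)^{-1} T'W at center t0.
# Adds a tiny ridge when the local system is ill-conditioned.
.smoother_row <- function(t, t0, p, w) {
  Tm <- outer(t - t0, 0:p, `^`)
  Tw <- Tm * w
  A <- crossprod(Tm, Tw)
  if (!all(is.finite(A)) ||
      kappa(A, exact = FALSE) > 1e12) {
    A <- A + 1e-10 * diag(p + 1)
  }
  sol <- tryCatch(solve(A, t(Tw)), error = function(e) NULL)
  if (is.null(sol)) {
    stop(sprintf(paste("singular local polynomial system at t0 = %g;",
                       "increase the bandwidth or reduce the degree"), t0),
         call. = FALSE)
  }
  sol[1L, ]
}

#' Local polynomial smoother matrix
#'
#' Builds the n x n linear smoother S whose i-th row evaluates the local
#' polynomial fit of degree p at `t0 = t[i]`:
#' `S[i, ] = e1' (T' W T)^{-1} T' W` with `T` the local design matrix and
#' `W = diag(K((t - t[i])/h))`. Rows sum to one and S reproduces
#' polynomials in `t` up to degree p exactly.
#'
#' @param t covariate vector (any order; rows are computed at each observed
#'   `t[i]` as given).
#' @param config an [lp_config()] with a set bandwidth.
#' @return An object of class `smoother_matrix`: list with the matrix `S`,
#'   the `config` used and `t`.
#' @export
smoother_matrix <- function(t, config) {
  stopifnot(inherits(config, "lp_config"))
  t <- as.numeric(t)
  n <- length(t)
  h <- config$bandwidth
  if (is.null(h)) stop("`config` has no bandwidth set", call. = FALSE)
  p <- config$degree
  kern <- .kernel_fun(config$kernel)
  S <- NULL
  if (p == 1L) {
    # vectorized local-linear weights:
    # S_ij = w_ij (s2_i - d_ij s1_i) / (s0_i s2_i - s1_i^2), d_ij = t_j - t_i
    D <- matrix(t, n, n, byrow = TRUE) - t
    W <- kern(D / h) / h
    if (any(rowSums(W) == 0)) {
      bad <- t[which(rowSums(W) == 0)[1L]]
      stop(sprintf(paste("degenerate neighborhood at t0 = %g: all kernel",
                         "weights are zero; increase the bandwidth"), bad),
           call. = FALSE)
    }
    s0 <- rowSums(W)
    s1 <- rowSums(W * D)
    s2 <- rowSums(W * D * D)
    den <- s0 * s2 - s1^2
    ok <- is.finite(den) & abs(den) > 1e-300 * pmax(s0 * s2, 1)
    S <- (W * (s2 - D * s1)) / den  # den recycles down columns = per row
    if (!all(ok)) {
      for (i in which(!ok)) {
        S[i, ] <- .smoother_row(t, t[i], p, W[i, ])
      }
    }
  } else {
    S <- matrix(0, n, n)
    for (i in seq_len(n)) {
      w <- kern((t - t[i]) / h) / h
      if (all(w == 0)) {
        stop(sprintf(paste("degenerate neighborhood at t0 = %g: all kernel",
                           "weights are zero; increase the bandwidth"),
                     t[i]), call. = FALSE)
      }
      S[i, ] <- .smoother_row(t, t[i], p, w)
    }
  }
  structure(list(S = S, config = config, t = t), class = "smoother_matrix")
}

#' @export
print.smoother_matrix <- function(x, ...) {
  cat(sprintf(
    "Local polynomial smoother: n = %d, degree = %d, h = %g, kernel = %s\n",
    nrow(x$S), x$config$degree, x$config$bandwidth, x$config$kernel))
  invisible(x)
}

#' @export
as.matrix.smoother_matrix <- function(x, ...) x$S

#' Partial residuals with respect to a smoother matrix
#'
#' Applies `(I - S)` to both the design matrix and the synthetic response,
#' removing the nonparametric trend before the penalized least-squares step:
#' `Xtilde = (I - S) X`, `ytilde = (I - S) ystar`.
#'
#' @param S a [smoother_matrix()] (or a plain n x n matrix).
#' @param X n x k design matrix of the parametric covariates.
#' @param ystar a [synthetic_response()] or a numeric response vector.
#' @return An object of class `partial_residuals` with fields `Xtilde` and
#'   `ytilde`.
#' @export
partial_residuals <- function(S, X, ystar) {
  Sm <- if (inherits(S, "smoother_matrix")) S$S else as.matrix(S)
  y <- if (inherits(ystar, "synthetic_response")) ystar$ystar
       else as.numeric(ystar)
  X <- as.matrix(X)
  if (nrow(X) != nrow(Sm) || length(y) != nrow(Sm)) {
    stop("dimensions of S, X and ystar do not conform", call. = FALSE)
  }
  structure(list(Xtilde = X - Sm %*% X,
                 ytilde = as.numeric(y - Sm %*% y)),
            class = "partial_residuals")
}
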