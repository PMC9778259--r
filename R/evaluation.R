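#' Coefficient root mean squared error
#'
#' `sqrt(k^{-1} (beta - betahat)' (beta - betahat))`. The benchmark tables
#' report this rooted form; the unrooted quadratic form is available as
#' [coefficient_mse()].
#'
#' @param beta_true,beta_hat coefficient vectors of equal length.
#' @export
coefficient_rmse <- function(beta_true, beta_hat) {
  if (length(beta_true) != length(beta_hat)) {
    stop("coefficient vectors must have equal length", call. = FALSE)
  }
  sqrt(mean((beta_true - beta_hat)^2))
}

#' Coefficient mean squared error (unrooted quadratic form)
#'
#' `k^{-1} (beta - betahat)' (beta - betahat)`, the literal quadratic form;
#' see [coefficient_rmse()] for the rooted version used in the tables.
#'
#' @inheritParams coefficient_rmse
#' @export
coefficient_mse <- function(beta_true, beta_hat) {
  coefficient_rmse(beta_true, beta_hat)^2
}

#' Coefficient of determination
#'
#' `1 - RSS/TSS` of the fitted values against a response vector. In the
#' simulation engine this is evaluated against the synthetic-response
#' vector used in fitting.
#'
#' @param y response vector (non-constant, length >= 2).
#' @param yhat fitted values.
#' @export
r_squared <- function(y, yhat) {
  if (length(y) < 2 || var(y) == 0) {
    stop("R-squared is undefined for a constant response", call. = FALSE)
  }
  1 - sum((y - yhat)^2) / sum((y - mean(y))^2)
}

#' Variable-selection confusion metrics
#'
#' Cross-classifies the true zero/nonzero pattern against the estimated
#' one: `a` = true nonzeros selected, `b` = true nonzeros missed,
#' `c` = true zeros selected, `d` = true zeros dropped. Derived rates:
#' `sens = a/(a+b)`, `spec = d/(c+d)`, `acc = (a+d)/k`, and the G-score
#' `g = sqrt(sens * spec)` (geometric mean). An empty denominator yields a
#' 0 rate with a warning.
#'
#' @param beta_true true coefficient vector.
#' @param beta_hat estimated coefficient vector.
#' @param zero_tol magnitude below which an estimate counts as zero.
#'   Coordinate descent produces exact zeros, so the default `1e-8` only
#'   guards against numerical fuzz; ridge never triggers it.
#' @return List of class `selection_metrics` with counts `a`, `b`, `c`,
#'   `d` and rates `sens`, `spec`, `acc`, `g`.
#' @export
selection_confusion <- function(beta_true, beta_hat, zero_tol = 1e-8) {
  if (length(beta_true) != length(beta_hat)) {
    stop("coefficient vectors must have equal length", call. = FALSE)
  }
  tn <- beta_true != 0
  en <- abs(beta_hat) > zero_tol
  a <- sum(tn & en)
  b <- sum(tn & !en)
  cc <- sum(!tn & en)
  d <- sum(!tn & !en)
  sens <- if (a + b > 0) a / (a + b) else {
    warning("no true nonzero coefficients; sensitivity set to 0",
            call. = FALSE)
    0
  }
  spec <- if (cc + d > 0) d / (cc + d) else {
    warning("no true zero coefficients; specificity set to 0",
            call. = FALSE)
    0
  }
  structure(list(a = a, b = b, c = cc, d = d, sens = sens, spec = spec,
                 acc = (a + d) / length(beta_true),
                 g = sqrt(sens * spec)),
            class = "selection_metrics")
}

#' Mean squared error of an estimated curve
#'
#' `n^{-1} sum (f(t_i) - fhat(t_i))^2` over the evaluation points.
#'
#' @param f_true true curve values.
#' @param f_hat estimated curve values.
#' @export
curve_mse <- function(f_true, f_hat) {
  if (length(f_true) != length(f_hat)) {
    stop("curve vectors must have equal length", call. = FALSE)
  }
  mean((f_true - f_hat)^2)
}

#' Relative curve MSE across methods
#'
#' For method i among nm methods, the average of the pairwise ratios
#' `MSE_i / MSE_j` over `j != i`. With the default divisor `nm - 1` (the
#' number of ratio terms) identical MSEs give exactly 1 for every method;
#' `literal = TRUE` divides by `nm` instead, matching the formula as
#' printed.
#'
#' @param mse_by_method positive MSE scores, one per method, `nm >= 2`.
#' @param literal use `nm` as the divisor rather than `nm - 1`.
#' @export
relative_mse <- function(mse_by_method, literal = FALSE) {
  nm <- length(mse_by_method)
  if (nm < 2) stop("need at least two methods", call. = FALSE)
  if (any(!is.finite(mse_by_method)) || any(mse_by_method <= 0)) {
    stop("relative MSE is undefined for non-positive MSE values",
         call. = FALSE)
  }
  div <- if (literal) nm else nm - 1
  vapply(seq_len(nm), function(i) {
    sum(mse_by_method[i] / mse_by_method[-i]) / div
  }, numeric(1))
}

#' Per-coefficient selection ratio over replicates
#'
#' Fraction of replicates in which coefficient `j` is estimated nonzero
#' (magnitude above `zero_tol`).
#'
#' @param replicate_betas list of estimated coefficient vectors, one per
#'   replicate.
#' @param j coefficient index.
#' @param zero_tol zero threshold.
#' @export
selection_ratio <- function(replicate_betas, j, zero_tol = 1e-8) {
  if (!length(replicate_betas)) stop("empty replicate list", call. = FALSE)
  mean(vapply(replicate_betas,
              function(b) abs(b[j]) > zero_tol, logical(1)))
}
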