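#' Construct a right-censored sample
#'
#' Bundles the observed times `y` and the censoring indicators `delta`
#' (1 = event observed, 0 = right-censored) after validating them. This is
#' the `(y_i, delta_i)` pair produced by observing `y = min(z, c)` where `z`
#' is the latent complete response and `c` the censoring time.
#'
#' @param y numeric vector of observed times (finite).
#' @param delta vector of censoring indicators; every element must be
#'   exactly 0 or 1.
#' @return An object of class `censored_sample` with fields `y`, `delta`
#'   and `n`.
#' @examples
#' censored_sample(c(1, 2, 3), c(1, 0, 1))
#' @export
censored_sample <- function(y, delta) {
  y <- as.numeric(y)
  delta <- as.numeric(delta)
  if (length(y) != length(delta)) {
    stop("`y` and `delta` must have the same length", call. = FALSE)
  }
  if (length(y) < 2L) {
    stop("a censored sample needs at least 2 observations", call. = FALSE)
  }
  if (!all(is.finite(y))) {
    stop("all observed times in `y` must be finite", call. = FALSE)
  }
  if (!all(delta %in% c(0, 1))) {
    stop("`delta` may only contain 0 (censored) and 1 (uncensored)",
         call. = FALSE)
  }
  structure(list(y = y, delta = as.integer(delta), n = length(y)),
            class = "censored_sample")
}

#' @export
print.censored_sample <- function(x, ...) {
  cat(sprintf("Right-censored sample: n = %d, censored = %d (%.1f%%)\n",
              x$n, sum(x$delta == 0), 100 * mean(x$delta == 0)))
  invisible(x)
}

#' Right-continuous step distribution function
#'
#' Container for an estimated censoring-time distribution G: a
#' right-continuous step function that is 0 before the first jump. Used to
#' hold the reversed Kaplan-Meier estimate returned by [fit_censoring_km()].
#'
#' @param jump_times sorted vector of distinct jump locations.
#' @param cdf_values values of G at and after each jump; non-decreasing,
#'   each in \[0, 1\].
#' @return An object of class `step_survival`.
#' @export
step_survival <- function(jump_times, cdf_values) {
  jump_times <- as.numeric(jump_times)
  cdf_values <- as.numeric(cdf_values)
  if (length(jump_times) != length(cdf_values)) {
    stop("`jump_times` and `cdf_values` must have the same length",
         call. = FALSE)
  }
  if (is.unsorted(jump_times, strictly = TRUE) && length(jump_times) > 1L) {
    stop("`jump_times` must be strictly increasing", call. = FALSE)
  }
  if (length(cdf_values) &&
      (any(cdf_values < -1e-12) || any(cdf_values > 1 + 1e-12) ||
       is.unsorted(cdf_values))) {
    stop("`cdf_values` must be non-decreasing and lie in [0, 1]",
         call. = FALSE)
  }
  structure(list(jump_times = jump_times,
                 cdf_values = pmin(pmax(cdf_values, 0), 1)),
            class = "step_survival")
}

#' Evaluate a censoring distribution function
#'
#' Evaluates G at the points `t`, right-continuously, returning 0 below the
#' first jump. `G` may be a [step_survival()] object or an ordinary function
#' (a known parametric censoring distribution).
#'
#' @param G a `step_survival` object or a function of one argument.
#' @param t numeric vector of evaluation points.
#' @return Numeric vector of G(t) values.
#' @export
censoring_cdf <- function(G, t) {
  if (is.function(G)) return(G(t))
  stopifnot(inherits(G, "step_survival"))
  if (length(G$jump_times) == 0L) return(rep(0, length(t)))
  f <- stepfun(G$jump_times, c(0, G$cdf_values), right = FALSE)
  f(t)
}

#' Reversed Kaplan-Meier estimate of the censoring distribution
#'
#' Product-limit estimate of the distribution G of the censoring times,
#' obtained by treating the right-censored observations (`delta = 0`) as the
#' events. With the order statistics `y_(1) <= ... <= y_(n)`,
#' `Ghat(t) = 1 - prod_i ((n - i) / (n - i + 1))^(I[y_(i) <= t, delta_(i) = 0])`.
#' At tied times the uncensored observations are ranked before the censored
#' ones, so an uncensored observation never "sees" a censoring jump at its
#' own time.
#'
#' @param sample a [censored_sample()].
#' @return A [step_survival()] object; jump times are the distinct censored
#'   observation times. With no censored observations the estimate is
#'   identically 0.
#' @examples
#' fit_censoring_km(censored_sample(c(1, 2, 3), c(1, 0, 1)))
#' @export
fit_censoring_km <- function(sample) {
  stopifnot(inherits(sample, "censored_sample"))
  n <- sample$n
  ord <- order(sample$y, -sample$delta)
  ys <- sample$y[ord]
  ds <- sample$delta[ord]
  i <- seq_len(n)
  fac <- ifelse(ds == 0L, (n - i) / (n - i + 1), 1)
  gbar <- cumprod(fac)
  cens <- ds == 0L
  if (!any(cens)) return(step_survival(numeric(0), numeric(0)))
  jt <- ys[cens]
  gv <- 1 - gbar[cens]
  last <- !duplicated(jt, fromLast = TRUE)  # value after all tied jumps
  step_survival(jt[last], gv[last])
}

#' Synthetic-data transformation of a censored response
#'
#' Transforms the observed pairs `(y_i, delta_i)` into synthetic responses
#' `ystar_i = delta_i * y_i / (1 - G(y_i))`: censored observations are mapped
#' to exactly 0 and uncensored ones are inflated by the inverse estimated
#' probability of remaining uncensored, so that the synthetic response has
#' the same conditional mean as the latent complete response.
#'
#' If `1 - G(y_i)` falls at or below `guard` for an uncensored observation
#' (possible when the largest observation is censored and ties occur), the
#' smallest positive value of `1 - G` over the sample is substituted and the
#' event counted in `truncation_count`.
#'
#' @param sample a [censored_sample()].
#' @param G the censoring distribution: a [step_survival()] (typically from
#'   [fit_censoring_km()]) or a function.
#' @param guard smallest denominator accepted before truncation kicks in.
#' @return An object of class `synthetic_response` with fields `ystar`,
#'   `ghat` (the `G` used) and `truncation_count`.
#' @examples
#' s <- censored_sample(c(1, 2, 3), c(1, 0, 1))
#' synthetic_response(s, fit_censoring_km(s))$ystar  # 1, 0, 6
#' @export
synthetic_response <- function(sample, G, guard = .Machine$double.eps) {
  stopifnot(inherits(sample, "censored_sample"))
  gbar <- 1 - censoring_cdf(G, sample$y)
  bad <- sample$delta == 1L & gbar <= guard
  pos <- gbar[gbar > guard]
  repl <- if (length(pos)) min(pos) else 1 / sample$n
  denom <- ifelse(bad, repl, gbar)
  ystar <- ifelse(sample$delta == 0L, 0, sample$y / denom)
  structure(list(ystar = ystar, ghat = G,
                 truncation_count = sum(bad)),
            class = "synthetic_response")
}

#' Monte-Carlo check of mean preservation under a known censoring law
#'
#' With a known censoring distribution G, the synthetic-data transform
#' satisfies `E(ystar | x, t) = E(z | x, t)`. This utility draws `n_mc`
#' latent pairs `(z, c)` from `generator`, applies the transform with the
#' known `G`, and reports the absolute deviation between the empirical means
#' of `ystar` and of the latent complete response `z`, together with its
#' Monte-Carlo standard error.
#'
#' @param n_mc number of Monte-Carlo draws.
#' @param generator a `function(n)` returning `list(z = , c = )` with `c`
#'   drawn from the distribution `G`.
#' @param G the known censoring distribution (function or `step_survival`).
#' @return List with `deviation` (|mean(ystar) - mean(z)|) and `mc_se`
#'   (standard error of the mean of `ystar - z`).
#' @export
mean_preservation_error <- function(n_mc, generator, G) {
  draws <- generator(n_mc)
  z <- draws$z
  cc <- draws$c
  y <- pmin(z, cc)
  delta <- as.numeric(z <= cc)
  gbar <- pmax(1 - censoring_cdf(G, y), .Machine$double.eps)
  ystar <- delta * y / gbar
  list(deviation = abs(mean(ystar) - mean(z)),
       mc_se = sd(ystar - z) / sqrt(n_mc))
}
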