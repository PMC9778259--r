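#' Read a right-censored dataset from CSV
#'
#' Loads a CSV with a header row and validates the column roles: one
#' observed-time column, one 0/1 status column (1 = event observed,
#' 0 = right-censored), a set of parametric covariate columns, and exactly
#' one nonparametric covariate column. This matches the layout of clinical
#' survival exports such as the hepatocellular carcinoma data (log overall
#' survival as the response, 12 clinical/expression covariates, age as the
#' nonparametric covariate).
#'
#' @param path CSV file path.
#' @param time name of the observed-time column.
#' @param status name of the 0/1 censoring-indicator column.
#' @param covariates character vector of parametric covariate columns.
#' @param nonparametric name of the single nonparametric covariate column.
#' @param log_time apply `log()` to the time column before modeling (for
#'   survival times modeled on the log scale).
#' @return List with `sample` (a [censored_sample()]), `X` (covariate
#'   matrix), `t` (nonparametric covariate), and `censoring_level`.
#' @export
read_censored_dataset <- function(path, time, status, covariates,
                                  nonparametric, log_time = FALSE) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path),
                               call. = FALSE)
  d <- read.csv(path, check.names = FALSE)
  need <- c(time, status, covariates, nonparametric)
  missing_cols <- setdiff(need, names(d))
  if (length(missing_cols)) {
    stop(sprintf("missing column(s): %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  if (length(nonparametric) != 1L) {
    stop("exactly one nonparametric covariate column is required",
         call. = FALSE)
  }
  for (cn in need) {
    if (!is.numeric(d[[cn]])) {
      stop(sprintf("column `%s` contains non-numeric values", cn),
           call. = FALSE)
    }
  }
  st <- d[[status]]
  if (!all(st %in% c(0, 1))) {
    stop(sprintf("status column `%s` must contain only 0 and 1", status),
         call. = FALSE)
  }
  y <- d[[time]]
  if (log_time) {
    if (any(y <= 0)) {
      stop("log_time requires strictly positive times", call. = FALSE)
    }
    y <- log(y)
  }
  list(sample = censored_sample(y, st),
       X = as.matrix(d[covariates]),
       t = as.numeric(d[[nonparametric]]),
       censoring_level = mean(st == 0))
}

#' Serialize a fit to JSON
#'
#' Writes the coefficients, the selected tuning values, the degrees of
#' freedom and the residual variance of a `penplm_fit` as JSON.
#'
#' @param fit a `penplm_fit`.
#' @param path output file.
#' @export
write_fit_json <- function(fit, path) {
  stopifnot(inherits(fit, "penplm_fit"))
  jsonlite::write_json(
    list(penalty = fit$spec$family,
         beta = fit$beta,
         lambda = fit$lambda,
         h = fit$h,
         df = fit$df,
         sigma2 = fit$sigma2,
         n_nonzero = sum(fit$beta != 0),
         degree = fit$config$degree,
         kernel = fit$config$kernel),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write the fitted nonparametric curve to CSV
#'
#' Two columns: the nonparametric covariate `t` and the fitted `fhat`.
#'
#' @param fit a `penplm_fit`.
#' @param path output file.
#' @export
write_curve_csv <- function(fit, path) {
  stopifnot(inherits(fit, "penplm_fit"))
  ord <- order(fit$t)
  write.csv(data.frame(t = fit$t[ord], fhat = fit$fhat[ord]), path,
            row.names = FALSE)
  invisible(path)
}

#' Generate small CSV fixtures with known ground truth
#'
#' Writes a small dataset (n <= 60) plus a sidecar JSON describing the
#' ground truth. All values are synthetic. Kinds:
#' \describe{
#'   \item{tiny-censored}{the 3-point worked example `y = (1, 2, 3)`,
#'     `delta = (1, 0, 1)` with its hand-computable censoring estimate.}
#'   \item{scenario1-small, scenario2-small}{n = 60 draws of the benchmark
#'     scenarios (k = 15, censoring level 10%).}
#'   \item{hepato-shaped}{a synthetic dataset mimicking the column layout
#'     of the hepatocellular carcinoma study: 12 parametric covariates,
#'     age as the nonparametric covariate, log survival time, status, and
#'     a 37% censoring level. Synthetic values only, not the real data.}
#' }
#'
#' @param kind fixture kind (see Details).
#' @param seed RNG seed.
#' @param dir output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
make_fixture <- function(kind = c("tiny-censored", "scenario1-small",
                                  "scenario2-small", "hepato-shaped"),
                         seed = 1L, dir = ".") {
  kind <- match.arg(kind)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  csv <- file.path(dir, paste0(kind, ".csv"))
  side <- file.path(dir, paste0(kind, ".json"))
  if (kind == "tiny-censored") {
    d <- data.frame(y = c(1, 2, 3), status = c(1, 0, 1))
    write.csv(d, csv, row.names = FALSE)
    jsonlite::write_json(
      list(kind = kind, synthetic = TRUE,
           ghat_jump_times = 2, ghat_values = 0.5,
           ystar = c(1, 0, 6)),
      side, auto_unbox = TRUE, digits = NA)
  } else if (kind %in% c("scenario1-small", "scenario2-small")) {
    sc <- if (kind == "scenario1-small") 1 else 2
    dat <- generate_scenario(scenario_config(sc, n = 60, k = 15,
                                             cl = 0.1, seed = seed))
    d <- data.frame(time = dat$y, status = dat$delta, dat$X, t = dat$t)
    names(d) <- c("time", "status", paste0("x", 1:15), "t")
    write.csv(d, csv, row.names = FALSE)
    jsonlite::write_json(
      list(kind = kind, synthetic = TRUE, scenario = sc, seed = seed,
           beta_true = dat$beta_true,
           n_nonzero = sum(dat$beta_true != 0),
           f_true = dat$f_true,
           censoring_level_target = 0.1),
      side, auto_unbox = TRUE, digits = NA)
  } else { # hepato-shaped
    set.seed(seed)
    n <- 60
    covs <- c("RFS", "Gen", "HB", "ALT", "AST", "AFP", "TS", "TNM",
              "BCLC", "CXCT", "CXCP", "CXCN")
    X <- matrix(rnorm(n * 12), n, 12, dimnames = list(NULL, covs))
    age <- sort(runif(n, 30, 80))
    f_age <- sin((age - 30) / 15)
    beta <- c(0.4, 0.2, 0, 0.1, -0.3, 0, -0.2, -0.4, -0.3, 0.1, 0, 0)
    z <- as.numeric(X %*% beta) + f_age + rnorm(n, 0, 0.5)
    cc <- calibrate_censoring(z, 0.37)
    log_os <- pmin(z, cc)
    status <- as.integer(z <= cc)
    d <- data.frame(X, age = age, log_os = log_os, status = status)
    write.csv(d, csv, row.names = FALSE)
    jsonlite::write_json(
      list(kind = kind, synthetic = TRUE, seed = seed,
           beta_true = beta, censoring_level_target = 0.37,
           censoring_level_empirical = mean(status == 0),
           note = paste("synthetic stand-in mimicking the hepatocellular",
                        "carcinoma column layout; not the real data")),
      side, auto_unbox = TRUE, digits = NA)
  }
  invisible(c(csv, side))
}
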