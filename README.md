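# penplm

Penalized local-polynomial estimation and variable selection for
**right-censored partially linear models**.

Survival-type studies often fit the semiparametric model

```
z_i = x_i' beta + f(t_i) + eps_i,        i = 1, ..., n
```

— a linear part in k covariates plus an unknown smooth function of one
covariate (age, say) — but observe the response only as the censored pair
`y_i = min(z_i, c_i)`, `delta_i = I(z_i <= c_i)`. Ignoring the censoring
biases every downstream estimate; with many candidate covariates one also
wants the fit to select the relevant ones. `penplm` addresses both at
once:

1. **Synthetic data.** The censoring distribution G is estimated by the
   reversed Kaplan–Meier product-limit estimator (censored observations
   are the "events") and the response is transformed to
   `ystar_i = delta_i * y_i / (1 - Ghat(y_i))`, which zeroes censored
   observations and inflates uncensored ones so that
   `E(ystar | x, t) = E(z | x, t)`.
2. **Local polynomial partial residuals.** A kernel-weighted local
   polynomial smoother matrix `S` removes the nonparametric trend:
   `Xtilde = (I - S) X`, `ytilde = (I - S) ystar`.
3. **Penalized least squares.** `beta` minimizes
   `||ytilde - Xtilde b||^2 + P_lambda(b)` with ridge, lasso, adaptive
   lasso, SCAD, MCP or elasticnet penalties (closed form for ridge,
   coordinate descent with the family's thresholding operator otherwise),
   and `fhat = S (ystar - X beta)`. The pair `(lambda, h)` is selected
   jointly by the corrected AIC
   `log(sigma^2) + 1 + 2 (df + 1) / (n - df - 2)`.

The package also ships the benchmark simulation engine (two sparse
coefficient scenarios, Gaussian censoring calibrated to a target level),
the standard evaluation metrics (coefficient RMSE, R², the
selection confusion matrix with its G-score, curve MSE and relative MSE),
and a small command line.

## Worked example

```r
library(penplm)

d <- generate_scenario(scenario_config(2, n = 150, k = 15, cl = 0.1,
                                       seed = 1))
fit <- tune_plm(censored_sample(d$y, d$delta), d$X, d$t,
                family = "adaptive_lasso")
fit
#> Right-censored partially linear model fit
#>   n = 150, k = 15, censored = 12.0%
#>   penalty = adaptive_lasso, lambda = 4.371, h = 0.4376
#>   df = 13.00, sigma2 = 3.882, nonzero = 13

coefficient_rmse(d$beta_true, fit$beta)
#> [1] 0.1169171
selection_confusion(d$beta_true, fit$beta)$acc
#> [1] 0.8
```

The printed fit reports the AICc-selected shrinkage parameter and
bandwidth, the degrees of freedom (nonzero-coefficient count for the
sparse families), and the partial-residual residual variance. Here the
adaptive lasso keeps 13 of 15 covariates — all 10 true signals (the
blocks at positions 1–5 and 11–15) plus 3 spurious ones — for a selection
accuracy of 0.8 and a coefficient RMSE of 0.12 against the generating
vector. `fit$fhat` holds the estimated smooth component at the observed
`t`; `predict(fit, Xnew, tnew)` evaluates the fit elsewhere.

Real datasets load from CSV via `read_censored_dataset()` (one time
column, one 0/1 status column, the parametric covariates, and a single
nonparametric covariate; `log_time = TRUE` models log survival time), and
the same pipeline runs from the shell:

```sh
inst/cli/penplm fit --data export.csv --time os --status status \
  --covariates RFS,Gen,HB --np age --log-time --penalty scad --out fit
inst/cli/penplm simulate --scenario 2 --n 50 --k 15 --cl 0.1 \
  --reps 10 --seed 1 --out table.csv
```

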