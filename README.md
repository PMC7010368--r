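# tailqr

Density-weighted quantile regression for high conditional quantiles of
heavy-tailed responses.

## The problem

Extreme events — record snowfalls, floods, emission spikes — live in the
upper tail of a response distribution, where ordinary least squares says
nothing useful: the conditional *mean* of a heavy-tailed response is a poor
guide to its 95th or 99th percentile. Linear quantile regression estimates
the conditional quantile
`Q_y(τ | x) = x'β(τ)` directly by minimizing the check (pinball) loss

```
β̂(τ) = argmin_β Σ_i ρ_τ(y_i − x_i'β),   ρ_τ(u) = u (τ − 1{u < 0}),
```

a linear program. At high τ with heavy tails, however, few observations
carry information about the quantile surface, and the classical estimator
becomes volatile. `tailqr` implements a *weighted* check-loss estimator

```
β̂_w(τ) = argmin_β Σ_i w_i(x_i, τ) ρ_τ(y_i − x_i'β),
```

with the weight taken as the conditional density of the response at its own
τth conditional quantile, `w_i = f(ξ(τ | x_i) | x_i)`: observations whose
response is locally most informative about the quantile get the most say.
In simulations from a heavy-tailed bivariate Pareto law — where the true
conditional quantile line and the ideal weights are known in closed form —
the density-weighted estimator is substantially more efficient than the
unweighted one at high quantile levels.

The package provides:

* `fit_quantile_regression()` — weighted/unweighted check-loss fits via an
  interior-point LP solver with exact vertex polishing;
* `density_weights()` — feasible weights by kernel conditional-density
  estimation (whitened multivariate normal kernel, conditional-cdf
  inversion), plus `norm_weights()` and closed-form `oracle_weights()`;
* `gpd_mle()`, `gpd_gof_tests()` — generalized Pareto peaks-over-threshold
  tail modelling with parametric-bootstrap Kolmogorov–Smirnov,
  Anderson–Darling and Cramér–von Mises tests;
* `bvpareto_sample()` and friends — a bivariate Pareto simulator with
  closed-form conditional quantiles and densities;
* `run_benchmark()` — the Monte Carlo SMSE/SEFF efficiency study;
* `run_pipeline()` / `load_observations()` / `make_fixtures()` — an
  end-to-end peaks-over-threshold analysis for tabular CSV data, plus a thin
  command-line front end in `inst/cli/tailqr.R`.

## Worked example

Simulate heavy-tailed data with a known conditional-quantile line
(intercept 1, slope 1.1147 at τ = 0.95), then fit the unweighted and the
density-weighted estimator:

```r
library(tailqr)
model <- bvpareto_model(3)
obs   <- bvpareto_sample(300, model, seed = 2026)

fit_r <- fit_quantile_regression(obs, tau = 0.95)
fit_w <- fit_quantile_regression(obs, tau = 0.95,
                                 oracle_weights(obs, 0.95, model))
fit_r
#> Quantile regression fit, tau = 0.95 (uniform weights, optimal)
#> (Intercept)           x
#>  0.02623819  1.64834060
#> Objective (weighted check loss): 24.35905
fit_w
#> Quantile regression fit, tau = 0.95 (density_oracle weights, optimal)
#> (Intercept)           x
#>   0.3244908   1.3993011
#> Objective (weighted check loss): 1.560655
bvpareto_true_line(0.95, model)
#> intercept     slope
#>  1.000000  1.114743
```

On this draw the weighted fit's slope (1.399) is closer to the true 1.115
than the unweighted fit's (1.648). One sample proves nothing, so
`run_benchmark()` repeats this over many replicates and reports the
simulation efficiency `SEFF = SMSE(regular) / SMSE(weighted)` (values above
1 favor the weighted estimator; the integrated squared error against the
true line is accumulated in closed form over x in [1, N]):

```r
b <- run_benchmark(m = 100, n = 300, alpha = 3,
                   tau_grid = c(0.95, 0.97), seed = 7)
round(b$seff, 4)
#>                 tau_0.95 tau_0.97
#> regular           1.0000   1.0000
#> weighted_oracle   1.3390   0.9424
#> weighted_norm     1.3552   0.9517
```

At m = 100 these ratios are still noisy (the errors being averaged are
themselves heavy-tailed); the package's acceptance script runs the full
m = 1000 design. For a real tabular analysis, `run_pipeline()` applies a
response threshold, fits a GPD to the excesses with bootstrap
goodness-of-fit tests, fits least-squares, regular and weighted quantile
models at each τ, and reports the Relative R(τ) fit comparison; see
`?run_pipeline` and the vignette.

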