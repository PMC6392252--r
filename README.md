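# iccmix

High-dimensional finite mixture linear regression, estimated by the
imputation-conditional consistency (ICC) algorithm with per-component
SIS-MCP sparse fits, average-BIC selection of the number of components,
and consensus-clustering aggregation.

## The problem

In drug-sensitivity modeling (and many other biomedical regressions) the
population is *heterogeneous*: different latent subgroups of samples — say,
molecular subtypes of cancer cell lines — respond to different features,
and a single sparse regression both blurs the subgroups and selects a
compromise gene set. With expression data the feature dimension `p` (10^3
to 10^4 genes) far exceeds the sample count `n` (hundreds of cell lines),
so classical mixture-regression EM is unusable.

`iccmix` fits the mixture of sparse Gaussian regressions

y_i ~ Σ_k π_k · N(β_k0 + x_iᵀβ_k, σ_k²),  k = 1..K,

simultaneously clustering the samples into K regression regimes and
selecting the relevant features *within each regime*. Estimation
alternates stochastic imputation of the memberships from their posterior
(I-step) with blockwise consistent re-estimation of each component
(CC-step): mixing proportions by counts, coefficients by sure independence
screening + MCP-penalized least squares, residual scale from the
within-cluster residuals. The imputed partitions and parameter estimates
form two interleaved Markov chains; after burn-in, the per-iteration BIC
values are averaged to choose K, the sampled partitions are aggregated
into one consensus clustering (co-assignment dissimilarity +
average-linkage hierarchical clustering), and variables are selected per
consensus cluster. The target audience is anyone fitting subgroup-specific
sparse regressions: statistical genomics, pharmacogenomics, or any
small-n-large-p regression with suspected population structure.

See `vignettes/mixture-regression-icc.Rmd` for the model, the algorithmic
choices and their rationale, and known limitations.

## Worked example

Simulate a two-component design (60 samples per component, 100 features,
three true coefficients each, residual sd 1), fit with a known K = 2, and
inspect the result:

```r
library(iccmix)

cfg <- sim_config(n_per_component = c(60, 60), p = 100)
d   <- simulate_mixreg(cfg, seed = 7)

fit <- icc_mixreg(d$X, d$y, K = 2, iters = 100, burn_in = 30, seed = 7)
fit$model
#> Mixture regression model with K = 2 components
#>   [1] pi = 0.517, sigma = 1.064, support = {1, 2, 3}
#>   [2] pi = 0.483, sigma = 0.883, support = {1, 4, 5}
```

The generator placed the true supports at {1, 2, 3} and {1, 4, 5} (feature
1 shared), with all coefficients 3 and σ = 1: both supports are recovered
exactly, and the fitted σ̂ are near 1. Component labels are arbitrary —
match them to a reference before comparing:

```r
sel <- selection_metrics(fit$model, d$truth, p = cfg$p)
sel[, c("component", "fsr", "nsr", "l2_error")]
#>   component fsr nsr  l2_error
#> 1         1   0   0 0.8612503
#> 2         2   0   0 0.5011349
```

`fsr`/`nsr` are the false and negative selection rates FP/(TP+FP) and
FN/(TP+FN) — here 0: no spurious and no missed features — and `l2_error`
is ‖β̂_k − β_k‖₂ including the intercept (at n = 60 per component the
coefficient noise is visible; it shrinks with the component size). Choosing
K when it is unknown, and predicting for new samples:

```r
ks <- select_K(d$X, d$y, K_grid = 1:3, iters = 100, burn_in = 30, seed = 7)
ks$table
#>   K  avg_bic        se   ok
#> 1 1 643.3086 0.0000000 TRUE
#> 2 2 504.1068 0.4597013 TRUE
#> 3 3 508.5032 1.4479140 TRUE
ks$selected
#> [1] 2

pr <- predict(fit, d$X, y = d$y, mode = "posterior")
pr
#> Prediction report (mode = posterior, n = 120)
#>   corr(Y, Yhat) = 0.982, RMSE = 0.903
```

The average BIC is minimized at the true K = 2 (the K = 1 entry is the BIC
of a single SIS-MCP regression). The `"posterior"` prediction mode assigns
each sample to the component maximizing its membership posterior evaluated
with the observed response, then predicts from that component's
regression; `"mixture"` and `"prior"` modes need no response access.

A thin command-line wrapper over the same functions is installed at
`inst/cli/iccmix.R` (subcommands `simulate`, `fit`, `select-k`,
`predict`).

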