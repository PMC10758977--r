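# cmclogit

Copula-based Markov chain logistic regression for binomial time series.

## The problem

Epidemiological surveillance often produces *binomial* time series: at each
time point `t` one observes a success count `y_t` out of `n_t` trials (for
example, positive influenza specimens out of all specimens tested that
month), together with continuous covariates `X_t` (temperature, rainfall,
humidity, ...). Two features must be modelled at once:

1. **the covariate effect** — the success probability follows a logistic
   regression,
   `logit(π_t) = β₀ + β₁ x_{1t} + ... + β_d x_{dt}`, so
   `Y_t | X_t ~ Binomial(n_t, π_t)`;
2. **serial dependence** — adjacent observations are not independent.
   Classical binomial AR(1)/INAR(1) constructions allow only positive
   correlation and do not accommodate covariates naturally; GLMM-style
   approaches push the dependence into a latent process.

`cmclogit` instead models the joint law of each adjacent pair
`(Y_t, Y_{t-1})` through a bivariate Archimedean copula `C(·, ·; α)`
(Clayton, Gumbel or Frank) over the binomial-logistic margins. Because the
margins are discrete, the joint pmf is the copula **volume over the
CDF-jump rectangle**

    Pr(Y_t = y_t, Y_{t-1} = y_{t-1})
      = C(u_t, v_t) − C(u_t, v_t⁻) − C(u_t⁻, v_t) + C(u_t⁻, v_t⁻)

with `u_t = F(y_t | X_t; β)`, `u_t⁻ = F(y_t − 1 | X_t; β)` and likewise
`v_t`, `v_t⁻` at `t − 1` (with `F(−1) = 0`). The first-order Markov
property gives the exact log-likelihood

    L(β, α) = log f₁(y₁) + Σ_{t=2}^{T} [ log ΔC_t − log f_{t−1}(y_{t−1}) ]

which is maximized **simultaneously** in `(β, α)` by quasi-Newton
iterations; standard errors come from the inverse observed Fisher
information. The copula parameter `α` is the interpretable time-dependence
estimate — each family maps to Kendall's τ (Clayton `τ = α/(α+2)`, Gumbel
`τ = 1 − 1/α`, Frank via the first-order Debye function), and the families
differ in tail behaviour (Clayton: lower-tail dependence `2^{−1/α}`;
Gumbel: upper-tail `2 − 2^{1/α}`; Frank: symmetric, tail-free).

The package provides the copula machinery (CDF, density, conditional
h-function and its inverse, τ conversions, tail dependence), the
rectangle-probability likelihood and joint MLE, one-step-ahead prediction
with MSE/MAPE metrics, a forward simulator driven by the inverse
conditional copula, a Monte-Carlo parameter-recovery harness, and a CLI.

## Worked example

Simulate a Frank-copula chain at Kendall's τ = 0.5 (α ≈ 5.74) with
`β = (−2, 0.3, −0.5)`, covariates `X₁ ~ U(0,10)`, `X₂ ~ U(0,1)` and trial
counts in {200, ..., 500}, then re-estimate everything jointly:

```r
library(cmclogit)
design <- default_design("frank", tau_level = 0.5, T = 300)
series <- generate_series(design, seed = 2024)
fit <- cmc_fit(series, "frank")
print(fit)
```

```
Copula-based Markov chain logistic regression (frank copula)
            estimate      se
(Intercept) -1.99361 0.01775
x1           0.29762 0.00177
x2          -0.51496 0.01539
alpha        5.05055 0.41856
log-likelihood: -975.9347  (Kendall tau = 0.4599, converged, 85 iterations)
```

The regression coefficients are recovered to within two standard errors
and the dependence estimate `alpha = 5.05` (τ̂ = 0.46) sits 1.6 SE from the
generating α = 5.74 — a single series of length 300; the Monte-Carlo
studies below average this noise away. One-step-ahead forecasts are
conditional means under the fitted transition law:

```r
yhat <- predict(fit, series)
fit_metrics(series$y, yhat)
```

```
MSE = 43.662, MAPE = 0.0516
```

(Counts average ≈ 75 out of n ≈ 350 here, so a 5.2% mean absolute
percentage error is tight.)

A full recovery study in the published-table layout:

```r
study <- run_study(sim_design("clayton", T = 500, beta = c(-2, 0.3, -0.5),
                              alpha = 2), B = 100, seed = 301)
study_table(list(study))
```

## Command line

```sh
Rscript inst/scripts/cmclogit simulate --family clayton --tau 0.5 --T 200 --seed 7 --out series.csv
Rscript inst/scripts/cmclogit fit      --family clayton --input series.csv --out fit.json
Rscript inst/scripts/cmclogit predict  --fit fit.json --input series.csv --out pred.csv
Rscript inst/scripts/cmclogit study    --family frank --alpha 2 --T 200 --reps 100 --seed 1 --out study.csv
```

Identical arguments and `--seed` give byte-identical outputs.

## Documentation

See `vignettes/copula-markov-binomial.Rmd` for the model, its assumptions,
the numerical choices (likelihood flooring, optimizer parameterization,
h-inverse root-finding) and the limits of what the simulation studies
establish.
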