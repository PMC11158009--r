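# centime

Discrete-time survival analysis with an **event-conditional censoring
model** (CenTime) that directly estimates the time to an event — death, in
the motivating clinical setting — and remains a *consistent* estimator of
the event-time model even when every training record is right-censored.
The package is aimed at biostatisticians and methodologists who want to
study censoring mechanisms, benchmark time-to-event estimators, or fit
month-resolution survival models to tabular cohorts.

## The model

Time is discrete: a subject dies in month `t ∈ {1, …, Tmax}`. The
event-time model is a discretised Gaussian over that grid,

```
p(D = t | x) = exp( -(t - μ(x))² / 2σ² ) / Z,    Z = Σ_t exp( -(t - μ(x))² / 2σ² ),
```

with a linear location `μ(x) = b₀ + w·x` and a shared scale `σ` (months,
fixed at 12 by default). An uncensored record `(δ=1, x, t)` contributes
`log p(D = t | x)`.

The two censoring stories differ in how a censored record `(δ=0, x, c)`
arises:

* **Event-conditional (CenTime)** — the death time is drawn first, then the
  censoring time uniformly below it. Marginalising the unknown death time:

  ```
  P(C = c | x) = Σ_{t = c+1}^{Tmax}  p(D = t | x) / (t - 1)
  ```

  Both the censored and the uncensored term are consistent objectives for
  the event-model parameters, so the model is learnable from purely
  censored cohorts — the package's central property.

* **Classical** — death and censoring times are drawn independently and the
  smaller one is observed; the censored term is
  `(1/Tmax) Σ_{t>c} p(D = t | x)`, which carries no information about
  *where* above `c` the death lies. On purely censored data its optimum
  runs away toward the horizon.

Baselines included: the Cox partial likelihood (full-batch, minibatch with
an explicit skip signal for all-censored batches, and a memory-bank variant
"CoxMB" whose stored scores rescue those batches), DeepHit-style
likelihood + ranking losses, and Breslow-baseline death-time prediction
from Cox risk scores. Metrics: Harrell concordance index, MAE and RAE over
uncensored subjects.

## Worked example: learning from 100% censored data

```r
library(centime)

cfg <- generator_config(n_subjects = 500, t_max = 60, covariate_dim = 2,
                        intercept = 30, true_weights = c(5, -5), sigma = 12,
                        mechanism = "fixed_proportion", censored_fraction = 1,
                        seed = 42)
cohort <- sample_cohort(cfg)          # 500 subjects, every one censored
fit <- fit_event_model(cohort, "centime", sigma = 12)
fit
#> <event_model_fit> likelihood = centime, sigma = 12 (fixed), t_max = 60
#>   intercept: 29.26272
#>   weights:    5.469796, -4.174452
#>   mean loglik: -3.555651  (20 iterations, converged)

round(coef(fit_event_model(cohort, "classical", sigma = 12)), 2)
#> intercept        x1        x2
#>    216.66     14.71    -35.37
```

The true parameters are `(30, 5, -5)`. The event-conditional likelihood
recovers them from censoring times alone (up to sampling error ≈ σ/√n);
the classical likelihood — the matched objective for the *other* generative
mechanism — drifts far past the 60-month horizon, the inconsistency it is
known for on purely censored data. On a held-out uncensored test cohort:

```r
test <- sample_event_conditional(
  generator_config(300, t_max = 60, covariate_dim = 2, intercept = 30,
                   true_weights = c(5, -5), sigma = 12, censoring_prob = 0,
                   seed = 43))
predict_and_evaluate(fit, test)
#> <metrics_report>
#>   C-index: 0.6472  (43853 comparable pairs)
#>   MAE:     8.9918 months
#>   RAE:     0.3821
#>   uncensored subjects evaluated: 300
```

(The classical fit on the same data scores MAE 28.05 months.) An MAE near
9 months is what an oracle achieves here: with σ = 12 the irreducible
spread of each subject's death time is E|T − μ(x)| ≈ 0.8·σ.

## Command line

```sh
Rscript inst/cli/centime.R simulate --mechanism event_conditional --n 500 \
    --tmax 60 --sigma 12 --censored-frac 0.65 --seed 1 --out cohort.csv
Rscript inst/cli/centime.R fit --likelihood centime --data cohort.csv \
    --tmax 60 --out fit.json
Rscript inst/cli/centime.R evaluate --model fit.json --data cohort.csv
Rscript inst/cli/centime.R sweep --n-train 400 --replicates 5 --out sweep.csv
```

Cohort files are comma-delimited with a header: covariate columns, then
`status` (1 = death observed, 0 = censored) and `time` (integer months).

## Scope

Linear predictors only — the location `μ(x)` and the risk score `g(x)` are
interfaces behind which richer models (the motivating use case feeds CNN
features) can be plugged; imaging I/O, deep-network training, left/interval
censoring, Efron ties and time-dependent covariates are out of scope. See
`vignettes/centime-methods.Rmd` for the modelling details, numerical
choices and limitations.
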