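# bmtl — Bayesian multitask learning for ordinal star ratings

`bmtl` jointly models several related ordinal rating tasks — the motivating
application is patient drug reviews scored 1–5 stars on *satisfaction*,
*ease of use* and *effectiveness* — so that the regression for each task can
borrow strength from the others.  The fitted model predicts the probability
that a new patient would "recommend" a drug (rate it three stars or above)
from information available at a first visit (demographics plus drug
characteristics distilled from existing patients' review texts), which
sidesteps the cold-start problem of interaction-based recommenders.

## The model

For patient *i*, task *j*, rating `y_ij ∈ {1,…,R}` and covariates `x_ij`,
the ordinal probit model is

    P(y_ij ≤ r) = Φ(α_r − x_ijᵀ β_j),    α_1 < … < α_{R−1},

equivalently `y_ij = r` iff `α_{r−1} < y*_ij ≤ α_r` for a latent utility
`y*_ij = x_ijᵀ β_j + ε_ij`, `ε_ij ~ N(0,1)`.  Multitask coupling enters
through the prior on each covariate's coefficient row:

    β_k· = (β_k1,…,β_kJ) ~ N(0, Σ_k),    Σ_k ~ W⁻¹(Ψ_k, ν),

so the J tasks "learn from each other" via the inverse-Wishart hierarchy.
Inference is a Gibbs sampler with truncated-normal data augmentation: the
sweep updates latent utilities, the stacked coefficient vector
(from `N((XXᵀ+Σ⁻¹)⁻¹Xy*, (XXᵀ+Σ⁻¹)⁻¹)`), each Σ_k
(`W⁻¹(Ψ_k+β_k·β_k·ᵀ, ν+1)`), and each cutpoint (a truncated normal pinned
between the neighboring cutpoints and the relevant latent values).

The Bayesian-LASSO variant (`mode = "bmull"`) adds per-covariate shrinkage
scales, `β_k· ~ N(0, τ_k²Σ_k)` with `τ_k² ~ Exponential(rate λ²/2)`; the
full conditional of `τ_k²` is generalized-inverse-Gaussian and λ is updated
by Monte-Carlo empirical Bayes.  Irrelevant covariates (e.g. uninformative
review topics) are pulled toward zero without being removed.

Review texts never enter the model directly: each review's topic-probability
vector π (from an external topic model) becomes binary indicators
`1{π_k > 1/K}`, and a `prior_sentiment` covariate averages the sentiment of
strictly earlier same-dominant-topic reviews of the drug.

## Worked example

```r
library(bmtl)
sim <- simulate_panel(n = 200, p = 3, J = 3, effect_size = 0.6,
                      task_corr = 0.7, seed = 7)
fit <- bmtl(sim$panel, bmtl_control(n_iter = 2000), seed = 7)
round(coef(fit), 2)
#>    task1 task2 task3
#> x1 -0.89 -0.51 -0.71
#> x2 -0.04  0.12  0.08
#> x3  0.57  0.17  0.43
```

The posterior-mean coefficient matrix recovers the generating truth
(`-0.77, -0.48, -0.67` for the first row, etc.).  Predictions are
Rao-Blackwellized recommend probabilities, one per patient and task:

```r
round(predict(fit, sim$panel$x[1:3, ])$recommend, 3)
#>       [,1]  [,2]  [,3]
#> [1,] 0.030 0.275 0.120
#> [2,] 0.979 0.898 0.961
#> [3,] 0.738 0.732 0.723
```

The evaluation protocol resamples 50 training patients (150 training
observations with three tasks), refits, and scores the held-out patients:

```r
resample_experiment(sim$panel, n_train = 50, reps = 5, n_iter = 600, seed = 7)
#> Resampling evaluation (bmul): 5 repetitions, 50 training patients
#>      accuracy    auc accuracy_task1 auc_task1 ...
#> mean   0.7293 0.8040          0.768    0.8630
#> sd     0.0227 0.0191          0.028    0.0276
```

Here pooled accuracy is the fraction of held-out observations whose
recommend probability, thresholded at 0.5, matches the binary label
`rating ≥ 3`, and AUC is the tie-corrected rank probability that a random
positive outranks a random negative.

A command-line wrapper (`inst/cli/bmtl.R`) exposes `fit`, `predict`,
`simulate` and `evaluate` subcommands over CSV files and YAML configs.

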