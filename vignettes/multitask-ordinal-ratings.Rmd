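---
title: "Multitask Bayesian ordinal probit regression for review ratings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multitask Bayesian ordinal probit regression for review ratings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bmtl)
```

## The problem

Patient review sites collect, for each drug, ordinal star ratings on several
related quality measures — satisfaction, ease of use, effectiveness — along
with basic demographics and free-text reviews.  The three measures are
strongly positively correlated (correlations between roughly 0.3 and 0.9 are
typical, highest between satisfaction and effectiveness), so modelling them
jointly should beat three separate regressions, especially when a drug has
few reviews.  The quantity a recommender needs is the probability that a
*new* patient — someone with demographics but no review history — would rate
the drug three stars or above ("recommend").  Because prediction uses only
covariates available at a first visit, the model has no cold-start problem.

## Model

For patient $i = 1..n$, task $j = 1..J$ and rating $y_{ij} \in \{1..R\}$
(default $J=3$, $R=5$),

$$P(y_{ij} \le r) = \Phi(\alpha_r - x_{ij}^\top \beta_j),$$

with the latent-variable representation $y^*_{ij} = x_{ij}^\top\beta_j +
\epsilon_{ij}$, $\epsilon_{ij}\sim N(0,1)$, and $y_{ij} = r$ iff
$\alpha_{r-1} < y^*_{ij} \le \alpha_r$ (intervals open on the left, closed
on the right; $\alpha_0 = -\infty$, $\alpha_R = \infty$).  The unit latent
variance fixes the probit scale, so covariates are deliberately *not*
standardized — coefficients stay comparable across fits (an optional
centering flag exists in the feature layer).

Tasks are coupled through the prior on each covariate's coefficient row
$\beta_{k\cdot} = (\beta_{k1},\dots,\beta_{kJ})$:

$$\beta_{k\cdot} \sim N(0, \Sigma_k), \qquad
  \Sigma_k \sim W^{-1}(\Psi_k, \nu).$$

Defaults are $\Psi_k = I_J$ and $\nu = J + 2$: the smallest integer degrees
of freedom giving a proper prior with a finite mean ($E\,\Sigma_k = \Psi_k$),
weak enough not to dominate small training sets.  Both are configurable in
`bmtl_control()`.

Cutpoints can be shared across tasks (the default simplified model — the
measures live on one five-star scale, so common intercepts are plausible) or
task-specific (`shared_cutpoints = FALSE`).  On matched synthetic data the
two variants produce pooled AUC within 0.02 of each other (this is asserted
by the acceptance suite), so the cheaper shared variant is the default.

### The cutpoint prior, precisely

Each cutpoint has a $N(0, 10)$ prior (variance 10, not standard deviation),
constrained to the ordering $\alpha_1 < \dots < \alpha_{R-1}$.  We read this
constraint *jointly*: the prior is proportional to
$\prod_r \phi(\alpha_r/\sqrt{10})$ on the ordered cone — equivalently, the
order statistics of $R-1$ iid $N(0,10)$ draws.  The single-site full
conditional of $\alpha_r$ is then exactly a $N(0,10)$ truncated to

$$\Big(\max\{\alpha_{r-1},\ \max_{ij}\{y^*_{ij}: y_{ij}=r\}\},\ \
   \min\{\alpha_{r+1},\ \min_{ij}\{y^*_{ij}: y_{ij}=r+1\}\}\Big),$$

which is what the sampler draws (pooling latent values across tasks in the
shared variant).  A sequential reading — each $\alpha_r$ a truncated normal
given $\alpha_{r-1}$ — would add a $1/(1-\Phi(\alpha_r/\sqrt{10}))$ factor to
this conditional; the joint reading is the one whose conditionals match the
simple truncated-normal update, and the joint-distribution test below holds
the sampler to exactly this prior.

## Gibbs sampler

Sweep order is fixed (any fixed order is valid; fixing it makes runs
reproducible): latent utilities, coefficients, task covariances, cutpoints,
then the shrinkage block when active.

* **Latent utilities**: $y^*_{ij} \sim N(x_{ij}^\top\beta_j, 1)$ truncated
  to its rating interval.
* **Coefficients**: the stacked vector $\beta$ (covariate-major, task-minor)
  is drawn from $N((XX^\top + \Sigma^{-1})^{-1}Xy^*,\ (XX^\top +
  \Sigma^{-1})^{-1})$ with $\Sigma = \mathrm{diag}(\Sigma_1..\Sigma_p)$.
  The $pJ \times nJ$ block design matrix is never materialized: with shared
  covariates the data precision is $X_{\mathrm{mat}}^\top X_{\mathrm{mat}}
  \otimes I_J$, assembled directly (a unit test checks exact agreement with
  the dense formula, including the task-specific-covariate case).  The draw
  uses the Cholesky factor of the precision.
* **Task covariances**: $\Sigma_k \sim W^{-1}(\Psi_k +
  c_k\beta_{k\cdot}\beta_{k\cdot}^\top,\ \nu+1)$ with $c_k = 1$
  (or $\tau_k^{-2}$ under shrinkage), via `stats::rWishart` on the inverted
  scale.
* **Cutpoints**: single-site truncated normals as above.  No Metropolis
  reparameterization is used — at review-panel sizes the single-site update
  mixes adequately.

Summaries use the second half of the chain by default (`burn_in =
n_iter/2`, overridable), with a default of `n_iter = 5000`.  Convergence is
monitored with Geweke z-scores (first 10% vs last 50%, spectral-density
standard errors via **coda**); the fit emits a note when any $|z| > 3$.
Chains are fully reproducible from the seed.

### Numerical choices

Truncated-normal draws use inverse-CDF sampling in the bulk, switching to
upper-tail probabilities when the interval sits in a tail (accurate to
$\sim 37\sigma$), and beyond $6\sigma$ a rejection sampler — exponential
proposal with the optimal rate, or a uniform proposal for short intervals —
so draws stay finite even for intervals of negligible mass.  Inverse-Gaussian
draws use the Michael–Schucany–Haas transform.  Generalized-inverse-Gaussian
draws of order $\pm 1/2$ (every odd $J$, including the application's $J=3$
and the classical $J=1$ case) reduce exactly to inverse-Gaussian transforms;
other orders use numerical inversion of the CDF on an 8192-point log-spaced
grid spanning 45 log-density units around the mode.  Cutpoint initialization
places $\alpha_r$ at standard-normal quantiles of the pooled empirical
cumulative category frequencies (epsilon-spaced on ties); a category absent
from the data triggers equal spacing on $[-2, 2]$.  Degenerate
zero-coefficient rows in the shrinkage update (where the conditional becomes
improper for $J \ge 2$) get a $10^{-12}$ floor on the quadratic form, with a
warning counting the occurrences.

## Shrinkage (Bayesian LASSO) layer

With many candidate covariates — topic indicators in particular can be pure
noise — `mode = "bmull"` replaces the coefficient prior by
$\beta_{k\cdot} \sim N(0, \tau_k^2\Sigma_k)$ with
$\tau_k^2 \sim \mathrm{Exp}(\text{rate } \lambda^2/2)$.  Deriving the
$\tau_k^2$ full conditional from these priors gives

$$p(\tau_k^2 \mid \beta_{k\cdot}, \Sigma_k) \propto
  (\tau_k^2)^{-J/2} \exp\!\Big\{-\frac{q_k}{2\tau_k^2}
  - \frac{\lambda^2\tau_k^2}{2}\Big\},
  \qquad q_k = \beta_{k\cdot}^\top\Sigma_k^{-1}\beta_{k\cdot},$$

a GIG of order $1 - J/2$ with parameters $(\lambda^2, q_k)$.  Note the
quadratic form requires $\Sigma_k^{-1}$ — a conditional written without it
would not be consistent with the stated joint model.  For $J = 1$ this is
exactly the classical Bayesian-LASSO result,
$1/\tau_k^2 \sim \mathrm{InvGaussian}(\sqrt{\lambda^2/\beta_k^2},
\lambda^2)$, and the test suite checks both this reduction and the $J = 3$
conditional against grid-normalized densities.

The global hyperparameter is set by Monte-Carlo empirical Bayes.  Maximizing
the expected complete-data log marginal likelihood
$Q(\lambda) = p\log(\lambda^2/2) - (\lambda^2/2)\sum_k E(\tau_k^2)$ gives

$$\lambda^2 = \frac{2p}{\sum_k E(\tau_k^2)},$$

with the expectations estimated from the $\tau_k^2$ draws accumulated since
the previous update (window 1 by default; configurable).  `update_lambda()`
returns this $\lambda^2$ quantity and the sampler assigns $\lambda$ its
square root.  This matters: treating the same right-hand side as an update
for $\lambda$ itself makes the iteration expansive — in our experiments
$\lambda$ overflows past $10^{150}$ within a few dozen sweeps as shrinkage
and the hyperparameter amplify each other — whereas the square-root map is a
contraction to the unique fixed point.  $\lambda$ can also be held fixed
(`lambda_update = "fixed"`) for sensitivity studies; at fixed
$\lambda \to 0$ the shrinkage posterior reproduces the plain multitask
posterior, which the tests assert.

## Review-derived features

The covariate layout is fixed and serialized with every fitted artifact:
gender (0 = female, 1 = male), age-group code, its square, treatment-length
code, its square, $K$ topic indicators, `prior_sentiment`.  Topic-model
estimation and sentiment scoring are *adapter seams* — the package consumes
their outputs (a probability vector $\pi$ on the simplex and a sentiment in
$[-1,1]$) and owns only the post-processing:

* indicator $k$ is $1$ iff $\pi_k > 1/K$, strictly — so a uniform vector
  flags no topics (the tie direction is our choice; ties are measure-zero
  for real topic models);
* the dominant topic is the argmax of $\pi$ (0-based, ties to the lowest
  index);
* `prior_sentiment` is the mean sentiment of strictly earlier reviews of the
  same drug sharing the dominant topic, 0 when there are none — a causal
  quantity: permuting later reviews can never change earlier values;
* new patients without review data get each topic's modal indicator value
  over the drug's existing reviews (ties and empty histories default to 0,
  "not mentioned") and `prior_sentiment` 0;
* `select_topic_count()` picks $K$ by coherence over candidate counts
  (default 4, 7, 10, 13, 16, 19; ties to the smaller count) through
  user-supplied fit/coherence adapters.

Age coding differs between data sources (10 bins vs 9); the layout applies
an optional user-supplied recode map and otherwise passes codes through,
since no canonical merge rule exists.  Reviews lacking text get all-zero
indicators and sentiment 0 (logged) rather than being dropped.

## Synthetic data: what it emulates, and what it does not

`simulate_panel()` runs the model forward: mixed-type covariates (binary
gender-like, ordinal age 1–9 and treatment 1–6 with squares, sparse binary
topic-like indicators, a continuous sentiment-like term — or plain iid
Gaussians), coefficient rows drawn with cross-task correlation `task_corr`
and per-covariate scale `effect_size / sd(x_k)` so that, e.g., a squared age
code does not dwarf a binary indicator on the latent scale.  True cutpoints
sit at normal quantiles of the pooled latent distribution, giving roughly
balanced categories.  Presets: `"drug-small"` (n = 110, p = 13, J = 3 — the
scale of a small single-drug review panel with seven topics),
`"recovery"` (n = 500, p = 4) and `"correlated"` (strong effects, task
correlation 0.9, which lands cross-task rating correlations in the 0.5–0.9
band seen in real review panels).  `simulate_review_stream()` additionally
generates Dirichlet topic vectors and sentiments and pushes them through the
real feature-construction code, so the CSV-to-prediction pipeline is
testable end to end.

What the generator does **not** emulate: topic-model posterior uncertainty
(topic vectors are clean Dirichlet draws, not LDA output), review text
itself, missing-data patterns, patient self-selection into reviewing, and
rating-scale heaping.  Passing tests therefore demonstrate correctness of
the inference machinery under the stated model, not robustness to the ways
real review data violate it.

## Testing strategy and problem sizes

Distributional correctness is tested at three levels.  (1) Each conditional
update against an independent oracle: closed-form truncated-normal moments,
the dense block-matrix formula for the coefficient draw, inverse-Wishart
moments and the $J=1$ scaled-inverse-chi-square reduction,
Kolmogorov–Smirnov tests against grid-normalized densities for the cutpoint
and shrinkage-scale conditionals ($10^4$ draws, level 0.01, with one
independent retry since a correct sampler fails a level-$\alpha$ test with
probability $\alpha$).  (2) The joint "getting it right" check
(`sampler_joint_check()`): marginal-conditional versus
successive-conditional simulation on an $n=5, p=2, J=2, R=3$ instance for
20000 sweeps, every monitored mean within 4 standard errors (spectral SEs
for the autocorrelated chain) — any error in any conditional, or any
prior/conditional mismatch, fails this.  (3) Parameter recovery: 20
replicates of the n = 500, p = 4, J = 3 scenario with 3000-sweep chains;
at least 95% of coefficients within 3 posterior SDs of truth and 95%
credible-interval coverage between 0.88 and 0.99.  Shrinkage behavior uses
50 replicates of a half-null n = 120, p = 8 panel with 600-sweep chains, and
the cutpoint-variant comparison 20 replicates with 1000-sweep chains.  These
sizes are the package's chosen compromise between Monte-Carlo resolution and
a test suite that runs in minutes; all are driven by fixed seeds.

## Limitations

* Accuracy and AUC are computed from the pooled per-observation recommend
  probabilities (tasks weighted by observation count); with balanced tasks,
  as here, per-task and pooled weighting coincide.
* The model offers no principled aggregation of the J per-task predictions
  into a single overall score — that would require overall ratings or a
  utility function, which review data do not supply.  Averaging the
  per-task probabilities is possible but is a heuristic.
* Single-site cutpoint updates can mix slowly for very large n (the
  truncation interval tightens as $O(1/n)$); at review-panel sizes this is
  not binding.
* The probability a review mentions a topic is treated as exchangeable
  across patients; no patient-level topic preferences are modelled.
* `mode = "op_single_task"` provides the no-coupling Bayesian baseline; the
  frequentist baseline is `fit_ordered_probit()`, and `importance_ratios()`
  (|Bayes/MLE| > 0.5) flags informative covariates — the cutoff is the
  conventional one, not an optimized quantity.
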