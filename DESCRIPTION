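Package: bmtl
Title: Bayesian Multitask Learning for Ordinal Star Ratings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Bayesian multitask ordinal probit regression for jointly modelling
    several related ordinal rating tasks (e.g. patient drug-review ratings of
    satisfaction, ease of use and effectiveness), with Gibbs sampling via
    truncated-normal data augmentation, an inverse-Wishart cross-task prior,
    and an optional Bayesian-LASSO shrinkage extension with empirical-Bayes
    hyperparameter updates for variable selection. Includes review-derived
    feature construction (topic indicators, dominant topics, prior sentiment),
    synthetic panel generation with known truth, posterior prediction of
    "recommend" probabilities, a patient-level resampling evaluation protocol
    (accuracy/AUC), a frequentist ordered-probit baseline, and importance
    ratios for flagging informative covariates.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    coda,
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    MASS,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
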