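# Synthetic ordinal multitask panels with known generating truth, for
# parameter-recovery, selection-behavior and evaluation-harness tests.  The
# generator runs the ordinal probit model forward: latent utilities
# y* = x'beta_j + N(0,1), ratings by cutpoint segmentation (open-left /
# closed-right intervals, matching the model's convention).

#' Simulate an ordinal multitask panel
#'
#' Covariates follow the chosen scheme; non-null coefficient rows are drawn
#' from a mean-zero normal with cross-task correlation \code{task_corr} and
#' per-covariate scale \code{effect_size / sd(x_k)}, so covariates of very
#' different magnitudes (e.g. a squared age code) contribute comparably on the
#' unit-variance latent scale.  True cutpoints sit at normal quantiles of the
#' pooled latent utilities, giving roughly balanced rating categories.
#'
#' @param n patients.
#' @param p covariates (\code{"drug"} scheme requires \code{p >= 7}).
#' @param J tasks (default 3) and @param R ordinal levels (default 5).
#' @param effect_size latent-scale coefficient magnitude (0 = pure noise).
#' @param task_corr cross-task correlation of each coefficient row, in [0, 1).
#' @param null_fraction fraction of coefficient rows forced to zero.
#' @param covariate_scheme \code{"gaussian"} (iid N(0,1)) or \code{"drug"}
#'   (binary gender, ordinal age 1-9 and treatment 1-6 with their squares,
#'   sparse binary topic indicators, one continuous sentiment in [-1, 1]).
#' @param seed integer seed; the panel is reproducible given the seed.
#' @return list with the \code{\link{ordinal_panel}} and a \code{truth} list
#'   (\code{beta}, \code{cutpoints}, \code{null_mask}, scheme, seed).
#' @examples
#' sim <- simulate_panel(n = 50, p = 3, J = 2, seed = 7)
#' table(sim$panel$y[, 1])
#' @export
simulate_panel <- function(n, p, J = 3, R = 5, effect_size = 0.5,
                           task_corr = 0.5, null_fraction = 0,
                           covariate_scheme = c("gaussian", "drug"),
                           seed = NULL) {
  covariate_scheme <- match.arg(covariate_scheme)
  if (n < 1 || R < 2) stop("need n >= 1 and R >= 2")
  if (task_corr < 0 || task_corr >= 1) stop("task_corr must lie in [0, 1)")
  if (null_fraction < 0 || null_fraction > 1) stop("null_fraction must lie in [0, 1]")
  if (!is.null(seed)) set.seed(seed)

  X <- switch(covariate_scheme,
    gaussian = {
      m <- matrix(rnorm(n * p), n, p)
      colnames(m) <- paste0("x", seq_len(p))
      m
    },
    drug = {
      if (p < 7) stop("drug scheme needs p >= 7 (demographics + at least one topic)")
      K <- p - 6
      age <- sample(1:9, n, replace = TRUE, prob = dnorm(1:9, 6.5, 1.6))
      trt <- sample(1:6, n, replace = TRUE, prob = dnorm(1:6, 3.2, 1.3))
      m <- cbind(gender = rbinom(n, 1, 0.3), age = age, age2 = age^2,
                 treatment = trt, treatment2 = trt^2,
                 matrix(rbinom(n * K, 1, 0.25), n, K,
                        dimnames = list(NULL, paste0("topic", 0:(K - 1)))),
                 prior_sentiment = runif(n, -1, 1))
      m
    })

  n_null <- round(null_fraction * p)
  null_mask <- rep(FALSE, p)
  if (n_null > 0) null_mask[sample.int(p, n_null)] <- TRUE

  C <- matrix(task_corr, J, J); diag(C) <- 1
  Cch <- chol(C)
  beta <- matrix(0, p, J, dimnames = list(colnames(X), NULL))
  xsd <- apply(X, 2, sd)
  xsd[xsd < 1e-8] <- 1                       # constant column guard
  for (k in which(!null_mask))
    beta[k, ] <- (effect_size / xsd[k]) * drop(rnorm(J) %*% Cch)

  ystar <- X %*% beta + matrix(rnorm(n * J), n, J)
  s <- max(sd(as.vector(ystar)), 1e-8)
  cuts <- qnorm(seq_len(R - 1) / R, mean = mean(ystar), sd = s)
  # y = r iff alpha_{r-1} < y* <= alpha_r: count strictly exceeded cutpoints
  y <- matrix(1L + rowSums(outer(as.vector(ystar), cuts, ">")), n, J)

  list(panel = ordinal_panel(y, X, R = R),
       truth = list(beta = beta, cutpoints = cuts, null_mask = null_mask,
                    task_corr = task_corr, effect_size = effect_size,
                    covariate_scheme = covariate_scheme, seed = seed))
}

#' Preset synthetic scenarios
#'
#' \code{"drug-small"} mimics the scale of a small drug-review data set
#' (n = 110 patients, p = 13 covariates in the drug scheme: demographics with
#' squares, 7 topic indicators, sentiment); \code{"recovery"} is the
#' parameter-recovery scenario (n = 500, p = 4, gaussian covariates);
#' \code{"correlated"} uses strong coefficients and high task correlation so
#' cross-task rating correlations land in the 0.5-0.9 band typical of drug
#' review data.
#'
#' @param name preset name.
#' @param seed integer seed.
#' @return as \code{\link{simulate_panel}}.
#' @export
panel_preset <- function(name = c("drug-small", "recovery", "correlated"),
                         seed = NULL) {
  name <- match.arg(name)
  switch(name,
    "drug-small" = simulate_panel(n = 110, p = 13, J = 3, R = 5,
                                  effect_size = 0.4, task_corr = 0.8,
                                  null_fraction = 0.3,
                                  covariate_scheme = "drug", seed = seed),
    "recovery" = simulate_panel(n = 500, p = 4, J = 3, R = 5,
                                effect_size = 0.5, task_corr = 0.5,
                                covariate_scheme = "gaussian", seed = seed),
    "correlated" = simulate_panel(n = 400, p = 4, J = 3, R = 5,
                                  effect_size = 1, task_corr = 0.9,
                                  covariate_scheme = "gaussian", seed = seed))
}

#' Simulate a time-ordered review stream
#'
#' Generates full review records for one synthetic drug: Dirichlet
#' topic-probability vectors, sentiments in [-1, 1], demographics, and three
#' ratings drawn from the ordinal probit model applied to the constructed
#' design (indicators at the 1/K cutoff, running prior_sentiment).  Feeds the
#' end-to-end CSV pipeline with no external data.
#'
#' @param n reviews.
#' @param K topics.
#' @param concentration Dirichlet concentration (small values give near
#'   one-hot topic vectors).
#' @param effect_size,task_corr coefficient scale and cross-task correlation.
#' @param seed integer seed.
#' @return list with \code{records} (CSV-schema data frame), \code{truth} and
#'   the \code{spec} used.
#' @export
simulate_review_stream <- function(n, K = 4, concentration = 1,
                                   effect_size = 0.5, task_corr = 0.7,
                                   seed = NULL) {
  if (K < 2) stop("K must be at least 2")
  if (!is.null(seed)) set.seed(seed)
  g <- matrix(rgamma(n * K, shape = concentration), n, K)
  dead <- rowSums(g) < 1e-300          # gamma underflow at tiny concentration
  if (any(dead)) g[cbind(which(dead), sample.int(K, sum(dead), TRUE))] <- 1
  P <- g / rowSums(g)
  sent <- runif(n, -1, 1)
  age <- sample(1:9, n, replace = TRUE, prob = dnorm(1:9, 6.5, 1.6))
  trt <- sample(1:6, n, replace = TRUE, prob = dnorm(1:6, 3.2, 1.3))
  gender <- rbinom(n, 1, 0.3)

  spec <- feature_spec(K)
  ind <- t(vapply(seq_len(n), function(i) as.integer(topic_indicators(P[i, ], K)),
                  integer(K)))
  dom <- vapply(seq_len(n), function(i) dominant_topic(P[i, ]), integer(1))
  ps <- prior_sentiment(sent, dom, seq_len(n))
  X <- matrix(0, n, spec$p, dimnames = list(NULL, spec$names))
  for (i in seq_len(n))
    X[i, ] <- build_design(list(gender = gender[i], age_group = age[i],
                                treatment_group = trt[i], indicators = ind[i, ],
                                prior_sentiment = ps[i]), spec)

  J <- 3
  C <- matrix(task_corr, J, J); diag(C) <- 1
  xsd <- apply(X, 2, sd); xsd[xsd < 1e-8] <- 1
  beta <- t(vapply(seq_len(spec$p),
                   function(k) (effect_size / xsd[k]) * drop(rnorm(J) %*% chol(C)),
                   numeric(J)))
  ystar <- X %*% beta + matrix(rnorm(n * J), n, J)
  s <- max(sd(as.vector(ystar)), 1e-8)
  cuts <- qnorm(seq_len(4) / 5, mean = mean(ystar), sd = s)
  y <- matrix(1L + rowSums(outer(as.vector(ystar), cuts, ">")), n, J)

  records <- data.frame(drug = "synthetic_drug", order = seq_len(n),
                        rating_satisfaction = y[, 1], rating_ease = y[, 2],
                        rating_effectiveness = y[, 3], gender = gender,
                        age_group = age, treatment_group = trt)
  probs <- as.data.frame(P)
  names(probs) <- paste0("topic_prob_", 0:(K - 1))
  records <- cbind(records, probs, sentiment = sent)
  list(records = records,
       truth = list(beta = beta, cutpoints = cuts, seed = seed),
       spec = spec)
}
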