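# Shared oracles and fixture builders, independent of the sampler code paths
# they check.

# KS test of draws against a density known up to a constant, normalized
# numerically on a grid
ks_vs_density <- function(draws, logdens, lower = NULL, upper = NULL,
                          n_grid = 8192) {
  if (is.null(lower)) lower <- min(draws) * 0.5
  if (is.null(upper)) upper <- max(draws) * 1.5
  # log spacing on positive supports keeps resolution at the body even for
  # heavy-tailed draws
  g <- if (lower > 0) exp(seq(log(lower), log(upper), length.out = n_grid))
       else seq(lower, upper, length.out = n_grid)
  w <- exp(logdens(g) - max(logdens(g)))
  cdf <- cumsum((w[-1] + w[-n_grid]) / 2 * diff(g))
  cdf <- c(0, cdf / cdf[length(cdf)])
  F <- approxfun(g, cdf, yleft = 0, yright = 1, ties = "ordered")
  suppressWarnings(ks.test(draws, F))
}

# flaky-test guard for distributional checks: a correct sampler fails a KS
# test at level alpha with probability alpha, so re-test once on a fresh
# independent sample before declaring failure
ks_pvalue_retry <- function(draw_fun, test_fun, alpha = 0.01) {
  p <- test_fun(draw_fun())$p.value
  if (p > alpha) p else test_fun(draw_fun())$p.value
}

# closed-form inverse-Gaussian CDF (mu, shape parameterization)
pig <- function(q, mu, shape) {
  a <- sqrt(shape / q)
  pnorm(a * (q / mu - 1)) + exp(2 * shape / mu) * pnorm(-a * (q / mu + 1))
}

# closed-form mean of N(mu, 1) truncated to (a, b); upper-tail probabilities
# keep the denominator exact far out in the tail
truncnorm_mean <- function(mu, a, b) {
  as <- a - mu; bs <- b - mu
  mass <- pnorm(as, lower.tail = FALSE) - pnorm(bs, lower.tail = FALSE)
  mu + (dnorm(as) - dnorm(bs)) / mass
}

# brute-force rejection sampler from N(mu,1) on (a, b] -- slow, exact
rtnorm_reject <- function(n, mu, a, b) {
  out <- numeric(0)
  while (length(out) < n) {
    x <- rnorm(10 * n, mu)
    out <- c(out, x[x > a & x <= b])
  }
  out[seq_len(n)]
}

# tiny deterministic panel for exactness tests
toy_panel <- function(n = 3, J = 2, R = 3, p = 2, seed = 42) {
  set.seed(seed)
  y <- matrix(sample.int(R, n * J, replace = TRUE), n, J)
  y[1, 1] <- 1; y[n, J] <- R       # make sure extreme categories occur
  x <- matrix(round(rnorm(n * p), 2), n, p)
  ordinal_panel(y, x, R = R)
}

# a minimal bmtl-shaped object from hand-set draws (for prediction tests)
fake_fit <- function(beta_draws, alpha_draws, p, J, R, burn_in = 0) {
  structure(list(
    draws = list(beta = beta_draws, alpha = alpha_draws),
    burn_in = burn_in,
    control = bmtl_control(n_iter = nrow(beta_draws) + burn_in,
                           burn_in = burn_in, shared_cutpoints = TRUE),
    p = p, J = J, R = R, x_names = paste0("x", seq_len(p)), n = NA),
    class = "bmtl")
}

# a valid sampler state for a panel (beta zero, balanced cutpoints)
fresh_state <- function(panel, control = bmtl_control(n_iter = 10)) {
  control <- bmtl:::resolve_prior(control, panel$J)
  bmtl:::init_state(panel, control)
}
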