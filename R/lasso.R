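# Bayesian-LASSO shrinkage layer: per-covariate scales tau_k^2 with an
# Exponential(rate lambda^2/2) prior on tau_k^2 so that beta_k. ~
# N(0, tau_k^2 Sigma_k) marginalizes to a Laplace-type prior, plus the
# empirical-Bayes (Monte-Carlo EM) update of lambda.

# tau_k^2 full conditional derived from the stated priors:
#   p(tau^2 | beta_k., Sigma_k) ∝ (tau^2)^{-J/2} exp(-q_k / (2 tau^2))
#                                  * exp(-lambda^2 tau^2 / 2)
# with q_k = beta_k.' Sigma_k^{-1} beta_k., i.e. GIG(order 1 - J/2,
# a = lambda^2, b = q_k).  For J = 1 this is exactly the classical
# Bayesian-LASSO result: 1/tau^2 ~ InvGaussian(sqrt(lambda^2/beta^2), lambda^2).
update_tau <- function(state, control) {
  J <- ncol(state$beta)
  ord <- 1 - J / 2
  for (k in seq_len(nrow(state$beta))) {
    bk <- state$beta[k, ]
    q <- drop(crossprod(bk, chol2inv(chol(state$sigma[[k]])) %*% bk))
    if (q < 1e-12) {
      # zero coefficient row: conditional degenerates toward the prior; use a
      # tiny floor on the quadratic form (gamma limit is improper for J >= 2)
      state$tau_floor <- state$tau_floor + 1L
      q <- 1e-12
    }
    state$tau2[k] <- rgig(ord, state$lambda^2, q)
  }
  state
}

#' Empirical-Bayes update of the squared shrinkage hyperparameter
#'
#' Monte-Carlo EM step for the Bayesian-LASSO hyperparameter: returns
#' \eqn{2p / \sum_k \hat E(\tau_k^2)}, the maximum-marginal-likelihood update
#' of \eqn{\lambda^2} under the Exponential(rate \eqn{\lambda^2/2}) prior on
#' each \eqn{\tau_k^2} (setting \eqn{dQ/d\lambda = 2p/\lambda -
#' \lambda \sum E(\tau_k^2) = 0} gives \eqn{\lambda^2 = 2p/\sum E(\tau_k^2)};
#' note the prior-only expectation \eqn{E(\tau^2) = 2/\lambda^2} makes the
#' returned quantity exactly \eqn{\lambda^2} at the fixed point).  The
#' expectations are estimated by averaging the \eqn{\tau_k^2} draws
#' accumulated since the previous update; the sampler sets
#' \eqn{\lambda = \sqrt{2p / \sum \hat E(\tau_k^2)}}, which makes the EM
#' iteration a contraction.
#'
#' @param tau2 a numeric vector of one draw per covariate, or a matrix with
#'   one row per accumulated draw and one column per covariate.
#' @param p number of covariates.
#' @return the updated positive \eqn{\lambda^2}.
#' @examples
#' update_lambda(c(1, 1, 2), p = 3)  # 6 / 4 = 1.5
#' @export
update_lambda <- function(tau2, p) {
  if (is.null(tau2) || length(tau2) == 0) stop("no tau^2 draws accumulated")
  m <- if (is.matrix(tau2)) colMeans(tau2) else tau2
  if (length(m) != p) stop("tau2 draws do not match the covariate count")
  lam <- 2 * p / sum(m)
  if (!is.finite(lam) || lam <= 0) stop("lambda update produced a non-positive value")
  lam
}

#' Per-covariate shrinkage summary
#'
#' For each covariate row k of a shrinkage (\code{bmull}) fit: posterior mean
#' of \eqn{\tau_k^2}, posterior mean of the coefficient-row norm
#' \eqn{\|\beta_{k\cdot}\|}, and, when a matching non-shrinkage (\code{bmul})
#' fit is supplied, the ratio of the two norms with a flag for rows the
#' shrinkage layer pulled toward zero.
#'
#' @param fit a \code{"bmtl"} fit in \code{bmull} mode.
#' @param reference optional \code{"bmtl"} fit of the same panel without
#'   shrinkage.
#' @return data frame with one row per covariate.
#' @export
shrinkage_profile <- function(fit, reference = NULL) {
  if (is.null(fit$draws$tau2)) stop("fit has no shrinkage draws; refit with mode = 'bmull'")
  out <- data.frame(covariate = fit$x_names,
                    mean_tau2 = colMeans(posterior_draws(fit, "tau2")),
                    mean_beta_norm = row_norm_means(fit), row.names = NULL)
  if (!is.null(reference)) {
    ref <- row_norm_means(reference)
    out$ref_beta_norm <- ref
    out$norm_ratio <- out$mean_beta_norm / ref
    out$shrunk <- out$norm_ratio < 1
  }
  out
}

# posterior mean of ||beta_k.|| per covariate row
row_norm_means <- function(fit) {
  d <- posterior_draws(fit, "beta")
  J <- fit$J
  vapply(seq_len(fit$p), function(k) {
    cols <- ((k - 1) * J + 1):(k * J)
    mean(sqrt(rowSums(d[, cols, drop = FALSE]^2)))
  }, numeric(1))
}
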