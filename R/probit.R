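#' Ordinal probit category probabilities
#'
#' Probabilities of each rating level under the ordinal probit model
#' \eqn{P(y \le r) = \Phi(\alpha_r - x^T \beta)}, with implicit
#' \eqn{\alpha_0 = -\infty} and \eqn{\alpha_R = +\infty}.  Rating categories
#' correspond to the latent intervals \eqn{(\alpha_{r-1}, \alpha_r]}.
#'
#' @param x covariate vector of length p.
#' @param beta_j coefficient vector for one task, length p.
#' @param alpha strictly increasing cutpoint vector of length R-1.
#' @return numeric vector of length R summing to 1.
#' @examples
#' category_probabilities(0, 0, qnorm(c(.2, .4, .6, .8)))
#' @export
category_probabilities <- function(x, beta_j, alpha) {
  check_cutpoints(alpha)
  if (length(x) != length(beta_j))
    stop("x and beta_j must have the same length")
  eta <- sum(x * beta_j)
  cum <- c(0, pnorm(alpha - eta), 1)
  pr <- diff(cum)
  names(pr) <- seq_along(pr)
  pr
}

#' Probability of a rating at or above a threshold
#'
#' \eqn{P(y \ge t) = 1 - \Phi(\alpha_{t-1} - x^T \beta)}: the "recommend"
#' probability when \code{threshold = 3} on a five-star scale.
#'
#' @inheritParams category_probabilities
#' @param threshold integer rating in \code{2..R}.
#' @return scalar probability.
#' @export
recommend_probability <- function(x, beta_j, alpha, threshold = 3) {
  check_cutpoints(alpha)
  R <- length(alpha) + 1L
  if (length(threshold) != 1L || threshold != round(threshold) ||
      threshold < 2 || threshold > R)
    stop("threshold must be an integer in 2..R")
  eta <- sum(x * beta_j)
  1 - pnorm(alpha[threshold - 1] - eta)
}

#' Panel log-likelihood of the ordinal probit model
#'
#' Sum over all (patient, task) cells of the log category probability implied
#' by the cutpoints and per-task coefficients.  Returns \code{-Inf} (with a
#' warning) when some observed category has zero probability under degenerate
#' cutpoints.
#'
#' @param panel an \code{\link{ordinal_panel}}.
#' @param beta p x J coefficient matrix (column j for task j).
#' @param alpha cutpoints: either a single length R-1 vector shared by all
#'   tasks, or a (R-1) x J matrix of per-task cutpoints.
#' @return scalar log-likelihood.
#' @export
ordinal_loglik <- function(panel, beta, alpha) {
  beta <- as.matrix(beta)
  if (nrow(beta) != panel$p || ncol(beta) != panel$J)
    stop("beta must be p x J")
  am <- expand_alpha(alpha, panel$R, panel$J)
  ll <- 0
  for (j in seq_len(panel$J)) {
    eta <- panel_x(panel, j) %*% beta[, j]
    aug <- c(-Inf, am[, j], Inf)
    pr <- pnorm(aug[panel$y[, j] + 1L] - eta) - pnorm(aug[panel$y[, j]] - eta)
    if (any(pr <= 0)) {
      warning("zero-probability category under the supplied cutpoints; log-likelihood is -Inf")
      return(-Inf)
    }
    ll <- ll + sum(log(pr))
  }
  ll
}

#' Check latent utilities against their rating intervals
#'
#' Verifies that every latent value \eqn{y^*_{ij}} lies in
#' \eqn{(\alpha_{r-1}, \alpha_r]} for its observed rating r.
#'
#' @param panel an \code{\link{ordinal_panel}}.
#' @param ystar n x J matrix of latent utilities.
#' @param alpha shared cutpoint vector or (R-1) x J matrix.
#' @return logical scalar; attribute \code{"violations"} holds a two-column
#'   matrix of offending (patient, task) indices when \code{FALSE}.
#' @export
validate_latent <- function(panel, ystar, alpha) {
  ystar <- as.matrix(ystar)
  if (!all(dim(ystar) == dim(panel$y))) stop("ystar must match y in dimension")
  am <- expand_alpha(alpha, panel$R, panel$J)
  bad <- matrix(FALSE, panel$n, panel$J)
  for (j in seq_len(panel$J)) {
    aug <- c(-Inf, am[, j], Inf)
    lo <- aug[panel$y[, j]]
    hi <- aug[panel$y[, j] + 1L]
    bad[, j] <- !(ystar[, j] > lo & ystar[, j] <= hi)
  }
  ok <- !any(bad)
  structure(ok, violations = if (ok) NULL else which(bad, arr.ind = TRUE))
}

check_cutpoints <- function(alpha) {
  if (length(alpha) < 1L || anyNA(alpha) || any(!is.finite(alpha)))
    stop("cutpoints must be finite")
  if (length(alpha) > 1L && any(diff(alpha) <= 0))
    stop("cutpoints must be strictly increasing")
  invisible(alpha)
}

# normalize alpha input to an (R-1) x J matrix, validating each column
expand_alpha <- function(alpha, R, J) {
  if (is.matrix(alpha)) {
    if (nrow(alpha) != R - 1L || ncol(alpha) != J)
      stop("per-task cutpoints must be (R-1) x J")
    for (j in seq_len(J)) check_cutpoints(alpha[, j])
    alpha
  } else {
    if (length(alpha) != R - 1L) stop("cutpoint vector must have length R-1")
    check_cutpoints(alpha)
    matrix(alpha, R - 1L, J)
  }
}
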