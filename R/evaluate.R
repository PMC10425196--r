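# Posterior prediction, the patient-level resampling evaluation protocol
# (pooled and per-task accuracy / AUC on "recommend" probabilities), the
# frequentist ordered-probit baseline, and ratio-based variable importance.

#' Posterior predictions for new covariate vectors
#'
#' Rao-Blackwellized "recommend" probabilities: for each post-burn-in draw t
#' and task j, \eqn{P(y \ge threshold) = 1 - \Phi(\alpha^{(t)}_{thr-1} -
#' x' \beta_j^{(t)})}, averaged over draws (not a plug-in of posterior means).
#' Credible intervals come from the empirical quantiles of the per-draw
#' probabilities; averaged category probabilities are returned as well.
#'
#' @param object a \code{"bmtl"} fit.
#' @param x_new numeric matrix (rows = new observations, p columns) or vector.
#' @param threshold rating defining "recommend" (default 3).
#' @param level credible level for the interval (default 0.95).
#' @param ... unused.
#' @return list of class \code{"bmtl_prediction"}: \code{recommend} (n x J
#'   matrix of probabilities), \code{lower}/\code{upper} interval bounds, and
#'   \code{categories} (n x R x J array of averaged category probabilities).
#' @export
predict.bmtl <- function(object, x_new, threshold = 3, level = 0.95, ...) {
  if (is.null(dim(x_new))) x_new <- matrix(x_new, nrow = 1)
  x_new <- as.matrix(x_new)
  if (ncol(x_new) != object$p) stop("x_new must have p columns")
  if (threshold < 2 || threshold > object$R) stop("threshold must lie in 2..R")
  bdraws <- posterior_draws(object, "beta")
  adraws <- posterior_draws(object, "alpha")
  Tn <- nrow(bdraws); m <- nrow(x_new)
  J <- object$J; R <- object$R
  qs <- c((1 - level) / 2, 1 - (1 - level) / 2)

  rec <- lo <- hi <- matrix(NA_real_, m, J)
  cats <- array(NA_real_, c(m, R, J))
  shared <- object$control$shared_cutpoints
  for (j in seq_len(J)) {
    cols <- seq(j, by = J, length.out = object$p)     # covariate-major storage
    L <- x_new %*% t(bdraws[, cols, drop = FALSE])    # m x T linear predictors
    acols <- if (shared) seq_len(R - 1) else ((j - 1) * (R - 1) + 1):(j * (R - 1))
    A <- adraws[, acols, drop = FALSE]                # T x (R-1)
    pr <- 1 - pnorm(matrix(A[, threshold - 1], m, Tn, byrow = TRUE) - L)
    rec[, j] <- rowMeans(pr)
    lo[, j] <- apply(pr, 1, quantile, qs[1])
    hi[, j] <- apply(pr, 1, quantile, qs[2])
    cum_prev <- matrix(0, m, Tn)
    for (r in seq_len(R)) {
      cum <- if (r == R) matrix(1, m, Tn) else
        pnorm(matrix(A[, r], m, Tn, byrow = TRUE) - L)
      cats[, r, j] <- rowMeans(cum - cum_prev)
      cum_prev <- cum
    }
  }
  structure(list(recommend = rec, lower = lo, upper = hi, categories = cats,
                 threshold = threshold, level = level),
            class = "bmtl_prediction")
}

#' Classification accuracy at a probability cutoff
#'
#' Fraction of observations where \code{prob > cutoff} agrees with the binary
#' label; a probability exactly at the cutoff counts as a negative prediction.
#'
#' @param prob predicted probabilities.
#' @param labels 0/1 (or logical) labels.
#' @param cutoff decision cutoff (default 0.5).
#' @return fraction in [0, 1].
#' @export
binary_accuracy <- function(prob, labels, cutoff = 0.5) {
  labels <- as.integer(as.logical(labels))
  if (length(prob) != length(labels)) stop("prob and labels lengths differ")
  mean((prob > cutoff) == labels)
}

#' Rank-based AUC
#'
#' Mann-Whitney form with ties counted half: the probability that a random
#' positive outranks a random negative.  Returns \code{NA} with attribute
#' \code{"undefined"} when only one class is present (never silently 0.5).
#'
#' @inheritParams binary_accuracy
#' @return AUC in [0, 1], or flagged NA.
#' @export
rank_auc <- function(prob, labels) {
  labels <- as.integer(as.logical(labels))
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) {
    warning("AUC undefined: only one class present")
    return(structure(NA_real_, undefined = TRUE))
  }
  r <- rank(prob)                     # midranks handle ties
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Patient-level resampling evaluation
#'
#' The evaluation protocol for review panels: each repetition samples
#' \code{n_train} patients without replacement (their \code{n_train * J}
#' observations form the training set; 150 observations when
#' \code{n_train = 50, J = 3}), trains the chosen model on the full R-level
#' labels, scores every test observation by its posterior "recommend"
#' probability, and records pooled and per-task accuracy (cutoff 0.5) and
#' AUC against the binary label \code{rating >= threshold}.
#'
#' @param panel an \code{\link{ordinal_panel}} with more than \code{n_train}
#'   patients.
#' @param n_train training patients per repetition (default 50).
#' @param reps repetitions (default 100).
#' @param mode sampler mode passed to \code{\link{bmtl_control}}.
#' @param n_iter,burn_in chain length per repetition.
#' @param threshold,cutoff recommend threshold (default 3) and accuracy
#'   cutoff (default 0.5).
#' @param shared_cutpoints passed through to the sampler.
#' @param seed integer seed controlling both the patient resampling and the
#'   chains.
#' @return object of class \code{"metric_table"}: per-repetition data frame
#'   plus means and SDs.
#' @export
resample_experiment <- function(panel, n_train = 50, reps = 100,
                                mode = "bmul", n_iter = 1000,
                                burn_in = floor(n_iter / 2),
                                threshold = 3, cutoff = 0.5,
                                shared_cutpoints = TRUE, seed = NULL) {
  if (n_train >= panel$n) stop("n_train must be smaller than the patient count")
  if (!is.null(seed)) set.seed(seed)
  J <- panel$J
  per_rep <- vector("list", reps)
  for (rep in seq_len(reps)) {
    tr <- sort(sample.int(panel$n, n_train))
    te <- setdiff(seq_len(panel$n), tr)
    fit <- bmtl(panel_subset(panel, tr),
                bmtl_control(n_iter = n_iter, burn_in = burn_in, mode = mode,
                             shared_cutpoints = shared_cutpoints))
    pred <- predict(fit, if (panel$shared_x) panel$x[te, , drop = FALSE] else
      panel$x[te, , , drop = FALSE][, , 1], threshold = threshold)
    prob <- as.vector(pred$recommend)
    lab <- as.vector(panel$y[te, , drop = FALSE] >= threshold)
    row <- data.frame(rep = rep, n_train_obs = n_train * J,
                      accuracy = binary_accuracy(prob, lab, cutoff),
                      auc = as.numeric(rank_auc(prob, lab)))
    for (j in seq_len(J)) {
      pj <- pred$recommend[, j]; lj <- panel$y[te, j] >= threshold
      row[[paste0("accuracy_task", j)]] <- binary_accuracy(pj, lj, cutoff)
      row[[paste0("auc_task", j)]] <- suppressWarnings(as.numeric(rank_auc(pj, lj)))
    }
    per_rep[[rep]] <- row
  }
  per_rep <- do.call(rbind, per_rep)
  metric_cols <- setdiff(names(per_rep), c("rep", "n_train_obs"))
  structure(list(per_rep = per_rep,
                 mean = colMeans(per_rep[metric_cols], na.rm = TRUE),
                 sd = apply(per_rep[metric_cols], 2, sd, na.rm = TRUE),
                 n_train = n_train, reps = reps, mode = mode),
            class = "metric_table")
}

#' @export
print.metric_table <- function(x, ...) {
  cat(sprintf("Resampling evaluation (%s): %d repetitions, %d training patients\n",
              x$mode, x$reps, x$n_train))
  tab <- rbind(mean = x$mean, sd = x$sd)
  print(round(tab, 4))
  invisible(x)
}

#' Write a metric table to CSV
#'
#' @param x a \code{"metric_table"}.
#' @param path output CSV (summary rows: mean and sd per metric).
#' @export
write_metric_table <- function(x, path) {
  utils::write.csv(data.frame(metric = names(x$mean), mean = x$mean, sd = x$sd,
                              row.names = NULL), path, row.names = FALSE)
  invisible(path)
}

#' Frequentist ordered-probit fit for a single task
#'
#' Maximum-likelihood estimation of the ordinal probit model
#' \eqn{P(y \le r) = \Phi(\alpha_r - x'\beta)} by direct optimization of the
#' log-likelihood, with the ordering enforced through a log-increment
#' cutpoint parameterization.
#'
#' @param y integer ratings in 1..R.
#' @param x covariate matrix (n x p).
#' @param R ordinal levels (default \code{max(y)}).
#' @return list with \code{beta}, \code{alpha}, \code{logLik},
#'   \code{convergence} (0 = converged), and \code{grad_norm} at the optimum.
#' @export
fit_ordered_probit <- function(y, x, R = max(y)) {
  x <- as.matrix(x)
  n <- length(y); p <- ncol(x)
  if (nrow(x) != n) stop("x must have one row per observation")
  cf <- cumsum(tabulate(y, R))[seq_len(R - 1)] / n
  cf <- pmin(pmax(cf, 1e-3), 1 - 1e-3)
  a0 <- qnorm(cf)
  for (r in seq_len(R - 1)[-1]) if (a0[r] <= a0[r - 1]) a0[r] <- a0[r - 1] + 1e-3
  theta0 <- c(a0[1], if (R > 2) log(diff(a0)), rep(0, p))

  unpack <- function(theta) {
    alpha <- cumsum(c(theta[1], if (R > 2) exp(theta[2:(R - 1)])))
    list(alpha = alpha, beta = theta[R:(R - 1 + p)])
  }
  nll <- function(theta) {
    par <- unpack(theta)
    eta <- drop(x %*% par$beta)
    aug <- c(-Inf, par$alpha, Inf)
    pr <- pnorm(aug[y + 1L] - eta) - pnorm(aug[y] - eta)
    if (any(pr <= 0)) return(1e10)
    -sum(log(pr))
  }
  opt <- optim(theta0, nll, method = "BFGS",
               control = list(maxit = 500, reltol = 1e-12))
  gr <- numDeriv_grad(nll, opt$par)
  par <- unpack(opt$par)
  if (opt$convergence != 0)
    warning(sprintf("ordered-probit MLE did not converge (code %d, |grad| = %.3g)",
                    opt$convergence, sqrt(sum(gr^2))))
  list(beta = setNames(par$beta, colnames(x)), alpha = par$alpha,
       logLik = -opt$value, convergence = opt$convergence,
       grad_norm = sqrt(sum(gr^2)))
}

# central-difference gradient (small problems only)
numDeriv_grad <- function(f, theta, h = 1e-5) {
  vapply(seq_along(theta), function(i) {
    e <- numeric(length(theta)); e[i] <- h
    (f(theta + e) - f(theta - e)) / (2 * h)
  }, numeric(1))
}

#' Bayesian-to-frequentist importance ratios
#'
#' \eqn{ratio_k = |bayes_k / probit_k|}; covariates with ratio above the
#' cutoff (default 0.5) are flagged informative.  A zero frequentist estimate
#' yields an infinite, flagged ratio.
#'
#' @param bayes posterior-mean coefficient estimates.
#' @param probit matching frequentist ordered-probit estimates.
#' @param cutoff informativeness cutoff (default 0.5).
#' @return data frame with \code{ratio}, \code{informative} and
#'   \code{zero_denominator} columns.
#' @examples
#' importance_ratios(c(-0.345, -0.054), c(-0.602, 0.005))
#' @export
importance_ratios <- function(bayes, probit, cutoff = 0.5) {
  if (length(bayes) != length(probit)) stop("estimate vectors differ in length")
  ratio <- abs(bayes / probit)
  zero <- probit == 0
  ratio[zero] <- Inf
  data.frame(covariate = if (!is.null(names(bayes))) names(bayes) else seq_along(bayes),
             bayes = bayes, probit = probit, ratio = ratio,
             informative = ratio > cutoff, zero_denominator = zero,
             row.names = NULL)
}

#' Joint-distribution check of the Gibbs sampler ("getting it right")
#'
#' Compares two ways of sampling from the joint distribution of parameters
#' and data on a small instance: marginal-conditional (parameters from the
#' prior, data from the model, independently each iteration) versus
#' successive-conditional (one Gibbs sweep given the current data, then data
#' re-simulated from the current parameters).  If every conditional update is
#' correct the two chains share all marginal means; the return value reports
#' a z-score per monitored parameter (coefficients and cutpoints), with the
#' successive chain's standard error from its spectral density at zero.
#'
#' The cutpoint prior here (and in the sampler) is the jointly ordered form:
#' R-1 iid N(0, alpha_var) values sorted increasingly, whose single-site full
#' conditionals are the truncated normals the sampler draws.
#'
#' @param n,p,J,R instance size (defaults 5, 2, 2, 3).
#' @param n_iter iterations per chain.
#' @param control sampler control (fixes priors; mode \code{"bmul"}).
#' @param seed integer seed.
#' @return data frame with one row per monitored parameter: the two means,
#'   their standard errors and the comparison z-score.
#' @export
sampler_joint_check <- function(n = 5, p = 2, J = 2, R = 3, n_iter = 20000,
                                control = bmtl_control(n_iter = n_iter, mode = "bmul"),
                                seed = 1) {
  set.seed(seed)
  control <- resolve_prior(control, J)
  X <- matrix(rnorm(n * p), n, p)

  prior_draw <- function() {
    sigma <- lapply(seq_len(p), function(k) rinvwishart(control$Psi, control$nu))
    beta <- t(vapply(sigma, function(S) drop(crossprod(chol(S), rnorm(J))),
                     numeric(J)))
    alpha <- sort(rnorm(R - 1, 0, sqrt(control$alpha_var)))
    list(beta = beta, sigma = sigma, alpha = alpha)
  }
  sim_data <- function(beta, alpha) {
    ystar <- X %*% beta + matrix(rnorm(n * J), n, J)
    y <- matrix(1L + rowSums(outer(as.vector(ystar), alpha, ">")), n, J)
    list(y = y, ystar = ystar)
  }
  monitor <- function(beta, alpha) c(as.vector(t(beta)), alpha)
  nm <- c(as.vector(t(outer(seq_len(p), seq_len(J),
                            function(k, j) paste0("beta_", k, "_", j)))),
          paste0("alpha_", seq_len(R - 1)))

  # marginal-conditional: iid draws from the joint prior (data integrates out)
  mc <- matrix(NA_real_, n_iter, p * J + R - 1)
  for (t in seq_len(n_iter)) {
    th <- prior_draw()
    mc[t, ] <- monitor(th$beta, th$alpha)
  }

  # successive-conditional: Gibbs transition then data re-simulation
  th <- prior_draw()
  dat <- sim_data(th$beta, th$alpha)
  state <- list(alpha = th$alpha, beta = th$beta, sigma = th$sigma,
                ystar = dat$ystar, tau2 = rep(1, p), lambda = 1, tau_floor = 0L)
  sc <- matrix(NA_real_, n_iter, p * J + R - 1)
  for (t in seq_len(n_iter)) {
    panel <- ordinal_panel(dat$y, X, R = R)
    state <- update_latent(state, panel)
    state <- update_beta(state, panel, control)
    state <- update_sigma(state, control)
    state <- update_cutpoints(state, panel, control)
    sc[t, ] <- monitor(state$beta, state$alpha)
    dat <- sim_data(state$beta, state$alpha)
    state$ystar <- dat$ystar
  }

  se_mc <- apply(mc, 2, sd) / sqrt(n_iter)
  se_sc <- vapply(seq_len(ncol(sc)), function(i)
    sqrt(coda::spectrum0.ar(sc[, i])$spec / n_iter), numeric(1))
  z <- (colMeans(mc) - colMeans(sc)) / sqrt(se_mc^2 + se_sc^2)
  data.frame(parameter = nm, mean_marginal = colMeans(mc),
             mean_successive = colMeans(sc), se_marginal = se_mc,
             se_successive = se_sc, z = z, row.names = NULL)
}
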