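# Gibbs sampler for the Bayesian multitask ordinal probit model.
#
# Data augmentation scheme: each observed rating y_ij in 1..R corresponds to a
# latent utility y*_ij = x_ij' beta_j + e_ij, e_ij ~ N(0,1), with y_ij = r iff
# alpha_{r-1} < y*_ij <= alpha_r.  Coefficient rows beta_k. = (beta_k1..betakJ)
# share a N(0, Sigma_k) prior with Sigma_k ~ InvWishart(Psi, nu), which couples
# the J tasks.  The sweep order is fixed: latent -> beta -> Sigma -> cutpoints
# (-> tau^2, lambda in shrinkage mode).

#' Sampler control settings
#'
#' @param n_iter total Gibbs sweeps stored.
#' @param burn_in sweeps discarded for summaries; defaults to half the chain.
#' @param shared_cutpoints if TRUE (default) one cutpoint vector is shared by
#'   all tasks (the simplified model); otherwise each task has its own.
#' @param mode \code{"bmul"} (multitask prior), \code{"bmull"} (multitask +
#'   Bayesian-LASSO shrinkage) or \code{"op_single_task"} (independent
#'   single-task chains, no cross-task prior).
#' @param Psi inverse-Wishart scale matrix (J x J); default identity.
#' @param nu inverse-Wishart degrees of freedom; default J + 2 (proper, with a
#'   finite prior mean Psi / (nu - J - 1) = Psi).
#' @param alpha_var prior variance of each cutpoint (default 10).
#' @param lambda initial shrinkage hyperparameter (bmull mode).
#' @param lambda_update \code{"empirical_bayes"} (Monte-Carlo EM update every
#'   sweep) or \code{"fixed"}.
#' @param lambda_window number of sweeps of tau^2 draws averaged per
#'   empirical-Bayes update (default 1).
#' @param store_sigma keep the Sigma_k draws in the chain (default TRUE).
#' @param verbose print progress every 500 sweeps.
#' @return a list of class \code{"bmtl_control"}.
#' @export
bmtl_control <- function(n_iter = 5000, burn_in = floor(n_iter / 2),
                         shared_cutpoints = TRUE,
                         mode = c("bmul", "bmull", "op_single_task"),
                         Psi = NULL, nu = NULL, alpha_var = 10,
                         lambda = 1,
                         lambda_update = c("empirical_bayes", "fixed"),
                         lambda_window = 1L,
                         store_sigma = TRUE, verbose = FALSE) {
  mode <- match.arg(mode)
  lambda_update <- match.arg(lambda_update)
  if (n_iter <= burn_in || burn_in < 0) stop("need n_iter > burn_in >= 0")
  if (alpha_var <= 0 || lambda <= 0) stop("alpha_var and lambda must be positive")
  structure(list(n_iter = as.integer(n_iter), burn_in = as.integer(burn_in),
                 shared_cutpoints = shared_cutpoints, mode = mode,
                 Psi = Psi, nu = nu, alpha_var = alpha_var,
                 lambda = lambda, lambda_update = lambda_update,
                 lambda_window = as.integer(lambda_window),
                 store_sigma = store_sigma, verbose = verbose),
            class = "bmtl_control")
}

resolve_prior <- function(control, J) {
  if (is.null(control$Psi)) control$Psi <- diag(J)
  if (is.null(control$nu)) control$nu <- J + 2
  if (!all(dim(control$Psi) == c(J, J))) stop("Psi must be J x J")
  if (control$nu <= J - 1) stop("nu must exceed J - 1")
  control
}

# ---- state initialization ---------------------------------------------------

# cutpoints at standard-normal quantiles of empirical cumulative frequencies;
# equal spacing on [-2, 2] when a category is empty
init_cutpoints <- function(ycells, R) {
  cf <- cumsum(tabulate(ycells, R)) / length(ycells)
  cf <- cf[seq_len(R - 1)]
  if (any(cf <= 0) || any(cf >= 1)) {
    message("rating category absent from data; cutpoints initialized by equal spacing on [-2, 2]")
    return(seq(-2, 2, length.out = R - 1))
  }
  a <- qnorm(cf)
  for (r in seq_len(R - 1)[-1])              # epsilon spacing on ties
    if (a[r] <= a[r - 1]) a[r] <- a[r - 1] + 1e-6
  a
}

init_state <- function(panel, control) {
  control <- resolve_prior(control, panel$J)
  J <- panel$J
  alpha <- if (control$shared_cutpoints) {
    init_cutpoints(as.vector(panel$y), panel$R)
  } else {
    vapply(seq_len(J), function(j) init_cutpoints(panel$y[, j], panel$R),
           numeric(panel$R - 1))
  }
  sigma0 <- if (control$nu > J + 1) control$Psi / (control$nu - J - 1) else diag(J)
  state <- list(alpha = alpha,
                beta = matrix(0, panel$p, J,
                              dimnames = list(panel$x_names, NULL)),
                sigma = rep(list(sigma0), panel$p),
                ystar = NULL,
                tau2 = rep(1, panel$p),
                lambda = control$lambda,
                tau_floor = 0L)
  state$ystar <- draw_latent(state, panel)
  state
}

# ---- conditional updates ----------------------------------------------------

# alpha as an (R-1) x J matrix view, whatever the storage
alpha_matrix <- function(state, J, R) {
  if (is.matrix(state$alpha)) state$alpha else matrix(state$alpha, R - 1, J)
}

# latent utilities: N(x'beta_j, 1) truncated to the rating's interval
draw_latent <- function(state, panel) {
  am <- alpha_matrix(state, panel$J, panel$R)
  M <- if (panel$shared_x) panel$x %*% state$beta else
    vapply(seq_len(panel$J),
           function(j) panel_x(panel, j) %*% state$beta[, j, drop = FALSE],
           numeric(panel$n))
  lo <- hi <- matrix(0, panel$n, panel$J)
  for (j in seq_len(panel$J)) {
    aug <- c(-Inf, am[, j], Inf)
    lo[, j] <- aug[panel$y[, j]]
    hi[, j] <- aug[panel$y[, j] + 1L]
  }
  matrix(rtruncnorm(panel$n * panel$J, mean = as.vector(M),
                    lower = as.vector(lo), upper = as.vector(hi)),
         panel$n, panel$J)
}

update_latent <- function(state, panel) {
  state$ystar <- draw_latent(state, panel)
  state
}

# data-precision block XX' (pJ x pJ, covariate-major/task-minor ordering) and
# the matching Xy* vector, assembled from per-patient covariates without ever
# materializing the pJ x nJ block design matrix
data_precision <- function(panel, precomp = NULL) {
  J <- panel$J
  if (panel$shared_x) {
    XtX <- if (is.null(precomp)) crossprod(panel$x) else precomp$XtX
    kronecker(XtX, diag(J))
  } else {
    p <- panel$p
    A <- matrix(0, p * J, p * J)
    for (j in seq_len(J)) {
      idx <- seq(j, by = J, length.out = p)
      Xj <- panel_x(panel, j)
      A[idx, idx] <- crossprod(Xj)
    }
    A
  }
}

data_shift <- function(panel, ystar) {
  if (panel$shared_x) {
    as.vector(t(crossprod(panel$x, ystar)))         # element (k-1)J + j
  } else {
    p <- panel$p; J <- panel$J
    b <- numeric(p * J)
    for (j in seq_len(J)) {
      idx <- seq(j, by = J, length.out = p)
      b[idx] <- crossprod(panel_x(panel, j), ystar[, j])
    }
    b
  }
}

# draw from N(A^{-1} b, A^{-1}) via the Cholesky factor of the precision A
draw_mvn_precision <- function(A, b) {
  Rch <- chol(A)
  mu <- backsolve(Rch, forwardsolve(t(Rch), b))
  list(draw = mu + backsolve(Rch, rnorm(length(b))), mean = mu)
}

# prior precision blocks: (tau_k^2)Sigma_k in shrinkage mode, else Sigma_k
prior_precision <- function(state, shrink) {
  p <- length(state$sigma); J <- nrow(state$sigma[[1]])
  Q <- matrix(0, p * J, p * J)
  for (k in seq_len(p)) {
    S <- state$sigma[[k]]
    if (shrink) S <- state$tau2[k] * S
    idx <- ((k - 1) * J + 1):(k * J)
    Q[idx, idx] <- chol2inv(chol(S))
  }
  Q
}

update_beta <- function(state, panel, control, precomp = NULL) {
  J <- panel$J
  A <- data_precision(panel, precomp) +
    prior_precision(state, shrink = control$mode == "bmull")
  b <- data_shift(panel, state$ystar)
  bv <- draw_mvn_precision(A, b)$draw
  state$beta <- t(matrix(bv, J, panel$p))
  rownames(state$beta) <- panel$x_names
  state
}

# Sigma_k | beta_k. ~ InvWishart(Psi + c_k beta_k. beta_k.', nu + 1) with
# c_k = 1 (bmul) or 1/tau_k^2 (bmull)
update_sigma <- function(state, control) {
  shrink <- control$mode == "bmull"
  for (k in seq_along(state$sigma)) {
    bk <- state$beta[k, ]
    ck <- if (shrink) 1 / state$tau2[k] else 1
    state$sigma[[k]] <- rinvwishart(control$Psi + ck * tcrossprod(bk),
                                    control$nu + 1)
  }
  state
}

# single-site cutpoint update: alpha_r ~ N(0, alpha_var) truncated to
# (max{alpha_{r-1}, max y*: y = r}, min{alpha_{r+1}, min y*: y = r + 1});
# in shared mode the max/min pool latent values across tasks
update_cutpoints <- function(state, panel, control, precomp = NULL) {
  R <- panel$R
  sdp <- sqrt(control$alpha_var)
  draw_vec <- function(alpha, ystar_vec, cells) {
    for (r in seq_len(R - 1)) {
      lo <- if (r > 1) alpha[r - 1] else -Inf
      hi <- if (r < R - 1) alpha[r + 1] else Inf
      below <- cells[[r]]; above <- cells[[r + 1]]
      if (length(below)) lo <- max(lo, max(ystar_vec[below]))
      if (length(above)) hi <- min(hi, min(ystar_vec[above]))
      if (lo >= hi)
        stop(sprintf("empty truncation interval for cutpoint %d", r))
      alpha[r] <- rtruncnorm(1, 0, sdp, lo, hi)
    }
    alpha
  }
  if (control$shared_cutpoints) {
    cells <- if (!is.null(precomp)) precomp$cells_pooled else
      split_cells(as.vector(panel$y), R)
    state$alpha <- draw_vec(state$alpha, as.vector(state$ystar), cells)
  } else {
    for (j in seq_len(panel$J)) {
      cells <- if (!is.null(precomp)) precomp$cells_task[[j]] else
        split_cells(panel$y[, j], R)
      state$alpha[, j] <- draw_vec(state$alpha[, j], state$ystar[, j], cells)
    }
  }
  state
}

split_cells <- function(yvec, R) {
  lapply(seq_len(R), function(r) which(yvec == r))
}

# one full sweep in the documented order
gibbs_sweep <- function(state, panel, control, precomp = NULL) {
  state <- update_latent(state, panel)
  state <- update_beta(state, panel, control, precomp)
  state <- update_sigma(state, control)
  state <- update_cutpoints(state, panel, control, precomp)
  if (control$mode == "bmull") {
    state <- update_tau(state, control)
    if (control$lambda_update == "empirical_bayes") {
      state$tau2_window <- rbind(state$tau2_window, state$tau2)
      if (nrow(state$tau2_window) >= control$lambda_window) {
        state$lambda <- sqrt(update_lambda(state$tau2_window, nrow(state$beta)))
        state$tau2_window <- NULL
      }
    }
  }
  state
}

# ---- main driver ------------------------------------------------------------

#' Fit the Bayesian multitask ordinal probit model
#'
#' Runs the Gibbs sampler for the multitask ordinal probit model
#' (\code{mode = "bmul"}), its Bayesian-LASSO shrinkage extension
#' (\code{mode = "bmull"}), or independent single-task ordinal probit chains
#' (\code{mode = "op_single_task"}).  Posterior summaries use the second half
#' of the chain by default.
#'
#' @param panel an \code{\link{ordinal_panel}}.
#' @param control a \code{\link{bmtl_control}} list.
#' @param seed integer seed; the whole chain is reproducible given the seed.
#' @return an object of class \code{"bmtl"} with per-iteration draws
#'   (\code{$draws}), burn-in marker, control settings and metadata.
#' @examples
#' sim <- simulate_panel(n = 80, p = 3, J = 2, seed = 1)
#' fit <- bmtl(sim$panel, bmtl_control(n_iter = 200), seed = 1)
#' coef(fit)
#' @export
bmtl <- function(panel, control = bmtl_control(), seed = NULL) {
  stopifnot(inherits(panel, "ordinal_panel"))
  control <- resolve_prior(control, panel$J)
  if (!is.null(seed)) set.seed(seed)

  if (control$mode == "op_single_task") return(fit_single_task(panel, control))

  precomp <- list(
    XtX = if (panel$shared_x) crossprod(panel$x) else NULL,
    cells_pooled = split_cells(as.vector(panel$y), panel$R),
    cells_task = lapply(seq_len(panel$J), function(j) split_cells(panel$y[, j], panel$R)))

  state <- init_state(panel, control)
  n_alpha <- (panel$R - 1) * (if (control$shared_cutpoints) 1L else panel$J)
  T_ <- control$n_iter
  draws <- list(
    alpha = matrix(NA_real_, T_, n_alpha, dimnames = list(NULL, alpha_names(panel, control))),
    beta = matrix(NA_real_, T_, panel$p * panel$J,
                  dimnames = list(NULL, beta_names(panel))))
  if (control$store_sigma)
    draws$sigma <- matrix(NA_real_, T_, panel$p * panel$J * (panel$J + 1) / 2,
                          dimnames = list(NULL, sigma_names(panel)))
  if (control$mode == "bmull") {
    draws$tau2 <- matrix(NA_real_, T_, panel$p,
                         dimnames = list(NULL, paste0("tau2_", seq_len(panel$p))))
    draws$lambda <- matrix(NA_real_, T_, 1, dimnames = list(NULL, "lambda"))
  }

  for (it in seq_len(T_)) {
    state <- gibbs_sweep(state, panel, control, precomp)
    check_state_finite(state, it)
    draws$alpha[it, ] <- as.vector(state$alpha)
    draws$beta[it, ] <- as.vector(t(state$beta))   # covariate-major, task-minor
    if (control$store_sigma)
      draws$sigma[it, ] <- unlist(lapply(state$sigma, function(S) S[upper.tri(S, diag = TRUE)]))
    if (control$mode == "bmull") {
      draws$tau2[it, ] <- state$tau2
      draws$lambda[it, ] <- state$lambda
    }
    if (control$verbose && it %% 500 == 0)
      message(sprintf("sweep %d / %d", it, T_))
  }
  if (state$tau_floor > 0L)
    warning(sprintf("tau^2 conditional hit the zero-coefficient limit %d time(s); prior-dominated draws used", state$tau_floor))

  fit <- structure(
    list(draws = draws, burn_in = control$burn_in, control = control,
         p = panel$p, J = panel$J, R = panel$R, x_names = panel$x_names,
         n = panel$n, seed = seed, final_state = state),
    class = "bmtl")
  gz <- tryCatch(geweke_diagnostic(fit), error = function(e) NULL)
  fit$geweke <- gz
  if (!is.null(gz) && any(abs(gz) > 3, na.rm = TRUE))
    message(sprintf("Geweke diagnostic: %d parameter(s) with |z| > 3; consider a longer chain",
                    sum(abs(gz) > 3, na.rm = TRUE)))
  fit
}

# independent single-task Bayesian ordinal probit fits, assembled into one
# object (no cross-task prior: the OP baseline in Bayesian form)
fit_single_task <- function(panel, control) {
  J <- panel$J
  fits <- vector("list", J)
  for (j in seq_len(J)) {
    sub <- ordinal_panel(panel$y[, j, drop = FALSE],
                         if (panel$shared_x) panel$x else panel$x[, , j],
                         R = panel$R, patient_ids = panel$patient_ids)
    ctl <- control
    ctl$mode <- "bmul"; ctl$shared_cutpoints <- TRUE
    ctl$Psi <- NULL; ctl$nu <- NULL
    ctl <- resolve_prior(ctl, 1L)
    fits[[j]] <- bmtl(sub, ctl)
  }
  # interleave per-task columns into covariate-major/task-minor order
  beta <- do.call(cbind, lapply(seq_len(panel$p), function(k)
    do.call(cbind, lapply(seq_len(J), function(j) fits[[j]]$draws$beta[, k, drop = FALSE]))))
  alpha <- do.call(cbind, lapply(fits, function(f) f$draws$alpha))
  ctl_out <- control; ctl_out$shared_cutpoints <- FALSE
  fake_panel <- list(p = panel$p, J = J, R = panel$R, x_names = panel$x_names)
  colnames(beta) <- beta_names(fake_panel)
  colnames(alpha) <- alpha_names(fake_panel, ctl_out)
  structure(list(draws = list(alpha = alpha, beta = beta),
                 burn_in = control$burn_in, control = ctl_out,
                 p = panel$p, J = J, R = panel$R, x_names = panel$x_names,
                 n = panel$n, seed = NULL, task_fits = fits),
            class = "bmtl")
}

check_state_finite <- function(state, it) {
  for (nm in c("alpha", "beta", "tau2", "lambda"))
    if (!all(is.finite(unlist(state[[nm]]))))
      stop(sprintf("non-finite draw for %s at sweep %d", nm, it))
  invisible(NULL)
}

alpha_names <- function(panel, control) {
  R <- panel$R
  if (control$shared_cutpoints) paste0("alpha_", seq_len(R - 1))
  else as.vector(outer(seq_len(R - 1), seq_len(panel$J),
                       function(r, j) paste0("alpha_", r, "_", j)))
}

beta_names <- function(panel) {
  as.vector(t(outer(panel$x_names, seq_len(panel$J),
                    function(k, j) paste0("beta_", k, "_", j))))
}

sigma_names <- function(panel) {
  J <- panel$J
  ut <- which(upper.tri(diag(J), diag = TRUE), arr.ind = TRUE)
  unlist(lapply(seq_len(panel$p), function(k)
    paste0("sigma_", k, "_", ut[, 1], "_", ut[, 2])))
}

# ---- accessors and summaries ------------------------------------------------

#' Post-burn-in draws from a fitted chain
#'
#' @param fit a \code{"bmtl"} object.
#' @param what one of \code{"beta"}, \code{"alpha"}, \code{"sigma"},
#'   \code{"tau2"}, \code{"lambda"}.
#' @return matrix of draws (iterations in rows).
#' @export
posterior_draws <- function(fit, what = "beta") {
  d <- fit$draws[[what]]
  if (is.null(d)) stop(sprintf("no stored draws for '%s'", what))
  d[(fit$burn_in + 1):nrow(d), , drop = FALSE]
}

#' @export
coef.bmtl <- function(object, ...) {
  m <- colMeans(posterior_draws(object, "beta"))
  matrix(m, object$p, object$J, byrow = TRUE,
         dimnames = list(object$x_names, paste0("task", seq_len(object$J))))
}

# posterior-mean cutpoints as an (R-1) x J matrix
cutpoints_mean <- function(fit) {
  m <- colMeans(posterior_draws(fit, "alpha"))
  if (fit$control$shared_cutpoints) matrix(m, fit$R - 1, fit$J)
  else matrix(m, fit$R - 1, fit$J)
}

#' @export
summary.bmtl <- function(object, level = 0.95, ...) {
  qs <- c((1 - level) / 2, 1 - (1 - level) / 2)
  tab_for <- function(what) {
    d <- posterior_draws(object, what)
    data.frame(parameter = colnames(d), mean = colMeans(d),
               sd = apply(d, 2, sd),
               lower = apply(d, 2, quantile, qs[1]),
               upper = apply(d, 2, quantile, qs[2]), row.names = NULL)
  }
  out <- list(coefficients = tab_for("beta"), cutpoints = tab_for("alpha"),
              level = level, n_iter = object$control$n_iter,
              burn_in = object$burn_in, mode = object$control$mode,
              geweke = object$geweke)
  if (!is.null(object$draws$tau2)) {
    out$tau2 <- tab_for("tau2")
    out$lambda <- tab_for("lambda")
  }
  class(out) <- "summary.bmtl"
  out
}

#' @export
print.summary.bmtl <- function(x, ...) {
  cat(sprintf("Bayesian multitask ordinal probit (%s), %d sweeps (burn-in %d)\n",
              x$mode, x$n_iter, x$burn_in))
  cat("\nCoefficients (posterior mean and", sprintf("%d%%", round(100 * x$level)),
      "credible interval):\n")
  print(format(x$coefficients, digits = 3), row.names = FALSE)
  cat("\nCutpoints:\n")
  print(format(x$cutpoints, digits = 3), row.names = FALSE)
  if (!is.null(x$lambda))
    cat(sprintf("\nShrinkage: posterior mean lambda = %.3f\n", x$lambda$mean))
  invisible(x)
}

#' @export
print.bmtl <- function(x, ...) {
  cat(sprintf("bmtl fit (%s): p = %d covariates, J = %d tasks, R = %d levels, %d sweeps\n",
              x$control$mode, x$p, x$J, x$R, x$control$n_iter))
  invisible(x)
}

#' Geweke convergence diagnostic
#'
#' Geweke z-scores (difference of early- and late-window means standardized by
#' spectral-density standard errors, via \pkg{coda}) for every stored
#' parameter of a chain, computed on the post-burn-in draws.  Constant
#' (zero-variance) series get z = 0 with a warning rather than NaN.
#'
#' @param x a \code{"bmtl"} fit or a numeric matrix of draws (one column per
#'   parameter).
#' @param first,last fractions of the chain used for the early and late
#'   windows (defaults 0.1 and 0.5).
#' @return named vector of z-scores.
#' @export
geweke_diagnostic <- function(x, first = 0.1, last = 0.5) {
  mat <- if (inherits(x, "bmtl")) {
    cbind(posterior_draws(x, "beta"), posterior_draws(x, "alpha"))
  } else as.matrix(x)
  N <- nrow(mat)
  if (floor(first * N) < 2 || floor(last * N) < 2)
    stop("chain too short for the requested Geweke windows")
  z <- numeric(ncol(mat))
  names(z) <- colnames(mat)
  const <- apply(mat, 2, function(v) var(v) == 0)
  if (any(const)) {
    warning("zero-variance parameter(s); Geweke z set to 0")
    z[const] <- 0
  }
  if (any(!const)) {
    g <- coda::geweke.diag(coda::mcmc(mat[, !const, drop = FALSE]),
                           frac1 = first, frac2 = last)
    z[!const] <- g$z
  }
  z
}

# ---- chain serialization ----------------------------------------------------

#' Write a chain to CSV
#'
#' One row per stored sweep, named parameter columns (cutpoints, coefficients,
#' covariance elements, shrinkage scales), suitable for external diagnostics.
#'
#' @param fit a \code{"bmtl"} object.
#' @param path output CSV path.
#' @export
write_chain <- function(fit, path) {
  utils::write.csv(as.data.frame(do.call(cbind, fit$draws)), path,
                   row.names = FALSE)
  invisible(path)
}

#' Rebuild a minimal fit object from a serialized chain
#'
#' @param path CSV written by \code{\link{write_chain}}.
#' @param meta list with elements \code{p}, \code{J}, \code{R},
#'   \code{x_names}, \code{burn_in}, \code{shared_cutpoints}, \code{mode}.
#' @return a \code{"bmtl"} object usable with \code{predict} and
#'   \code{summary}.
#' @export
read_chain <- function(path, meta) {
  d <- as.matrix(utils::read.csv(path, check.names = FALSE))
  pick <- function(prefix) d[, startsWith(colnames(d), prefix), drop = FALSE]
  draws <- list(alpha = pick("alpha_"), beta = pick("beta_"))
  if (any(startsWith(colnames(d), "sigma_"))) draws$sigma <- pick("sigma_")
  if (any(startsWith(colnames(d), "tau2_"))) {
    draws$tau2 <- pick("tau2_")
    draws$lambda <- d[, "lambda", drop = FALSE]
  }
  ctl <- bmtl_control(n_iter = nrow(d), burn_in = meta$burn_in,
                      shared_cutpoints = meta$shared_cutpoints,
                      mode = if (identical(meta$mode, "op_single_task")) "bmul" else meta$mode)
  ctl$mode <- meta$mode
  structure(list(draws = draws, burn_in = meta$burn_in, control = ctl,
                 p = meta$p, J = meta$J, R = meta$R, x_names = meta$x_names,
                 n = NA_integer_, seed = NULL),
            class = "bmtl")
}
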