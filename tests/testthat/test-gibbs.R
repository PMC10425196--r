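test_that("state initialization: quantile cutpoints, determinism, degenerate fallback", {
  set.seed(20)
  y <- matrix(rep(rep(1:5, each = 20), 2), ncol = 2)   # perfectly balanced
  pan <- ordinal_panel(y, matrix(rnorm(200), 100, 2), R = 5)
  ctl <- bmtl:::resolve_prior(bmtl_control(n_iter = 10), 2)
  st <- bmtl:::init_state(pan, ctl)
  expect_equal(st$alpha, qnorm(c(.2, .4, .6, .8)), tolerance = 1e-10)
  expect_equal(st$beta, matrix(0, 2, 2, dimnames = list(pan$x_names, NULL)))
  expect_equal(st$sigma[[1]], ctl$Psi / (ctl$nu - 2 - 1))
  expect_true(validate_latent(pan, st$ystar, st$alpha))

  set.seed(99); st1 <- bmtl:::init_state(pan, ctl)
  set.seed(99); st2 <- bmtl:::init_state(pan, ctl)
  expect_identical(st1, st2)

  pan5 <- ordinal_panel(matrix(5L, 10, 2), matrix(rnorm(20), 10, 2), R = 5)
  expect_message(st5 <- bmtl:::init_state(pan5, ctl), "equal spacing")
  expect_equal(st5$alpha, seq(-2, 2, length.out = 4))
  expect_true(validate_latent(pan5, st5$ystar, st5$alpha))
})

test_that("latent update respects intervals and the truncated-normal mean", {
  pan <- toy_panel(n = 6, J = 2, R = 3)
  ctl <- bmtl:::resolve_prior(bmtl_control(n_iter = 10), 2)
  set.seed(21)
  st <- bmtl:::init_state(pan, ctl)
  st$beta <- matrix(rnorm(4, sd = 0.5), 2, 2)
  for (rep in 1:20) {
    st <- bmtl:::update_latent(st, pan)
    expect_true(validate_latent(pan, st$ystar, st$alpha))
  }

  # one cell, repeated draws vs closed-form truncated mean
  set.seed(22)
  i <- 1; j <- 1; r <- pan$y[i, j]
  aug <- c(-Inf, st$alpha, Inf)
  mu <- sum(pan$x[i, ] * st$beta[, j])
  draws <- replicate(1e5, bmtl:::draw_latent(st, pan)[i, j])
  m <- truncnorm_mean(mu, aug[r], aug[r + 1])
  expect_lt(abs(mean(draws) - m), 4 * sd(draws) / sqrt(length(draws)))

  # extreme cutpoints: category mass far in the tail still yields finite draws
  st$alpha <- c(-9, -8.5)
  st$ystar <- bmtl:::draw_latent(st, pan)
  expect_true(all(is.finite(st$ystar)))
  expect_true(validate_latent(pan, st$ystar, st$alpha))
})

test_that("beta update matches the dense block-matrix formula", {
  # independently materialize the pJ x nJ design of the joint model and
  # compare conditional mean / covariance with the sampler's assembly
  pan <- toy_panel(n = 3, J = 2, R = 3, p = 2)
  ctl <- bmtl:::resolve_prior(bmtl_control(n_iter = 10), 2)
  set.seed(23)
  st <- bmtl:::init_state(pan, ctl)
  st$sigma <- list(matrix(c(1, .3, .3, .8), 2), matrix(c(.5, -.1, -.1, .9), 2))
  n <- 3; J <- 2; p <- 2
  X <- matrix(0, p * J, n * J)       # row (k-1)J+j, column (i-1)J+j
  for (i in 1:n) for (j in 1:J) for (k in 1:p)
    X[(k - 1) * J + j, (i - 1) * J + j] <- pan$x[i, k]
  ystar_vec <- as.vector(t(st$ystar))     # (i-1)J+j ordering
  SigInv <- matrix(0, p * J, p * J)
  for (k in 1:p)
    SigInv[((k - 1) * J + 1):(k * J), ((k - 1) * J + 1):(k * J)] <- solve(st$sigma[[k]])
  V <- solve(X %*% t(X) + SigInv)
  mu_dense <- V %*% X %*% ystar_vec

  A <- bmtl:::data_precision(pan) + bmtl:::prior_precision(st, FALSE)
  b <- bmtl:::data_shift(pan, st$ystar)
  expect_equal(solve(A), V, tolerance = 1e-10)
  expect_equal(drop(solve(A, b)), drop(mu_dense), tolerance = 1e-10)

  # and a per-task covariate array must agree with itself stored densely
  xarr <- array(0, c(n, p, J))
  xarr[, , 1] <- pan$x; xarr[, , 2] <- pan$x * 2
  pan2 <- ordinal_panel(pan$y, xarr, R = 3)
  X2 <- X
  for (i in 1:n) for (k in 1:p) X2[(k - 1) * J + 2, (i - 1) * J + 2] <- pan$x[i, k] * 2
  expect_equal(bmtl:::data_precision(pan2), X2 %*% t(X2), tolerance = 1e-10)
  expect_equal(bmtl:::data_shift(pan2, st$ystar), drop(X2 %*% ystar_vec),
               tolerance = 1e-10)
})

test_that("beta update: least-squares limit and prior-only draws", {
  set.seed(24)
  pan <- toy_panel(n = 30, J = 2, R = 3, p = 2, seed = 7)
  ctl <- bmtl:::resolve_prior(bmtl_control(n_iter = 10), 2)
  st <- bmtl:::init_state(pan, ctl)
  st$sigma <- rep(list(diag(2) * 1e6), 2)   # diffuse prior: mean -> OLS
  A <- bmtl:::data_precision(pan) + bmtl:::prior_precision(st, FALSE)
  b <- bmtl:::data_shift(pan, st$ystar)
  mu <- solve(A, b)
  ols <- as.vector(t(qr.solve(pan$x, st$ystar)))   # per-task OLS, interleaved
  expect_equal(drop(mu), ols, tolerance = 1e-3)

  # no data: draws from draw_mvn_precision with prior precision only ~ N(0, Sigma)
  Sig <- matrix(c(1, .4, .4, .6), 2)
  Q <- solve(Sig)
  draws <- t(replicate(1e4, bmtl:::draw_mvn_precision(Q, c(0, 0))$draw))
  expect_lt(max(abs(colMeans(draws))), 0.05)
  expect_equal(cov(draws), Sig, tolerance = 0.08)
})

test_that("sigma update draws are SPD with the inverse-Wishart moment", {
  ctl <- bmtl:::resolve_prior(bmtl_control(n_iter = 10), 2)
  st <- list(beta = matrix(c(0.8, -0.3, 0.5, 1.1), 2, 2),
             sigma = rep(list(diag(2)), 2), tau2 = c(1, 1))
  set.seed(25)
  draws <- replicate(1e4, bmtl:::update_sigma(st, ctl)$sigma[[1]])
  expect_true(all(draws[1, 1, ] > 0))
  expect_true(all(apply(draws, 3, function(M)
    M[1, 2] == M[2, 1] && det(M) > 0 && M[1, 1] > 0)))
  bk <- st$beta[1, ]
  target <- (ctl$Psi + tcrossprod(bk)) / (ctl$nu + 1 - 2 - 1)
  expect_equal(apply(draws, 1:2, mean), target, tolerance = 0.1)

  # J = 1 reduction: scaled inverse chi-square density
  ctl1 <- bmtl:::resolve_prior(bmtl_control(n_iter = 10), 1)
  st1 <- list(beta = matrix(0.9, 1, 1), sigma = list(diag(1)), tau2 = 1)
  scale <- ctl1$Psi[1, 1] + 0.81; df <- ctl1$nu + 1
  p1 <- ks_pvalue_retry(
    function() replicate(1e4, bmtl:::update_sigma(st1, ctl1)$sigma[[1]][1, 1]),
    function(d1) ks_vs_density(
      d1, function(t) -(df / 2 + 1) * log(t) - scale / (2 * t),
      lower = 1e-4, upper = max(d1) * 2))
  expect_gt(p1, 0.01)
})

test_that("cutpoint update preserves order and handles vacuous categories", {
  pan <- toy_panel(n = 20, J = 2, R = 4, seed = 9)
  ctl <- bmtl:::resolve_prior(bmtl_control(n_iter = 10), 2)
  set.seed(26)
  st <- bmtl:::init_state(pan, ctl)
  for (rep in 1:50) {
    st <- bmtl:::update_latent(st, pan)
    st <- bmtl:::update_cutpoints(st, pan, ctl)
    expect_true(all(diff(st$alpha) > 0))
    expect_true(validate_latent(pan, st$ystar, st$alpha))
  }

  # categories 2 and 3 unobserved: alpha_2 constrained only by neighbors/prior
  y <- matrix(c(rep(1L, 8), rep(4L, 8)), ncol = 2)
  pan2 <- ordinal_panel(y, matrix(rnorm(16), 8, 2), R = 4)
  suppressMessages(st2 <- bmtl:::init_state(pan2, bmtl:::resolve_prior(ctl, 2)))
  draws <- t(replicate(2000, bmtl:::update_cutpoints(st2, pan2, ctl)$alpha))
  expect_true(all(draws[, 1] < draws[, 2] & draws[, 2] < draws[, 3]))
  # with no observations in categories 2 and 3 the middle cutpoint is bounded
  # only by its neighbors: its draws should reach close to both
  expect_lt(min(draws[, 2] - draws[, 1]), 0.05)
  expect_lt(min(draws[, 3] - draws[, 2]), 0.05)

  # per-task mode keeps each column ordered
  ctl_pt <- bmtl:::resolve_prior(bmtl_control(n_iter = 10, shared_cutpoints = FALSE), 2)
  st3 <- bmtl:::init_state(pan, ctl_pt)
  for (rep in 1:20) {
    st3 <- bmtl:::update_latent(st3, pan)
    st3 <- bmtl:::update_cutpoints(st3, pan, ctl_pt)
    expect_true(all(apply(st3$alpha, 2, function(a) all(diff(a) > 0))))
  }
})

test_that("chains are reproducible by seed and keep joint invariants", {
  sim <- simulate_panel(n = 60, p = 3, J = 2, seed = 27)
  f1 <- bmtl(sim$panel, bmtl_control(n_iter = 150), seed = 5)
  f2 <- bmtl(sim$panel, bmtl_control(n_iter = 150), seed = 5)
  expect_identical(f1$draws, f2$draws)
  expect_identical(summary(f1)$coefficients, summary(f2)$coefficients)

  st <- f1$final_state
  expect_true(all(diff(st$alpha) > 0))
  expect_true(all(vapply(st$sigma, function(S)
    all(eigen(S, symmetric = TRUE, only.values = TRUE)$values > 0), logical(1))))
  expect_true(validate_latent(sim$panel, st$ystar, st$alpha))
  expect_equal(nrow(f1$draws$beta), 150)
})

test_that("single-task mode agrees with the frequentist ordered probit at scale", {
  skip_if_not_installed("MASS")
  sim <- simulate_panel(n = 1200, p = 3, J = 1, effect_size = 0.5,
                        task_corr = 0, seed = 28)
  fit <- bmtl(sim$panel, bmtl_control(n_iter = 600), seed = 3)
  pol <- MASS::polr(factor(y) ~ ., data = data.frame(y = sim$panel$y[, 1], sim$panel$x),
                    method = "probit")
  expect_equal(unname(coef(fit)[, 1]), unname(coef(pol)), tolerance = 0.08)
  expect_equal(unname(colMeans(posterior_draws(fit, "alpha"))),
               unname(pol$zeta), tolerance = 0.08)
})

test_that("Geweke diagnostic: null calibration, trend detection, degenerate chain", {
  set.seed(29)
  z <- replicate(1000, geweke_diagnostic(matrix(rnorm(1000), ncol = 1)))
  expect_gte(mean(abs(z) < 3), 0.99)

  trend <- matrix(seq(0, 5, length.out = 400) + rnorm(400, sd = 0.1), ncol = 1)
  expect_gt(abs(geweke_diagnostic(trend)), 5)

  expect_warning(zc <- geweke_diagnostic(matrix(1, 100, 1)), "zero-variance")
  expect_identical(unname(zc), 0)

  expect_error(geweke_diagnostic(matrix(rnorm(8), ncol = 1)), "too short")
})

test_that("chain serialization round-trips draws and predictions", {
  sim <- simulate_panel(n = 50, p = 2, J = 2, seed = 30)
  fit <- suppressWarnings(
    bmtl(sim$panel, bmtl_control(n_iter = 120, mode = "bmull"), seed = 4))
  f <- tempfile(fileext = ".csv")
  write_chain(fit, f)
  meta <- list(p = fit$p, J = fit$J, R = fit$R, x_names = fit$x_names,
               burn_in = fit$burn_in, shared_cutpoints = TRUE, mode = "bmull")
  fit2 <- read_chain(f, meta)
  expect_equal(unname(fit2$draws$beta), unname(fit$draws$beta), tolerance = 1e-10)
  xnew <- sim$panel$x[1:4, ]
  p1 <- predict(fit, xnew); p2 <- predict(fit2, xnew)
  expect_equal(p1$recommend, p2$recommend, tolerance = 1e-10)
  unlink(f)
})
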