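# Random-variate workhorses for the Gibbs sampler.  All draw through R's RNG
# stream so that set.seed() makes whole chains reproducible.

#' Truncated normal draws
#'
#' Vectorized sampler for N(mean, sd^2) truncated to (lower, upper].  Uses
#' inverse-CDF sampling in the bulk (switching to upper-tail probabilities for
#' intervals in the right tail, and mirrored for the left tail) and rejection
#' sampling with an exponential proposal (Robert 1995) or a uniform proposal
#' in extreme tails, so draws stay finite and inside the interval even when
#' both endpoints are many standard deviations out.
#'
#' @param n number of draws.
#' @param mean,sd normal parameters (recycled).
#' @param lower,upper truncation bounds (recycled); may be -Inf/Inf.
#' @return numeric vector of length n.
#' @export
rtruncnorm <- function(n, mean = 0, sd = 1, lower = -Inf, upper = Inf) {
  mean <- rep_len(mean, n); sd <- rep_len(sd, n)
  a <- (rep_len(lower, n) - mean) / sd
  b <- (rep_len(upper, n) - mean) / sd
  if (any(a >= b)) stop("empty truncation interval")
  z <- numeric(n)

  # mirror intervals lying in the left tail so that work happens on the right
  flip <- b <= 0
  tmp <- a[flip]; a[flip] <- -b[flip]; b[flip] <- -tmp

  far <- a > 6            # inverse CDF unreliable; use rejection
  if (any(!far)) {
    ai <- a[!far]; bi <- b[!far]
    hi_tail <- ai > 0     # both endpoints right of centre: upper-tail probs
    zi <- numeric(length(ai))
    if (any(hi_tail)) {
      qa <- pnorm(ai[hi_tail], lower.tail = FALSE)
      qb <- pnorm(bi[hi_tail], lower.tail = FALSE)
      u <- runif(sum(hi_tail))
      zi[hi_tail] <- qnorm(qb + u * (qa - qb), lower.tail = FALSE)
    }
    if (any(!hi_tail)) {
      pa <- pnorm(ai[!hi_tail]); pb <- pnorm(bi[!hi_tail])
      u <- runif(sum(!hi_tail))
      zi[!hi_tail] <- qnorm(pa + u * (pb - pa))
    }
    # guard against roundoff pushing a draw onto/over a bound
    zi <- pmin(pmax(zi, ai), bi)
    z[!far] <- zi
  }
  if (any(far)) {
    idx <- which(far)
    z[idx] <- vapply(idx, function(i) rtail1(a[i], b[i]), numeric(1))
  }
  z[flip] <- -z[flip]
  mean + sd * z
}

# one draw from standard normal truncated to [a, b], a > 6
rtail1 <- function(a, b) {
  if (is.finite(b) && (b - a) * a < 2) {
    # short interval: uniform proposal with exact density ratio
    repeat {
      x <- runif(1, a, b)
      if (log(runif(1)) <= (a * a - x * x) / 2) return(x)
    }
  }
  # exponential proposal, optimal rate (Robert 1995), reject beyond b
  alpha <- (a + sqrt(a * a + 4)) / 2
  repeat {
    x <- a + rexp(1, alpha)
    if (x <= b && log(runif(1)) <= -(x - alpha)^2 / 2) return(x)
  }
}

#' Inverse-Gaussian draws
#'
#' Michael-Schucany-Haas transformation method for IG(mu, shape) with density
#' proportional to \eqn{x^{-3/2} \exp\{-shape (x-mu)^2 / (2 mu^2 x)\}}.
#'
#' @param n number of draws.
#' @param mu mean parameter (> 0).
#' @param shape shape parameter (> 0).
#' @return numeric vector of positive draws.
#' @export
rinvgauss <- function(n, mu, shape) {
  if (any(mu <= 0) || any(shape <= 0)) stop("mu and shape must be positive")
  mu <- rep_len(mu, n); shape <- rep_len(shape, n)
  y <- rnorm(n)^2
  x <- mu + mu^2 * y / (2 * shape) -
    mu / (2 * shape) * sqrt(4 * mu * shape * y + mu^2 * y^2)
  x <- pmax(x, .Machine$double.xmin)    # guard roundoff at tiny y
  u <- runif(n)
  ifelse(u <= mu / (mu + x), x, mu^2 / x)
}

#' Generalized inverse Gaussian draw
#'
#' One draw from the GIG distribution with density proportional to
#' \eqn{x^{ord - 1} \exp\{-(a x + b / x)/2\}}, x > 0.  Orders +1/2 and -1/2
#' reduce exactly to inverse-Gaussian transforms (these cover the shrinkage
#' conditional for every odd number of tasks, including J = 1 and J = 3);
#' other orders fall back to numerical inversion of the CDF on an adaptive
#' grid around the mode.
#'
#' @param ord order parameter (real).
#' @param a,b positive rate parameters (b may be 0 only when ord > 0, giving a
#'   gamma draw; a may be 0 only when ord < 0, giving an inverse-gamma draw).
#' @return one positive draw.
#' @export
rgig <- function(ord, a, b) {
  if (a < 0 || b < 0) stop("a and b must be nonnegative")
  if (b <= .Machine$double.eps^2) {
    if (ord <= 0) stop("b = 0 requires ord > 0")
    return(rgamma(1, shape = ord, rate = a / 2))
  }
  if (a <= .Machine$double.eps^2) {
    if (ord >= 0) stop("a = 0 requires ord < 0")
    return(1 / rgamma(1, shape = -ord, rate = b / 2))
  }
  if (ord == 0.5)  return(1 / rinvgauss(1, sqrt(a / b), a))
  if (ord == -0.5) return(rinvgauss(1, sqrt(b / a), b))

  # general order: inverse-CDF on a log-spaced grid spanning the density mass
  ld <- function(x) (ord - 1) * log(x) - (a * x + b / x) / 2
  m <- ((ord - 1) + sqrt((ord - 1)^2 + a * b)) / a   # mode
  peak <- ld(m)
  span <- function(dir) {                            # where log-density drops by 45
    s <- m
    repeat {
      s <- s * if (dir > 0) 2 else 0.5
      if (ld(s) < peak - 45) return(s)
    }
  }
  grid <- exp(seq(log(span(-1)), log(span(1)), length.out = 8192))
  w <- exp(ld(grid) - peak)
  cdf <- cumsum((w[-1] + w[-length(w)]) / 2 * diff(grid))
  cdf <- c(0, cdf / cdf[length(cdf)])
  stats::approx(cdf, grid, xout = runif(1), ties = "ordered")$y
}

#' Inverse-Wishart draw
#'
#' One draw from W^{ -1}(scale, df): the inverse of a Wishart(df, scale^{-1})
#' draw, computed with \code{stats::rWishart}.
#'
#' @param scale symmetric positive definite scale matrix.
#' @param df degrees of freedom, > nrow(scale) - 1.
#' @return an SPD matrix of the same dimension as \code{scale}.
#' @export
rinvwishart <- function(scale, df) {
  d <- nrow(scale)
  if (df <= d - 1) stop("df must exceed dimension - 1")
  W <- stats::rWishart(1, df, chol2inv(chol(scale)))[, , 1]
  S <- chol2inv(chol(W))
  (S + t(S)) / 2
}
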