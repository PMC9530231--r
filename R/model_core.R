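#' Define an estimation context
#'
#' An estimation context is the distribution of a population's initial
#' estimates for a given task: a distribution family together with the unknown
#' truth `theta`, a systematic bias `mu` (log-scale location offset for the
#' multiplicative families), and a dispersion/shape parameter `sigma`.
#'
#' For the multiplicative families an initial estimate is
#' `a = theta * exp(mu + noise)`:
#' * `"lognormal"`: noise is Normal(0, sigma^2), so `a` is log-normal with
#'   median `theta * exp(mu)`.
#' * `"loglaplace"`: noise is Laplace(0, sigma), giving log-Laplace (power-law)
#'   tails on both sides.
#' * `"pareto"`: `a = theta * exp(mu) * P` where `P` is Pareto with scale 1 and
#'   tail index `alpha = 1/sigma`, so larger `sigma` means a heavier tail.
#'
#' `"normal"` is additive: `a = theta + mu + sigma * Z`, truncated to positive
#' values by resampling (estimates of a positive quantity must be positive).
#'
#' @param family One of `"lognormal"`, `"pareto"`, `"loglaplace"`, `"normal"`.
#' @param theta Positive truth.
#' @param mu Real systematic bias.
#' @param sigma Positive dispersion/shape.
#' @return An object of class `estimation_context`.
#' @examples
#' ctx <- estimation_context("lognormal", theta = 2, mu = 1, sigma = 1)
#' ctx
#' @export
estimation_context <- function(family = c("lognormal", "pareto", "loglaplace", "normal"),
                               theta = 2, mu = 0, sigma = 1) {
  family <- match.arg(family)
  stopifnot(is.numeric(theta), length(theta) == 1L, is.finite(theta),
            is.numeric(mu), length(mu) == 1L, is.finite(mu),
            is.numeric(sigma), length(sigma) == 1L, is.finite(sigma))
  if (theta <= 0) stop("'theta' must be positive")
  if (sigma <= 0) stop("'sigma' must be positive")
  structure(list(family = family, theta = theta, mu = mu, sigma = sigma),
            class = "estimation_context")
}

#' @export
print.estimation_context <- function(x, ...) {
  cat(sprintf("Estimation context: %s(theta = %g, mu = %g, sigma = %g)\n",
              x$family, x$theta, x$mu, x$sigma))
  invisible(x)
}

#' Influence weights interpolating between equal voice and dictatorship
#'
#' Builds the ordered weight vector of the omega-indexed class of influence
#' structures: the central agent (index 1) receives
#' `w1 = omega + (1 - omega)/n` and every other agent `(1 - omega)/n`.
#' At `omega = 0` all agents have weight `1/n` (fully decentralized); at
#' `omega = 1` agent 1 is a dictator.
#'
#' @param n Group size, integer `>= 2`.
#' @param omega Centralization in `[0, 1]`.
#' @return An `influence_weights` object: list with the weight vector `w`
#'   (non-increasing, summing to one) and `omega`.
#' @examples
#' interpolation_weights(5, 0.5)$w  # 0.6 0.1 0.1 0.1 0.1
#' @export
interpolation_weights <- function(n, omega) {
  if (!is.numeric(n) || length(n) != 1L || n != round(n) || n < 2)
    stop("'n' must be a single integer >= 2")
  if (!is.numeric(omega) || length(omega) != 1L || !is.finite(omega) ||
      omega < 0 || omega > 1)
    stop("'omega' must be in [0, 1]")
  n <- as.integer(n)
  w <- rep((1 - omega) / n, n)
  w[1L] <- omega + (1 - omega) / n
  structure(list(w = w, omega = omega, n = n), class = "influence_weights")
}

#' @export
print.influence_weights <- function(x, ...) {
  cat(sprintf("Influence weights (n = %d, omega = %.4g): w1 = %.4g, w2..n = %.4g\n",
              x$n, x$omega, x$w[1L], if (x$n > 1L) x$w[2L] else NA_real_))
  invisible(x)
}

#' Freeman centralization of an influence-weight vector
#'
#' For weights summing to one, returns `(n * max(w) - 1) / (n - 1)`, which on
#' the omega-indexed class of structures inverts [interpolation_weights()] and
#' coincides with Freeman's network centralization index.
#'
#' @param w Numeric vector of non-negative weights summing to one, length >= 2.
#' @return Centralization in `[0, 1]`.
#' @examples
#' freeman_centralization(c(0.5, 0.25, 0.25))  # 0.25
#' @export
freeman_centralization <- function(w) {
  if (!is.numeric(w) || length(w) < 2L) stop("'w' must be a numeric vector of length >= 2")
  if (any(w < -1e-12)) stop("weights must be non-negative")
  if (abs(sum(w) - 1) > 1e-8) stop("weights must sum to one")
  n <- length(w)
  (n * max(w) - 1) / (n - 1)
}

#' Collective estimate of a group under influence centralization omega
#'
#' The collective estimate is the convex combination
#' `omega * a[1] + (1 - omega) * mean(a)`, where agent 1 occupies the central
#' position (by exchangeability of i.i.d. initial estimates, taking index 1 as
#' the central agent is without loss of generality). `omega = 0` reduces to the
#' simple mean -- the classical wisdom of crowds -- and `omega = 1` to the
#' central agent's own estimate.
#'
#' @param a Non-empty numeric vector of initial estimates; `a[1]` is the
#'   central agent's estimate.
#' @param omega Centralization in `[0, 1]`.
#' @return The collective estimate, guaranteed to lie in `[min(a), max(a)]`.
#' @examples
#' collective_estimate(c(1, 2, 6), omega = 0.5)  # 2
#' @export
collective_estimate <- function(a, omega) {
  if (!is.numeric(a) || length(a) < 1L || anyNA(a))
    stop("'a' must be a non-empty numeric vector without NAs")
  if (!is.numeric(omega) || length(omega) != 1L || omega < 0 || omega > 1)
    stop("'omega' must be in [0, 1]")
  omega * a[1L] + (1 - omega) * mean(a)
}

# Laplace(0, b) sampler via inverse CDF; base stats has no Laplace.
rlaplace0 <- function(n, b) {
  u <- stats::runif(n)
  ifelse(u < 0.5, b * log(2 * u), -b * log(2 * (1 - u)))
}

#' Sample i.i.d. initial estimates from an estimation context
#'
#' Draws `n` independent initial estimates from the context's distribution
#' (see [estimation_context()] for the parameterization of each family).
#' Uses R's session random number generator; call [set.seed()] beforehand for
#' reproducibility.
#'
#' For the `"normal"` family, non-positive draws are resampled so that all
#' estimates are positive; the number of resampled values is recorded in the
#' `"n_resampled"` attribute of the result.
#'
#' @param ctx An [estimation_context()].
#' @param n Number of estimates, integer `>= 1`.
#' @return Numeric vector of length `n`, all entries positive.
#' @examples
#' set.seed(1)
#' sample_initial_estimates(estimation_context("lognormal", 2, 1, 1), 5)
#' @export
sample_initial_estimates <- function(ctx, n) {
  stopifnot(inherits(ctx, "estimation_context"))
  if (!is.numeric(n) || length(n) != 1L || n != round(n) || n < 1)
    stop("'n' must be a single integer >= 1")
  n <- as.integer(n)
  switch(ctx$family,
    lognormal = stats::rlnorm(n, meanlog = log(ctx$theta) + ctx$mu, sdlog = ctx$sigma),
    loglaplace = ctx$theta * exp(ctx$mu + rlaplace0(n, ctx$sigma)),
    pareto = {
      # P = U^(-sigma) is Pareto(scale 1, tail index 1/sigma)
      ctx$theta * exp(ctx$mu) * stats::runif(n)^(-ctx$sigma)
    },
    normal = {
      m <- ctx$theta + ctx$mu
      p_pos <- stats::pnorm(0, mean = m, sd = ctx$sigma, lower.tail = FALSE)
      if (p_pos < 1e-6)
        stop("normal context has essentially no mass on positive estimates")
      a <- stats::rnorm(n, mean = m, sd = ctx$sigma)
      n_resampled <- 0L
      while (any(bad <- a <= 0)) {
        n_resampled <- n_resampled + sum(bad)
        a[bad] <- stats::rnorm(sum(bad), mean = m, sd = ctx$sigma)
      }
      attr(a, "n_resampled") <- n_resampled
      a
    },
    stop(sprintf("unsupported family '%s'", ctx$family))
  )
}

# CDF of the context's initial-estimate distribution, vectorized over x.
# For "normal" this is the truncated-to-positive CDF, matching the sampler.
context_cdf <- function(ctx, x) {
  out <- numeric(length(x))
  pos <- x > 0
  if (!any(pos)) return(out)
  xp <- x[pos]
  out[pos] <- switch(ctx$family,
    lognormal = stats::plnorm(xp, meanlog = log(ctx$theta) + ctx$mu, sdlog = ctx$sigma),
    loglaplace = {
      y <- (log(xp / ctx$theta) - ctx$mu) / ctx$sigma
      ifelse(y < 0, 0.5 * exp(y), 1 - 0.5 * exp(-y))
    },
    pareto = {
      scale <- ctx$theta * exp(ctx$mu)
      ifelse(xp >= scale, 1 - (xp / scale)^(-1 / ctx$sigma), 0)
    },
    normal = {
      m <- ctx$theta + ctx$mu
      p0 <- stats::pnorm(0, m, ctx$sigma)
      pmin(pmax((stats::pnorm(xp, m, ctx$sigma) - p0) / (1 - p0), 0), 1)
    },
    stop(sprintf("unsupported family '%s'", ctx$family))
  )
  out
}

# Survival function 1 - F, computed directly where a closed form avoids
# cancellation in the upper tail (needed for large-n powers of the CDF).
context_sf <- function(ctx, x) {
  out <- rep(1, length(x))
  pos <- x > 0
  if (!any(pos)) return(out)
  xp <- x[pos]
  out[pos] <- switch(ctx$family,
    lognormal = stats::plnorm(xp, meanlog = log(ctx$theta) + ctx$mu,
                              sdlog = ctx$sigma, lower.tail = FALSE),
    loglaplace = {
      y <- (log(xp / ctx$theta) - ctx$mu) / ctx$sigma
      ifelse(y < 0, 1 - 0.5 * exp(y), 0.5 * exp(-y))
    },
    pareto = {
      scale <- ctx$theta * exp(ctx$mu)
      ifelse(xp >= scale, (xp / scale)^(-1 / ctx$sigma), 1)
    },
    normal = {
      m <- ctx$theta + ctx$mu
      p0 <- stats::pnorm(0, m, ctx$sigma)
      pmin(pmax(stats::pnorm(xp, m, ctx$sigma, lower.tail = FALSE) / (1 - p0), 0), 1)
    },
    stop(sprintf("unsupported family '%s'", ctx$family))
  )
  out
}
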