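#' The ex-Gaussian distribution
#'
#' Density, distribution function and random generation for the ex-Gaussian
#' distribution: the sum of a normal variate (mean `mu`, standard deviation
#' `sigma`) and an independent exponential variate with mean `tau`. The
#' ex-Gaussian is the standard parametric model for reaction-time
#' distributions, and is used here for the finish times of the stop and go
#' racers of the stop-signal task. Its mean is `mu + tau`.
#'
#' All computations are carried out in log space so that extreme
#' `sigma`/`tau` ratios (at least \eqn{10^{-2}}--\eqn{10^{2}}) remain
#' numerically stable; as `tau` approaches 0 the density converges to the
#' normal density with mean `mu` and sd `sigma`.
#'
#' @param x,q vector of quantiles (seconds).
#' @param n number of draws.
#' @param mu mean of the Gaussian component (seconds, > 0 for racer use).
#' @param sigma standard deviation of the Gaussian component (> 0).
#' @param tau mean of the exponential component (> 0).
#' @param log,log.p logical; if `TRUE` return log density / log probability.
#' @param lower.tail logical; if `TRUE` (default) probabilities are
#'   \eqn{P(X \le q)}, otherwise \eqn{P(X > q)}.
#'
#' @return `dexgauss` a density vector, `pexgauss` a probability vector,
#'   `rexgauss` a vector of draws.
#' @examples
#' dexgauss(0.5, mu = 0.4, sigma = 0.05, tau = 0.1)
#' pexgauss(0.6, mu = 0.4, sigma = 0.05, tau = 0.1)
#' @export
dexgauss <- function(x, mu, sigma, tau, log = FALSE) {
  check_exgauss_params(mu, sigma, tau)
  # log f(x) = -log(tau) + (mu - x)/tau + sigma^2/(2 tau^2) + log Phi((x-mu)/sigma - sigma/tau)
  z <- (x - mu) / sigma
  ld <- -log(tau) + (mu - x) / tau + sigma^2 / (2 * tau^2) +
    stats::pnorm(z - sigma / tau, log.p = TRUE)
  if (log) ld else exp(ld)
}

#' @rdname dexgauss
#' @export
pexgauss <- function(q, mu, sigma, tau, lower.tail = TRUE, log.p = FALSE) {
  check_exgauss_params(mu, sigma, tau)
  z <- (q - mu) / sigma
  # F(q) = Phi(z) - exp(log-term); survival computed directly for accuracy
  lterm <- (mu - q) / tau + sigma^2 / (2 * tau^2) +
    stats::pnorm(z - sigma / tau, log.p = TRUE)
  term <- exp(lterm)
  if (lower.tail) {
    p <- stats::pnorm(z) - term
  } else {
    p <- stats::pnorm(z, lower.tail = FALSE) + term
  }
  p <- pmin(pmax(p, 0), 1)
  if (log.p) log(p) else p
}

#' @rdname dexgauss
#' @export
rexgauss <- function(n, mu, sigma, tau) {
  check_exgauss_params(mu, sigma, tau)
  stats::rnorm(n, mean = mu, sd = sigma) + stats::rexp(n, rate = 1 / tau)
}

check_exgauss_params <- function(mu, sigma, tau) {
  if (any(!is.finite(mu)) || any(!is.finite(sigma)) || any(!is.finite(tau)) ||
      any(sigma <= 0) || any(tau <= 0)) {
    stop("ex-Gaussian parameters must be finite with sigma > 0 and tau > 0",
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Ex-Gaussian parameter triple
#'
#' Small constructor/validator for the (`mu`, `sigma`, `tau`) triple used by
#' each racer of the stop-signal race model. The distribution mean is
#' `mu + tau`.
#'
#' @param mu,sigma,tau strictly positive scalars (seconds).
#' @return a named list of class `exgauss_params`.
#' @examples
#' exgauss_params(0.4, 0.05, 0.1)
#' @export
exgauss_params <- function(mu, sigma, tau) {
  if (length(mu) != 1 || length(sigma) != 1 || length(tau) != 1) {
    stop("mu, sigma, tau must be scalars", call. = FALSE)
  }
  if (!is.finite(mu) || mu <= 0) stop("mu must be positive", call. = FALSE)
  check_exgauss_params(mu, sigma, tau)
  structure(list(mu = mu, sigma = sigma, tau = tau), class = "exgauss_params")
}
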