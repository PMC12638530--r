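#' Standardize a covariate
#'
#' Centers and scales to unit SD, keeping the center and scale so that the
#' identical transform can be re-applied to a prediction grid (never the
#' grid's own statistics).
#'
#' @param x Numeric vector with at least two distinct values.
#' @return List with `values`, `center`, `scale`.
#' @export
standardize <- function(x) {
  if (!is.numeric(x) || length(unique(x[is.finite(x)])) < 2)
    stop("covariate is constant (or near-constant); cannot standardize")
  center <- mean(x)
  scale <- stats::sd(x)
  if (scale == 0) stop("covariate has zero SD")
  list(values = (x - center) / scale, center = center, scale = scale)
}

#' Apply a stored standardization
#' @param x Numeric vector.
#' @param center,scale Stored statistics from [standardize()].
#' @export
apply_standardize <- function(x, center, scale) (x - center) / scale

#' Breakpoint (hockey-stick) covariate effect
#'
#' A type-I functional response with saturation: the linear-predictor
#' contribution is `b0 * x` below the threshold `b1` and flat at `b0 * b1`
#' above it, i.e. `b0 * min(x, b1)`.  `x` is on the standardized covariate
#' scale.
#'
#' @param x Standardized covariate values.
#' @param b0 Slope below the threshold.
#' @param b1 Threshold (standardized scale).
#' @return Linear-predictor contribution, same length as `x`.
#' @examples
#' breakpoint_effect(c(1, 5), b0 = 2, b1 = 3)  # 2, 6
#' @export
breakpoint_effect <- function(x, b0, b1) {
  stopifnot(length(b0) == 1, length(b1) == 1, is.finite(b0), is.finite(b1))
  b0 * pmin(x, b1)
}

#' Poisson-link transformation
#'
#' Maps the two log-linked linear predictors of a Poisson-link delta model
#' -- log group density `eta1` and log catch-per-group `eta2` -- to the
#' encounter probability `p = 1 - exp(-n)` and positive-part mean
#' `n * w / p`, with `n = exp(eta1)` and `w = exp(eta2)`.  The
#' unconditional mean satisfies `p * r = exp(eta1 + eta2)` exactly.
#'
#' @param eta1,eta2 Finite linear predictors (vectors recycle).
#' @return List with vectors `p` and `r` (and `n`, `w`).
#' @export
poisson_link <- function(eta1, eta2) {
  if (anyNA(eta1) || anyNA(eta2) || any(!is.finite(eta1)) || any(!is.finite(eta2)))
    stop("linear predictors must be finite")
  n <- exp(eta1)
  w <- exp(eta2)
  p <- -expm1(-n)
  ## n / p -> 1 as n -> 0; series-stabilized ratio
  ratio <- ifelse(n < 1e-8, 1 + n / 2, n / p)
  list(p = p, r = ratio * w, n = n, w = w)
}

#' Poisson-link delta-gamma log-density
#'
#' Hurdle density: mass `1 - p` at zero; for `y > 0`, a Gamma density with
#' mean `r` and shape `gamma_shape`, weighted by `p`.
#'
#' @param y Non-negative response.
#' @param p Encounter probability in (0, 1).
#' @param r Positive-part mean (> 0).
#' @param gamma_shape Gamma shape parameter (> 0).
#' @return Log-density, vectorized.
#' @export
delta_gamma_loglik <- function(y, p, r, gamma_shape) {
  if (any(y < 0)) stop("response must be non-negative")
  stopifnot(all(p > 0 & p < 1), all(r > 0), gamma_shape > 0)
  p <- rep_len(p, length(y)); r <- rep_len(r, length(y))
  ifelse(y == 0, log1p(-p),
         log(p) + stats::dgamma(y, shape = gamma_shape,
                                rate = gamma_shape / r, log = TRUE))
}

#' Tweedie log-density
#'
#' Compound Poisson-Gamma log-density with mean `mu`, power index in
#' (1, 2) and dispersion `phi` (variance `phi * mu^power`).  The point
#' mass at zero is `exp(-mu^(2 - power) / (phi * (2 - power)))`.
#'
#' @param y Non-negative response.
#' @param mu Mean (> 0), recycled.
#' @param power Tweedie index, strictly between 1 and 2.
#' @param phi Dispersion (> 0).
#' @return Log-density, vectorized.
#' @export
tweedie_loglik <- function(y, mu, power, phi) {
  if (power <= 1 || power >= 2) stop("`power` must lie strictly in (1, 2)")
  stopifnot(phi > 0, all(mu > 0))
  if (any(y < 0)) stop("response must be non-negative")
  mu <- rep_len(mu, length(y))
  unname(mgcv::ldTweedie(y, mu = mu, p = power, phi = phi)[, 1])
}

#' Simulate Tweedie responses
#'
#' Draws from the compound Poisson-Gamma representation: a Poisson number
#' of Gamma-distributed jumps.
#'
#' @inheritParams tweedie_loglik
#' @param n Number of draws (ignored when `mu` is a vector of that length).
#' @export
rtweedie <- function(n, mu, power, phi) {
  if (power <= 1 || power >= 2) stop("`power` must lie strictly in (1, 2)")
  mu <- rep_len(mu, n)
  lambda <- mu^(2 - power) / (phi * (2 - power))
  alpha <- (2 - power) / (power - 1)
  gam_scale <- phi * (power - 1) * mu^(power - 1)
  nj <- stats::rpois(n, lambda)
  out <- numeric(n)
  pos <- nj > 0
  out[pos] <- stats::rgamma(sum(pos), shape = alpha * nj[pos],
                            scale = gam_scale[pos])
  out
}

#' Simulate Poisson-link delta-gamma responses
#' @param n Number of draws.
#' @param p Encounter probability.
#' @param r Positive-part mean.
#' @param gamma_shape Gamma shape.
#' @export
rdelta_gamma <- function(n, p, r, gamma_shape) {
  p <- rep_len(p, n); r <- rep_len(r, n)
  enc <- stats::rbinom(n, 1, p) == 1
  out <- numeric(n)
  out[enc] <- stats::rgamma(sum(enc), shape = gamma_shape,
                            rate = gamma_shape / r[enc])
  out
}
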