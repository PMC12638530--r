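#' AR(1) time-varying coefficient log-density
#'
#' Stationary first-order autoregression used for time-varying intercepts:
#' `gamma_1 ~ N(0, sigma^2)` and
#' `gamma_t ~ N(rho * gamma_(t-1), (1 - rho^2) * sigma^2)`, so every
#' marginal variance equals `sigma^2`.  Because the process has a proper
#' joint density over all years, a year with no data is interpolated from
#' its neighbours when the model is fitted.
#'
#' @param gamma Numeric vector, the coefficient value per year.
#' @param rho Autocorrelation, `|rho| < 1`.
#' @param sigma Stationary (marginal) SD, > 0.
#' @return Joint log-density.
#' @export
ar1_logdensity <- function(gamma, rho, sigma) {
  if (abs(rho) >= 1) stop("|rho| must be < 1")
  stopifnot(sigma > 0, length(gamma) >= 1)
  ll <- stats::dnorm(gamma[1], 0, sigma, log = TRUE)
  if (length(gamma) > 1) {
    n <- length(gamma)
    ll <- ll + sum(stats::dnorm(gamma[-1], rho * gamma[-n],
                                sigma * sqrt(1 - rho^2), log = TRUE))
  }
  ll
}

#' Random-walk time-varying coefficient log-density
#'
#' `gamma_1 ~ N(0, sigma^2)` and `gamma_t ~ N(gamma_(t-1), sigma^2)`; used
#' for slowly drifting covariate effects such as depth preferences.
#'
#' @param gamma Numeric vector of at least two time points.
#' @param sigma Innovation SD, > 0.
#' @return Joint log-density.
#' @export
rw_logdensity <- function(gamma, sigma) {
  stopifnot(sigma > 0)
  if (length(gamma) < 2) stop("need at least 2 time points")
  stats::dnorm(gamma[1], 0, sigma, log = TRUE) +
    sum(stats::dnorm(diff(gamma), 0, sigma, log = TRUE))
}

## simulation counterparts (used by the synthetic-data generator)
sim_ar1 <- function(n, rho, sigma) {
  g <- numeric(n)
  g[1] <- stats::rnorm(1, 0, sigma)
  for (t in seq_len(n)[-1])
    g[t] <- stats::rnorm(1, rho * g[t - 1], sigma * sqrt(1 - rho^2))
  g
}

sim_rw <- function(n, sigma) cumsum(stats::rnorm(n, 0, sigma))
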