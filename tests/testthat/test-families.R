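test_that("standardize centers, scales, and stores the transform", {
  s <- standardize(c(1, 2, 3))
  expect_equal(s$values, c(-1, 0, 1))
  expect_equal(s$center, 2)
  expect_equal(s$scale, 1)
  ## standardizing twice is idempotent up to floating error
  s2 <- standardize(s$values)
  expect_equal(s2$values, s$values, tolerance = 1e-12)
  ## prediction-time reuse applies the stored transform, not new statistics
  expect_equal(apply_standardize(c(10, 20), s$center, s$scale), c(8, 18))
  expect_error(standardize(rep(3, 5)), "constant")
})

test_that("breakpoint effect is b0*x below and b0*b1 above the threshold", {
  expect_equal(breakpoint_effect(1, b0 = 2, b1 = 3), 2)   # below: prey x b0
  expect_equal(breakpoint_effect(5, b0 = 2, b1 = 3), 6)   # asymptote: b0 x b1
  expect_equal(breakpoint_effect(3, b0 = 2, b1 = 3), 6)
  x <- seq(-2, 2, by = 0.1)
  eff <- breakpoint_effect(x, 0.5, 0.3)
  expect_true(all(eff <= 0.5 * 0.3 + 1e-12))  # bounded by the asymptote
})

test_that("poisson link satisfies its algebraic identities", {
  pl <- poisson_link(0, 0)
  expect_equal(pl$p, 1 - exp(-1), tolerance = 1e-12)
  expect_equal(pl$r, 1 / (1 - exp(-1)), tolerance = 1e-12)
  ## p * r = exp(eta1 + eta2) for arbitrary predictors
  set.seed(1)
  e1 <- rnorm(50, 0, 2); e2 <- rnorm(50, 0, 2)
  pl <- poisson_link(e1, e2)
  expect_equal(pl$p * pl$r, exp(e1 + e2), tolerance = 1e-12)
  ## eta1 -> -Inf limit: p -> 0 and r -> w
  pl_lo <- poisson_link(-30, 1.3)
  expect_lt(pl_lo$p, 1e-12)
  expect_equal(pl_lo$r, exp(1.3), tolerance = 1e-8)
  expect_error(poisson_link(Inf, 0), "finite")
})

test_that("delta-gamma density has the right zero mass and integrates to 1", {
  expect_equal(delta_gamma_loglik(0, p = 0.25, r = 2, gamma_shape = 1),
               log(0.75))
  ## total mass: (1 - p) + p * integral of the gamma part
  p <- 0.4; r <- 1.7; shape <- 0.8
  pos_mass <- integrate(function(y) exp(delta_gamma_loglik(y, p, r, shape)),
                        lower = 1e-12, upper = Inf)$value
  expect_equal((1 - p) + pos_mass, 1, tolerance = 1e-6)
  ## Monte-Carlo mean matches p * r
  set.seed(2)
  y <- rdelta_gamma(2e5, p, r, shape)
  expect_equal(mean(y), p * r, tolerance = 0.02)
  expect_error(delta_gamma_loglik(-1, p, r, shape), "non-negative")
})

test_that("tweedie density: closed-form zero mass, unit mass, moments", {
  ## P(Y=0) = exp(-mu^(2-p) / (phi (2-p))); mu=1, p=1.5, phi=1 -> log = -2
  expect_equal(tweedie_loglik(0, mu = 1, power = 1.5, phi = 1), -2,
               tolerance = 1e-8)
  mu <- 1.3; power <- 1.6; phi <- 0.9
  pos_mass <- integrate(function(y) exp(tweedie_loglik(y, mu, power, phi)),
                        lower = 1e-10, upper = 60, rel.tol = 1e-9)$value
  zero_mass <- exp(tweedie_loglik(0, mu, power, phi))
  expect_equal(zero_mass + pos_mass, 1, tolerance = 1e-5)
  set.seed(3)
  y <- rtweedie(3e5, mu, power, phi)
  expect_equal(mean(y), mu, tolerance = 0.02)
  expect_equal(var(y), phi * mu^power, tolerance = 0.05)
  expect_equal(mean(y == 0), zero_mass, tolerance = 0.02)
  expect_error(tweedie_loglik(1, 1, power = 2.3, phi = 1), "power")
})

test_that("poisson-link simulated responses hit the unconditional mean", {
  set.seed(4)
  e1 <- 0.4; e2 <- -1.1
  pl <- poisson_link(e1, e2)
  y <- rdelta_gamma(2e5, pl$p, pl$r, 1.2)
  expect_equal(mean(y), exp(e1 + e2), tolerance = 0.02)
  expect_equal(mean(y == 0), 1 - pl$p, tolerance = 0.01)
})
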