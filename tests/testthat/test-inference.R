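test_that("linear predictor assembles all declared terms exactly", {
  ## tiny mesh and two hand-chosen observations
  set.seed(21)
  mesh <- build_mesh(rbind(c(0, 0), c(20, 0), c(10, 18), c(30, 18)),
                     cutoff_km = 5, extension_km = 15)
  d <- data.frame(x_km = c(10, 12), y_km = c(6, 8), year = c(2001, 2003),
                  month = c(2, 11),
                  x = c(0.5, -1), b = c(-0.4, 2), s = c(1, 0.25),
                  yresp = c(1, 2))
  spec <- model_spec("yresp", "tweedie", fixed = ~ x, breakpoint = "b",
                     time_varying = list(intercept = "ar1"), svc = "s",
                     month_random_intercept = TRUE,
                     spatial_field = TRUE, spatiotemporal_field = TRUE)
  fr <- spatdiet:::build_model_frame(spec, d)
  A <- project(mesh, fr$locations)
  nm <- nrow(mesh$loc)
  pars <- list(beta1 = c(0.2, 0.7),
               bp_b0_1 = 1.5, bp_b1_1 = 0.5,
               gamma1 = matrix(seq(0.1, 0.3, length.out = 3), 1),
               alpha1 = seq(-0.6, 0.5, length.out = 12),
               omega1 = rnorm(nm, 0, 0.3),
               epsilon1 = matrix(rnorm(nm * 3, 0, 0.2), nm, 3),
               zeta1 = matrix(rnorm(nm, 0, 0.1), nm, 1))
  eta <- spatdiet:::eval_linear_predictor(fr$comp1, pars, "1", fr$year_idx,
                                          fr$month_idx, A, fr$n_year)
  ## manual assembly for each observation (covariates are standardized
  ## inside the frame, so recompute them the same way)
  xs <- fr$comp1$X[, "x"]
  bs <- fr$comp1$Xbp[, 1]
  ss <- fr$comp1$Xsvc[, 1]
  for (i in 1:2) {
    manual <- 0.2 + 0.7 * xs[i] +
      1.5 * min(bs[i], 0.5) +
      pars$gamma1[1, fr$year_idx[i]] +
      pars$alpha1[d$month[i]] +
      sum(A[i, ] * pars$omega1) +
      sum(A[i, ] * pars$epsilon1[, fr$year_idx[i]]) +
      ss[i] * sum(A[i, ] * pars$zeta1[, 1])
    expect_equal(eta[i], as.numeric(manual), tolerance = 1e-12)
  }
  ## dropping a term removes exactly its contribution
  spec2 <- model_spec("yresp", "tweedie", fixed = ~ x,
                      time_varying = list(intercept = "ar1"), svc = "s",
                      month_random_intercept = TRUE,
                      spatial_field = TRUE, spatiotemporal_field = TRUE)
  fr2 <- spatdiet:::build_model_frame(spec2, d)
  eta2 <- spatdiet:::eval_linear_predictor(fr2$comp1, pars, "1", fr2$year_idx,
                                           fr2$month_idx, A, fr2$n_year)
  expect_equal(eta - eta2, 1.5 * pmin(bs, 0.5), tolerance = 1e-12)
})

test_that("Laplace approximation is exact for a Gaussian spatial model", {
  set.seed(22)
  n <- 20
  d <- data.frame(x_km = runif(n, 0, 40), y_km = runif(n, 0, 40),
                  year = 2001, x = rnorm(n))
  mp <- matern_params(20, 0.8)
  S <- dense_matern_covariance(d[, c("x_km", "y_km")], mp)
  u <- drop(t(chol(S + diag(1e-8, n))) %*% rnorm(n))
  d$y <- 1 + 0.5 * scale(d$x)[, 1] + u + rnorm(n, 0, 0.3)
  spec <- model_spec("y", "gaussian", fixed = ~ x,
                     spatial_field = TRUE, spatiotemporal_field = FALSE)
  mesh <- build_mesh(d[, c("x_km", "y_km")], cutoff_km = 6,
                     extension_km = 30)
  fit <- fit_spatdiet(spec, d, mesh)
  ## closed-form MVN marginal at the fitted parameters
  pf <- fit$sdr$par.fixed
  kappa <- exp(pf["log_kappa1"]); tau <- exp(pf["log_tau_omega1"])
  fem <- fem_matrices(mesh)
  Q <- spatdiet:::spde_precision_from_fem(fem, kappa, tau)
  A <- as.matrix(fit$A)
  Sig <- A %*% as.matrix(Matrix::solve(Q)) %*% t(A) +
    diag(exp(pf["log_phi"])^2, n)
  X <- fit$frame$comp1$X
  betas <- pf[names(pf) == "beta1"]
  resid <- d$y - as.vector(X %*% betas)
  closed <- -0.5 * (n * log(2 * pi) +
                    determinant(Sig, logarithm = TRUE)$modulus +
                    drop(resid %*% solve(Sig, resid)))
  expect_equal(fit$loglik, as.numeric(closed), tolerance = 1e-6)
})

test_that("without latent terms the marginal equals the plain likelihood", {
  set.seed(23)
  n <- 40
  d <- data.frame(x_km = runif(n, 0, 30), y_km = runif(n, 0, 30),
                  year = 2001, x = rnorm(n))
  d$y <- 2 - 0.7 * scale(d$x)[, 1] + rnorm(n, 0, 0.5)
  spec <- model_spec("y", "gaussian", fixed = ~ x,
                     spatial_field = FALSE, spatiotemporal_field = FALSE)
  mesh <- build_mesh(d[, c("x_km", "y_km")], cutoff_km = 5,
                     extension_km = 20)
  fit <- fit_spatdiet(spec, d, mesh)
  pf <- fit$sdr$par.fixed
  mu_hat <- as.vector(fit$frame$comp1$X %*% pf[names(pf) == "beta1"])
  expect_equal(fit$loglik,
               sum(dnorm(d$y, mu_hat, exp(pf["log_phi"]), log = TRUE)),
               tolerance = 1e-8)
})

test_that("marginal log-likelihood is invariant to observation ordering", {
  set.seed(24)
  n <- 60
  d <- data.frame(x_km = runif(n, 0, 40), y_km = runif(n, 0, 40),
                  year = sample(2001:2003, n, TRUE), x = rnorm(n))
  d$y <- rtweedie(n, exp(0.3 + 0.4 * scale(d$x)[, 1]), 1.5, 1)
  spec <- model_spec("y", "tweedie", fixed = ~ x,
                     spatial_field = TRUE, spatiotemporal_field = FALSE)
  mesh <- build_mesh(d[, c("x_km", "y_km")], cutoff_km = 8,
                     extension_km = 30)
  ll1 <- laplace_marginal_loglik(spec, d, mesh)
  ll2 <- laplace_marginal_loglik(spec, d[sample(n), ], mesh)
  expect_equal(ll1, ll2, tolerance = 1e-8)
})

test_that("marginal AIC follows 2k - 2 logLik", {
  fake <- structure(list(loglik = -100, k = 5), class = "spatdiet_fit")
  expect_equal(marginal_aic(fake), 210)
  fake2 <- structure(list(loglik = -100, k = 6), class = "spatdiet_fit")
  expect_equal(marginal_aic(fake2), marginal_aic(fake) + 2)
})

test_that("joint-precision draws are reproducible and centred on the mode", {
  fx <- small_tweedie_fit()
  dr1 <- sample_joint_precision(fx$fit, n_draws = 5, seed = 31)
  dr2 <- sample_joint_precision(fx$fit, n_draws = 5, seed = 31)
  expect_identical(unclass(dr1), unclass(dr2))
  dr <- sample_joint_precision(fx$fit, n_draws = 4000, seed = 32)
  mode <- fx$fit$obj$env$last.par.best
  sds <- sqrt(Matrix::diag(Matrix::solve(fx$fit$sdr$jointPrecision)))
  err <- abs(rowMeans(dr) - mode) / (sds / sqrt(4000))
  expect_lt(stats::median(err), 4)  # standardized Monte-Carlo errors
  ## draw covariance matches the inverse joint precision (fixed block)
  fixed_idx <- which(rownames(dr) %in% c("beta1", "log_phi", "power_raw"))
  Sj <- as.matrix(Matrix::solve(fx$fit$sdr$jointPrecision))
  emp <- cov(t(dr[fixed_idx, ]))
  theo <- Sj[fixed_idx, fixed_idx]
  expect_equal(emp, theo, tolerance = 0.15)
})

test_that("randomized quantile residuals are N(0,1) under the true model", {
  fx <- small_tweedie_fit()
  r1 <- randomized_quantile_residuals(fx$fit, n_sim = 200, seed = 51)
  r2 <- randomized_quantile_residuals(fx$fit, n_sim = 200, seed = 51)
  expect_identical(r1, r2)
  ks <- suppressWarnings(stats::ks.test(r1, "pnorm"))
  expect_gt(ks$p.value, 0.01)
})

test_that("residuals flag a misspecified family", {
  set.seed(26)
  n <- 800
  d <- data.frame(x_km = runif(n, 0, 50), y_km = runif(n, 0, 50),
                  year = 2001)
  ## many zeros plus a sharp spike of positives: a delta-gamma shape no
  ## compound Poisson-gamma with power in (1,2) can mimic
  d$y <- rdelta_gamma(n, p = 0.5, r = 2, gamma_shape = 40)
  spec <- model_spec("y", "tweedie", fixed = ~ 1,
                     spatial_field = FALSE, spatiotemporal_field = FALSE)
  mesh <- build_mesh(d[, c("x_km", "y_km")], cutoff_km = 10,
                     extension_km = 20)
  fit <- fit_spatdiet(spec, d, mesh)
  r <- randomized_quantile_residuals(fit, n_sim = 200, seed = 52)
  ks <- suppressWarnings(stats::ks.test(r, "pnorm"))
  expect_lt(ks$p.value, 1e-4)
})
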