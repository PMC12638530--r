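test_that("matern parameters enforce the sqrt(8)/range convention", {
  mp <- matern_params(30, 0.5)
  expect_equal(mp$kappa * mp$range_km, sqrt(8))
  expect_error(matern_params(-1, 1), "positive")
  expect_error(matern_params(10, 0), "positive")
})

test_that("matern correlation is 1 at zero, ~0.14 at the range, decreasing", {
  mp <- matern_params(25, 1)
  expect_identical(matern_correlation(0, mp), 1)
  ## high-precision Bessel value of sqrt(8) K1(sqrt(8)) (scipy oracle)
  expect_equal(matern_correlation(25, mp), 0.1396674740152931, tolerance = 1e-10)
  d <- seq(0.5, 120, by = 0.5)
  rho <- matern_correlation(d, mp)
  expect_true(all(diff(rho) < 0))
  expect_true(all(rho >= 0 & rho <= 1))
  expect_error(matern_correlation(-1, mp), "non-negative")
})

test_that("dense matern covariance matches direct evaluation", {
  mp <- matern_params(12, 1.5)
  ## single point and coincident pair
  expect_equal(dense_matern_covariance(cbind(0, 0), mp),
               matrix(1.5^2, 1, 1))
  C2 <- dense_matern_covariance(rbind(c(1, 1), c(1, 1)), mp)
  expect_equal(C2[1, 2], 1.5^2)
  ## collinear points at 0, r, 2r
  r <- 7
  C3 <- dense_matern_covariance(cbind(c(0, r, 2 * r), 0), mp)
  expect_equal(C3[1, 2], 1.5^2 * matern_correlation(r, mp))
  expect_equal(C3[1, 3], 1.5^2 * matern_correlation(2 * r, mp))
  expect_true(isSymmetric(C3))
  expect_true(all(eigen(C3, only.values = TRUE)$values > -1e-10))
  expect_error(dense_matern_covariance(cbind(NA, 1), mp), "finite")
})

test_that("mesh thinning honours the cutoff and square-corner examples", {
  sq <- rbind(c(0, 0), c(10, 0), c(0, 10), c(10, 10))
  m8 <- build_mesh(sq, cutoff_km = 8, extension_km = 0)
  expect_equal(sum(m8$interior), 4L)  # min pairwise distance 10 >= 8
  m12 <- build_mesh(sq, cutoff_km = 12, extension_km = 20)
  expect_lt(sum(m12$interior), 4L)    # thinning by insertion order
  expect_gte(min(dist(m12$loc)), 12)
  set.seed(2)
  pts <- cbind(runif(80, 0, 60), runif(80, 0, 60))
  m <- build_mesh(pts, cutoff_km = 6, extension_km = 30)
  expect_gte(min(dist(m$loc)), 6)
  expect_error(build_mesh(sq, cutoff_km = 50), "diameter")
})

test_that("mesh round-trips through its plain-text serialization", {
  set.seed(3)
  m <- build_mesh(cbind(runif(40, 0, 50), runif(40, 0, 50)), 6, 25)
  pre <- file.path(tempdir(), "mesh_test")
  write_mesh(m, pre)
  m2 <- read_mesh(pre)
  expect_equal(m2$loc, m$loc)
  expect_equal(m2$tri, m$tri)
  expect_equal(m2$cutoff_km, m$cutoff_km)
})

test_that("projector rows are barycentric weights", {
  set.seed(4)
  m <- build_mesh(cbind(runif(50, 0, 60), runif(50, 0, 60)), 6, 30)
  ## at a vertex: single weight 1
  A <- project(m, m$loc[5, , drop = FALSE])
  expect_equal(A[1, 5], 1)
  expect_equal(Matrix::rowSums(A), 1, tolerance = 1e-12)
  ## at a triangle centroid: three weights of 1/3
  tri1 <- m$tri[1, ]
  centroid <- colMeans(m$loc[tri1, ])
  Ac <- project(m, rbind(centroid))
  expect_equal(sort(as.numeric(Ac[1, tri1])), rep(1 / 3, 3), tolerance = 1e-9)
  ## convexity: interpolated values within node-value range, rows sum to 1
  pts <- cbind(runif(200, 10, 50), runif(200, 10, 50))
  Ap <- project(m, pts)
  expect_equal(unname(Matrix::rowSums(Ap)), rep(1, 200), tolerance = 1e-12)
  f <- rnorm(nrow(m$loc))
  v <- as.vector(Ap %*% f)
  expect_true(all(v <= max(f) + 1e-12 & v >= min(f) - 1e-12))
  expect_error(project(m, cbind(1e4, 1e4)), "outside")
})

test_that("SPDE precision is SPD and agrees with the dense oracle", {
  mp <- matern_params(25, 0.8)
  g <- as.matrix(expand.grid(seq(0, 20, 1.5), seq(0, 20, 1.5)))
  m <- build_mesh(g, cutoff_km = 1.45, extension_km = 50)
  Q <- spde_precision(m, mp)
  expect_true(Matrix::isSymmetric(Q))
  expect_silent(Matrix::Cholesky(Q))  # positive definite
  S <- as.matrix(Matrix::solve(Q))
  ctr <- c(10, 10)
  d2c <- sqrt((m$loc[, 1] - ctr[1])^2 + (m$loc[, 2] - ctr[2])^2)
  ii <- which(m$interior & d2c < 8)
  ## marginal SD of central interior nodes within 5% of sigma
  expect_lt(max(abs(sqrt(diag(S)[ii]) / mp$sigma - 1)), 0.05)
  ## pairwise correlations within 5% relative error of the Matern oracle
  D <- as.matrix(dist(m$loc[ii, ]))
  emp <- cov2cor(S[ii, ii])
  theo <- matrix(matern_correlation(as.vector(D), mp), nrow(D))
  sel <- D > 0 & theo > 0.13
  expect_lt(max(abs(emp[sel] - theo[sel]) / theo[sel]), 0.05)
})

test_that("degenerate triangles are rejected in FEM assembly", {
  m <- list(loc = rbind(c(0, 0), c(1, 0), c(2, 0), c(0, 1)),
            tri = rbind(c(1, 2, 3), c(1, 2, 4)),
            interior = rep(TRUE, 4), cutoff_km = 1, extension_km = 0)
  class(m) <- "spat_mesh"
  expect_error(fem_matrices(m), "triangle 1")
})

test_that("GMRF sampling matches the dense-inverse covariance", {
  set.seed(5)
  B <- matrix(rnorm(25), 5, 5)
  Q <- Matrix::forceSymmetric(Matrix::Matrix(crossprod(B) + diag(5), sparse = TRUE))
  X <- sample_gmrf(Q, n_draws = 10000, seed = 42)
  expect_identical(sample_gmrf(Q, 3, seed = 7), sample_gmrf(Q, 3, seed = 7))
  S <- as.matrix(Matrix::solve(Q))
  emp <- cov(t(X))
  ## chi^2-style bound: element-wise error shrinks like 1/sqrt(n)
  tol <- 4 * max(diag(S)) / sqrt(10000)
  expect_lt(max(abs(emp - S)), tol * 5)
  expect_lt(max(abs(rowMeans(X))), 4 * sqrt(max(diag(S)) / 10000) * 2)
  expect_error(sample_gmrf(Matrix::Diagonal(3, c(1, -1, 1))), "positive definite")
})
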