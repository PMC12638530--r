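#' Finite-element matrices of a mesh
#'
#' Assembles the lumped (diagonal) mass matrix `C` and the stiffness matrix
#' `G` of linear finite elements on the mesh, the building blocks of the
#' SPDE precision.  Mass lumping keeps the precision matrix sparse and is
#' the standard approximation in this setting.
#'
#' @param mesh A `spat_mesh`.
#' @return List with sparse matrices `C` (diagonal) and `G`.
#' @export
fem_matrices <- function(mesh) {
  stopifnot(inherits(mesh, "spat_mesh"))
  loc <- mesh$loc; tri <- mesh$tri
  n <- nrow(loc)
  c_diag <- numeric(n)
  gi <- integer(0); gj <- integer(0); gx <- numeric(0)
  for (t in seq_len(nrow(tri))) {
    v <- tri[t, ]
    p1 <- loc[v[1], ]; p2 <- loc[v[2], ]; p3 <- loc[v[3], ]
    e1 <- p3 - p2; e2 <- p1 - p3; e3 <- p2 - p1
    area <- 0.5 * abs(e3[1] * (-e2[2]) - e3[2] * (-e2[1]))
    if (area < 1e-9)
      stop("degenerate (zero-area) triangle ", t, " in mesh")
    c_diag[v] <- c_diag[v] + area / 3
    E <- rbind(e1, e2, e3)
    Gl <- (E %*% t(E)) / (4 * area)
    gi <- c(gi, rep(v, 3L))
    gj <- c(gj, rep(v, each = 3L))
    gx <- c(gx, as.vector(Gl))
  }
  G <- Matrix::sparseMatrix(i = gi, j = gj, x = gx, dims = c(n, n))
  C <- Matrix::Diagonal(n, c_diag)
  list(C = C, G = G)
}

#' SPDE precision matrix of a Matern field
#'
#' Sparse GMRF precision `Q = tau^2 (kappa^4 C + 2 kappa^2 G + G C^-1 G)`
#' whose inverse approximates the Matern (nu = 1) covariance with the
#' parameters in `params` on the mesh interior.  `C` is the lumped mass
#' matrix and `G` the stiffness matrix; `tau` is fixed by (`kappa`,
#' `sigma`) so that the stationary marginal SD equals `sigma`.
#'
#' @param mesh A `spat_mesh`.
#' @param params A [matern_params()] object.
#' @return Sparse symmetric positive-definite `dsCMatrix`.
#' @export
spde_precision <- function(mesh, params) {
  stopifnot(inherits(params, "matern_params"))
  fem <- fem_matrices(mesh)
  spde_precision_from_fem(fem, params$kappa, params$tau)
}

spde_precision_from_fem <- function(fem, kappa, tau) {
  Cinv <- Matrix::Diagonal(nrow(fem$C), 1 / Matrix::diag(fem$C))
  Q <- tau^2 * (kappa^4 * fem$C + 2 * kappa^2 * fem$G +
                  fem$G %*% Cinv %*% fem$G)
  Matrix::forceSymmetric(Q)
}

#' Sample from a Gaussian Markov random field
#'
#' Draws from `N(0, Q^-1)` by sparse Cholesky back-substitution.
#'
#' @param Q Sparse symmetric positive-definite precision matrix.
#' @param n_draws Number of independent draws.
#' @param seed Optional integer; if supplied, draws are reproducible and
#'   the caller's random-number state is left untouched.
#' @return Matrix with `nrow(Q)` rows and `n_draws` columns.
#' @export
sample_gmrf <- function(Q, n_draws = 1, seed = NULL) {
  ch <- tryCatch(Matrix::Cholesky(Matrix::forceSymmetric(Q), LDL = FALSE,
                                  perm = TRUE),
                 error = function(e) stop("precision matrix is not positive definite: ",
                                          conditionMessage(e)))
  with_seed(seed, {
    z <- matrix(stats::rnorm(nrow(Q) * n_draws), nrow(Q), n_draws)
    rmvn_prec_chol(ch, z)
  })
}

## x = P' L^-T z  so that  Cov(x) = P'(LL')^-1 P = Q^-1
rmvn_prec_chol <- function(ch, z) {
  ex <- Matrix::expand(ch)
  as.matrix(Matrix::crossprod(ex$P, Matrix::solve(Matrix::t(ex$L), z)))
}

## evaluate `code` under a fixed seed without clobbering the global RNG
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  code
}
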