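#' Matern covariance parameters
#'
#' Container for the hyperparameters of a Matern (smoothness nu = 1)
#' Gaussian random field in the SPDE (alpha = 2) convention.  The range is
#' the distance at which spatial correlation has decayed to approximately
#' 0.13; the derived scale is `kappa = sqrt(8) / range_km`, and `tau` is the
#' precision scale that fixes the stationary marginal standard deviation at
#' `sigma` (`tau = 1 / (sqrt(4 * pi) * kappa * sigma)`).
#'
#' @param range_km Correlation range in kilometres (> 0).
#' @param sigma Marginal standard deviation of the field (> 0).
#'
#' @return An object of class `matern_params` with elements `range_km`,
#'   `sigma`, `kappa` and `tau`.
#' @examples
#' mp <- matern_params(30, 0.5)
#' mp$kappa * mp$range_km  # sqrt(8)
#' @export
matern_params <- function(range_km, sigma) {
  stopifnot(is.numeric(range_km), length(range_km) == 1L, is.finite(range_km),
            is.numeric(sigma), length(sigma) == 1L, is.finite(sigma))
  if (range_km <= 0) stop("`range_km` must be positive")
  if (sigma <= 0) stop("`sigma` must be positive")
  kappa <- sqrt(8) / range_km
  tau <- 1 / (sqrt(4 * pi) * kappa * sigma)
  structure(list(range_km = range_km, sigma = sigma, kappa = kappa, tau = tau),
            class = "matern_params")
}

#' @export
print.matern_params <- function(x, ...) {
  cat(sprintf("Matern (nu = 1): range = %g km, sigma = %g (kappa = %g, tau = %g)\n",
              x$range_km, x$sigma, x$kappa, x$tau))
  invisible(x)
}

#' Matern correlation function (nu = 1)
#'
#' Correlation at distance `d` for a Matern field with smoothness 1:
#' `kappa * d * K_1(kappa * d)` for `d > 0` and 1 at `d = 0`, where `K_1` is
#' the modified Bessel function of the second kind of order 1.  At
#' `d = range_km` the correlation equals `sqrt(8) * K_1(sqrt(8))`, about
#' 0.14 -- the conventional "effectively zero" level.
#'
#' @param d Vector of non-negative distances (km).
#' @param params A [matern_params()] object.
#'
#' @return Vector of correlations in `[0, 1]`.
#' @examples
#' mp <- matern_params(30, 1)
#' matern_correlation(c(0, 30), mp)
#' @export
matern_correlation <- function(d, params) {
  stopifnot(inherits(params, "matern_params"))
  if (!is.numeric(d) || anyNA(d) || any(!is.finite(d)))
    stop("distances must be finite numbers")
  if (any(d < 0)) stop("distances must be non-negative")
  kd <- params$kappa * d
  out <- rep(1, length(d))
  pos <- kd > 0
  out[pos] <- kd[pos] * besselK(kd[pos], nu = 1)
  # underflow at very large kd gives 0 * Inf -> NaN; correlation is ~0 there
  out[is.nan(out)] <- 0
  out
}

#' Dense Matern covariance matrix
#'
#' Direct evaluation of the Matern (nu = 1) covariance between a small set
#' of locations.  This is the exact covariance that the sparse SPDE
#' precision matrix ([spde_precision()]) approximates, and serves as its
#' oracle in tests.
#'
#' @param points Two-column matrix or data frame of planar coordinates
#'   (km).  Intended for at most a couple of thousand points.
#' @param params A [matern_params()] object.
#'
#' @return Symmetric positive-semidefinite matrix with diagonal `sigma^2`.
#' @export
dense_matern_covariance <- function(points, params) {
  pts <- as_points(points)
  if (nrow(pts) > 2000)
    stop("dense covariance is only intended for <= 2000 points")
  D <- as.matrix(stats::dist(pts))
  C <- params$sigma^2 * matern_correlation(as.vector(D), params)
  matrix(C, nrow(pts), nrow(pts))
}

## coerce x/y input to a numeric matrix with two columns
as_points <- function(points) {
  if (is.data.frame(points)) {
    nm <- names(points)
    if (all(c("x_km", "y_km") %in% nm)) {
      points <- cbind(points$x_km, points$y_km)
    } else {
      points <- as.matrix(points[, 1:2])
    }
  }
  pts <- as.matrix(points)
  if (ncol(pts) != 2) stop("`points` must have two columns (x_km, y_km)")
  storage.mode(pts) <- "double"
  if (anyNA(pts) || any(!is.finite(pts)))
    stop("coordinates must be finite")
  pts
}

#' Equirectangular projection to planar kilometres
#'
#' Simple equirectangular conversion of longitude/latitude to planar
#' kilometres around a reference point.  All modelling code in this package
#' works in planar projected kilometres; this helper is adequate for
#' regional, synthetic-scale domains but is not a substitute for a proper
#' projection on real survey data.
#'
#' @param lon,lat Coordinates in decimal degrees.
#' @param lon0,lat0 Reference point; defaults to the centroid.
#' @return Data frame with columns `x_km` and `y_km`.
#' @export
lonlat_to_km <- function(lon, lat, lon0 = mean(lon), lat0 = mean(lat)) {
  r_earth <- 6371
  x <- (lon - lon0) * pi / 180 * r_earth * cos(lat0 * pi / 180)
  y <- (lat - lat0) * pi / 180 * r_earth
  data.frame(x_km = x, y_km = y)
}
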