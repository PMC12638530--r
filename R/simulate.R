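#' Synthetic prediction domain
#'
#' Builds a regular grid of square cells with smooth synthetic bathymetry
#' and environmental covariates: depth is a Matern field draw rescaled to
#' 10-150 m (so the 130 m index filter always has cells to act on);
#' temperature, salinity and oxygen are independent smooth fields plus a
#' little white noise, with oxygen constructed to decline with depth.
#' Cells are tiled into square "rectangles" (coarse reporting units that
#' play the role of ICES rectangles for prey biomass series).
#'
#' @param nx,ny Grid dimensions (cells); `nx * ny <= 10000`.
#' @param cell_km Cell side (km); area is `cell_km^2`.
#' @param rect_cells Cells per rectangle side.
#' @param seed Seed; the domain is fully reproducible.
#' @return Data frame with `cell_id`, `x_km`, `y_km`, `area_km2`,
#'   `depth_m`, `temperature_C`, `salinity_permille`,
#'   `oxygen_concentration`, `rect_id`, plus attributes `nx`, `ny`,
#'   `cell_km`.
#' @export
make_domain <- function(nx = 30, ny = 30, cell_km = 3, rect_cells = 10,
                        seed = 1) {
  stopifnot(nx * ny <= 1e4, nx >= 2, ny >= 2)
  g <- expand.grid(ix = seq_len(nx), iy = seq_len(ny))
  x <- (g$ix - 0.5) * cell_km
  y <- (g$iy - 0.5) * cell_km
  pts <- cbind(x, y)
  dom_range <- 0.4 * max(nx, ny) * cell_km
  with_seed(seed, {
    f <- function(range_km) {
      S <- dense_matern_covariance(pts, matern_params(range_km, 1))
      drop(t(chol(S + diag(1e-8, nrow(pts)))) %*% stats::rnorm(nrow(pts)))
    }
    rescale <- function(z, lo, hi) lo + (hi - lo) * (z - min(z)) / diff(range(z))
    depth_f <- f(dom_range)
    depth <- rescale(depth_f, 10, 150)
    temp <- rescale(f(dom_range * 0.8), 4, 12) + stats::rnorm(nrow(pts), 0, 0.2)
    sal <- rescale(f(dom_range * 1.2), 6, 14) + stats::rnorm(nrow(pts), 0, 0.1)
    oxy <- rescale(-0.75 * scale(depth_f) + 0.25 * scale(f(dom_range * 0.7)),
                   0.5, 9) + stats::rnorm(nrow(pts), 0, 0.15)
    out <- data.frame(
      cell_id = seq_len(nrow(pts)), x_km = x, y_km = y,
      area_km2 = cell_km^2, depth_m = depth,
      temperature_C = temp, salinity_permille = sal,
      oxygen_concentration = pmax(oxy, 0.1),
      rect_id = paste0("R", (g$ix - 1) %/% rect_cells + 1, "_",
                       (g$iy - 1) %/% rect_cells + 1))
    attr(out, "nx") <- nx; attr(out, "ny") <- ny; attr(out, "cell_km") <- cell_km
    out
  })
}

#' Ground-truth parameter record for a synthetic scenario
#'
#' Collects every quantity the generator needs: model parameters for the
#' predator-biomass and diet models, Matern hyperparameters, the sampling
#' design, and prey-field construction parameters.  Regenerating a
#' scenario from the same truth and seed is bitwise reproducible.
#'
#' The defaults encode the package's reference study conditions: a
#' 90 x 90 km domain of 3 x 3 km cells, 15 survey years in quarters 1 and
#' 4, 60 hauls and 300 stomachs per year, a Tweedie diet response with a
#' saturating (breakpoint) response to local prey density, and a
#' Poisson-link delta-gamma biomass response with an oxygen breakpoint
#' and random-walk time-varying depth preferences.
#'
#' @param n_years Number of survey years.
#' @param b0,b1 Breakpoint slope and threshold (standardized prey scale)
#'   of the diet model; `b0 = 0` switches prey coupling off.
#' @param missing_years Years (indices 1..n_years) with no stomach
#'   sampling, exercising AR(1) interpolation.
#' @param diet_family `"tweedie"` or `"poisson_link_delta_gamma"`.
#' @param unbalanced Logical: alternate reduced spatial coverage across
#'   years (uneven survey effort).
#' @param prey_attraction Mean slope of predator log group-density on the
#'   standardized log local prey density: the predator aggregates on its
#'   prey, so the two distributions co-vary.  Set to 0 for independent
#'   distributions.
#' @param prey_attraction_sd Year-to-year SD of that slope: the predator
#'   shifts toward or away from the prey map across years, which is what
#'   makes annual overlap (and with it predation) vary.  Kept below the
#'   level at which the predator out-concentrates the prey map itself
#'   (overlap responds non-monotonically beyond that).
#' @param prey_mode `"static_raster"` (benthic-type prey, constant over
#'   years) or `"rectangle_series"` (pelagic-type rectangle biomass).
#' @param n_hauls_per_year,n_stomachs_per_year Sampling effort.
#' @param range_km,sigma_omega,sigma_epsilon Shared Matern range and field
#'   SDs of the diet model; the biomass model has its own entries in the
#'   returned list.
#' @return A list of class `scenario_truth`.
#' @export
scenario_truth <- function(n_years = 15, b0 = 0.5, b1 = 0.5,
                           missing_years = integer(),
                           diet_family = "tweedie",
                           unbalanced = TRUE,
                           n_hauls_per_year = 60,
                           n_stomachs_per_year = 300,
                           range_km = 30, sigma_omega = 0.3,
                           sigma_epsilon = 0.15,
                           prey_attraction = 0.3,
                           prey_attraction_sd = 0,
                           prey_mode = "static_raster") {
  years <- 2000 + seq_len(n_years)
  structure(list(
    years = years, missing_years = missing_years,
    n_hauls_per_year = n_hauls_per_year,
    n_stomachs_per_year = n_stomachs_per_year,
    unbalanced = unbalanced,
    diet = list(
      family = diet_family,
      intercept = -4.2, ar1_rho = 0.7, ar1_sigma = 0.1,
      depth_slope = -0.2, length_slope = 0.15,
      b0 = b0, b1 = b1,
      month_sigma = 0,           # month intercepts off unless set > 0
      range_km = range_km, sigma_omega = sigma_omega,
      sigma_epsilon = sigma_epsilon,
      tweedie_power = 1.6, tweedie_phi = 1.2,
      # delta-gamma alternative (used by the misspecified-family scenario)
      dg_intercept1 = -0.8, dg_intercept2 = -4.0, dg_shape = 0.7),
    biomass = list(
      intercept1 = 0.3, intercept2 = 5.5,
      year_sd = 0.1,             # iid fixed year effects, drawn once
      quarter4_1 = 0.3, quarter4_2 = 0.1,
      salinity = 0.1, temperature = 0.2, temperature2 = -0.15,
      oxygen_b0 = 0.4, oxygen_b1 = 0.3,
      depth_rw_start = -0.2, depth_rw_sd = 0.3,
      depth2_rw_start = -0.3, depth2_rw_sd = 0.05,
      prey_attraction = prey_attraction,
      prey_attraction_sd = prey_attraction_sd,
      range_km = range_km, sigma_omega = 0.3, sigma_epsilon = 0.2,
      sigma_zeta = 0.25,         # spatially varying quarter-4 coefficient
      gamma_shape = 1.5),
    prey = list(mode = prey_mode, base_density = 3000,
                lognorm_sd = 0.5, spatial_gradient = 1,
                static_range_km = 35, static_sigma = 0.7,
                # benthic prey concentrates at particular depths; the
                # predator's drifting depth preference then moves it on
                # and off the prey beds (the recoverable coupling channel)
                depth_loading = -0.7),
    length_mass = list(exponent = 3.05, condition_base = 0.0085,
                       condition_amp = 0.1),
    predator_length_mean = 33, predator_length_sd = 6
  ), class = "scenario_truth")
}

## reference standardization constants a generator-side covariate uses; the
## slopes in `scenario_truth` are defined on these scales
domain_standardizers <- function(domain) {
  list(depth = c(center = mean(domain$depth_m), scale = stats::sd(domain$depth_m)),
       temperature = c(center = mean(domain$temperature_C),
                       scale = stats::sd(domain$temperature_C)),
       salinity = c(center = mean(domain$salinity_permille),
                    scale = stats::sd(domain$salinity_permille)),
       oxygen = c(center = mean(domain$oxygen_concentration),
                  scale = stats::sd(domain$oxygen_concentration)))
}

## simulation mesh + node draws for (omega, epsilon-by-year); fields are
## sampled as GMRFs on a mesh over the domain and projected to locations
sim_fields <- function(domain, range_km, sigma_omega, sigma_epsilon,
                       n_years, sigma_zeta = 0) {
  pts <- cbind(domain$x_km, domain$y_km)
  mesh <- build_mesh(pts, cutoff_km = 2 * attr(domain, "cell_km"),
                     extension_km = 1.5 * range_km)
  out <- list(mesh = mesh)
  if (sigma_omega > 0) {
    Q <- spde_precision(mesh, matern_params(range_km, sigma_omega))
    out$omega <- sample_gmrf(Q, 1)[, 1]
  }
  if (sigma_epsilon > 0) {
    Q <- spde_precision(mesh, matern_params(range_km, sigma_epsilon))
    out$epsilon <- sample_gmrf(Q, n_years)
  }
  if (sigma_zeta > 0) {
    Q <- spde_precision(mesh, matern_params(range_km, sigma_zeta))
    out$zeta <- sample_gmrf(Q, 1)[, 1]
  }
  out
}

## local prey density for records in `cell` during year `year_val`
## (rectangle-series or static-raster prey input)
prey_density_at <- function(domain, prey, cell, year_val) {
  if ("rect_id" %in% names(prey)) {
    rect_area <- tapply(domain$area_km2, domain$rect_id, sum)
    dens <- prey$biomass_kg / rect_area[as.character(prey$rect_id)]
    key <- paste(domain$rect_id[cell], year_val)
    as.vector(dens[match(key, paste(prey$rect_id, prey$year))])
  } else {
    prey$prey_density[match(cell, prey$cell_id)]
  }
}

## nearest-cell lookup of domain rows for arbitrary locations
nearest_cell <- function(domain, x, y) {
  cell_km <- attr(domain, "cell_km")
  nx <- attr(domain, "nx"); ny <- attr(domain, "ny")
  ix <- pmin(pmax(ceiling(x / cell_km), 1), nx)
  iy <- pmin(pmax(ceiling(y / cell_km), 1), ny)
  (iy - 1) * nx + ix
}

## per-year spatial inclusion window (uneven survey coverage)
coverage_window <- function(year_index, unbalanced, extent) {
  if (!unbalanced || year_index %% 3 == 1) return(c(0, extent))
  if (year_index %% 3 == 2) c(0, 0.65 * extent) else c(0.35 * extent, extent)
}

#' Simulate prey fields
#'
#' Either a static raster (benthic prey whose predicted distribution is
#' constant over time) or a rectangle-level biomass series (pelagic prey
#' assessed acoustically per reporting rectangle, varying across years
#' with log-normal innovations over a fixed spatial gradient).
#'
#' @param domain A [make_domain()] grid.
#' @param truth A [scenario_truth()].
#' @param mode `"static_raster"` or `"rectangle_series"`.
#' @param seed Seed.
#' @return For `static_raster`, data frame `cell_id`, `prey_density`; for
#'   `rectangle_series`, data frame `rect_id`, `year`, `biomass_kg`.
#' @export
simulate_prey_fields <- function(domain, truth,
                                 mode = truth$prey$mode, seed = 1) {
  pars <- truth$prey
  with_seed(seed, {
    if (mode == "static_raster") {
      pts <- cbind(domain$x_km, domain$y_km)
      S <- dense_matern_covariance(pts, matern_params(pars$static_range_km,
                                                      pars$static_sigma))
      f <- drop(t(chol(S + diag(1e-8, nrow(pts)))) %*% stats::rnorm(nrow(pts)))
      dl <- if (is.null(pars$depth_loading)) 0 else pars$depth_loading
      ds <- (domain$depth_m - mean(domain$depth_m)) / stats::sd(domain$depth_m)
      data.frame(cell_id = domain$cell_id,
                 prey_density = pars$base_density *
                   exp(dl * ds + f - max(f) / 2))
    } else if (mode == "rectangle_series") {
      rects <- unique(domain$rect_id)
      area <- tapply(domain$area_km2, domain$rect_id, sum)[rects]
      ## fixed west-east gradient in baseline density
      cx <- tapply(domain$x_km, domain$rect_id, mean)[rects]
      base <- pars$base_density *
        exp(pars$spatial_gradient * (cx - mean(cx)) / max(abs(cx - mean(cx))))
      out <- expand.grid(rect_id = rects, year = truth$years,
                         KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
      innov <- matrix(stats::rnorm(length(rects) * length(truth$years), 0,
                                   pars$lognorm_sd),
                      length(rects), length(truth$years))
      out$biomass_kg <- base[match(out$rect_id, rects)] *
        area[match(out$rect_id, rects)] *
        exp(innov[cbind(match(out$rect_id, rects),
                        match(out$year, truth$years))])
      out
    } else stop("unknown prey mode: ", mode)
  })
}

#' Simulate a predator biomass-density survey
#'
#' Haul locations are uniform over the (optionally year-restricted)
#' domain in quarters 1 and 4; biomass density is drawn from the
#' Poisson-link delta-gamma model with fixed year effects, a quarter
#' effect (plus a spatially varying quarter coefficient), linear
#' salinity / temperature / temperature-squared effects, an oxygen
#' breakpoint, random-walk time-varying depth and depth-squared effects,
#' and spatial (`omega`) plus iid-by-year (`epsilon`) Matern fields.  The
#' second linear predictor carries the intercept and quarter effect only.
#'
#' @param truth A [scenario_truth()].
#' @param domain A [make_domain()] grid.
#' @param prey Optional prey input from [simulate_prey_fields()]; when
#'   supplied and `prey_attraction` is non-zero, the predator's log group
#'   density gains a `prey_attraction * standardized log prey density`
#'   term, so the predator distribution co-varies with its prey.
#' @param seed Seed.
#' @return List: `hauls` (survey records), `truth_effects` (the realized
#'   year effects and random-walk series), `fields` (mesh and node
#'   values, reused for truth-level predictions).
#' @export
simulate_predator_survey <- function(truth, domain, prey = NULL, seed = 1) {
  bm <- truth$biomass
  ny <- length(truth$years)
  std <- domain_standardizers(domain)
  with_seed(seed, {
    fld <- sim_fields(domain, bm$range_km, bm$sigma_omega, bm$sigma_epsilon,
                      ny, bm$sigma_zeta)
    year_eff <- stats::rnorm(ny, 0, bm$year_sd)
    g_depth <- bm$depth_rw_start + c(0, sim_rw(ny - 1, bm$depth_rw_sd))
    g_depth2 <- bm$depth2_rw_start + c(0, sim_rw(ny - 1, bm$depth2_rw_sd))

    n <- truth$n_hauls_per_year * ny
    extent_x <- attr(domain, "nx") * attr(domain, "cell_km")
    extent_y <- attr(domain, "ny") * attr(domain, "cell_km")
    year_i <- rep(seq_len(ny), each = truth$n_hauls_per_year)
    xw <- t(vapply(year_i, coverage_window, numeric(2),
                   unbalanced = truth$unbalanced, extent = extent_x))
    x <- stats::runif(n, xw[, 1], xw[, 2])
    y <- stats::runif(n, 0, extent_y)
    quarter <- rep_len(c(1L, 4L), n)
    month <- ifelse(quarter == 1L, sample(2:3, n, TRUE), sample(10:11, n, TRUE))
    cell <- nearest_cell(domain, x, y)

    ds <- (domain$depth_m[cell] - std$depth["center"]) / std$depth["scale"]
    ts <- (domain$temperature_C[cell] - std$temperature["center"]) /
      std$temperature["scale"]
    ss <- (domain$salinity_permille[cell] - std$salinity["center"]) /
      std$salinity["scale"]
    os <- (domain$oxygen_concentration[cell] - std$oxygen["center"]) /
      std$oxygen["scale"]
    q4 <- as.numeric(quarter == 4L)

    Ah <- project(fld$mesh, cbind(x, y))
    om <- if (is.null(fld$omega)) 0 else as.vector(Ah %*% fld$omega)
    ep <- if (is.null(fld$epsilon)) 0 else
      as.matrix(Ah %*% fld$epsilon)[cbind(seq_len(n), year_i)]
    ze <- if (is.null(fld$zeta)) 0 else as.vector(Ah %*% fld$zeta)

    a_t <- rep(0, ny)
    pa <- if (is.null(bm$prey_attraction)) 0 else bm$prey_attraction
    pa_sd <- if (is.null(bm$prey_attraction_sd)) 0 else bm$prey_attraction_sd
    attraction <- 0
    if (!is.null(prey) && (pa != 0 || pa_sd > 0)) {
      a_t <- pa + stats::rnorm(ny, 0, pa_sd)
      pd <- prey_density_at(domain, prey, cell, truth$years[year_i])
      lp <- log(pd)
      attraction <- a_t[year_i] * (lp - mean(lp)) / stats::sd(lp)
    }

    ## spatial part of the first predictor at the hauls ...
    spat <- bm$quarter4_1 * q4 +
      bm$salinity * ss + bm$temperature * ts + bm$temperature2 * ts^2 +
      breakpoint_effect(os, bm$oxygen_b0, bm$oxygen_b1) +
      g_depth[year_i] * ds + g_depth2[year_i] * ds^2 +
      om + ep + ze * q4 + attraction

    ## ... and on the full grid (quarter 4), to normalize each year's
    ## surface: a shifting distribution must not manufacture or destroy
    ## stock biomass, so yearly totals follow the year effects alone.
    ## The normalizer is a per-year constant that a fitted year factor
    ## absorbs exactly.
    cells_xy <- cbind(domain$x_km, domain$y_km)
    Ac <- project(fld$mesh, cells_xy)
    om_c <- if (is.null(fld$omega)) 0 else as.vector(Ac %*% fld$omega)
    ep_c <- if (is.null(fld$epsilon)) matrix(0, nrow(domain), ny) else
      as.matrix(Ac %*% fld$epsilon)
    ze_c <- if (is.null(fld$zeta)) 0 else as.vector(Ac %*% fld$zeta)
    std_c <- domain_standardizers(domain)
    ds_c <- (domain$depth_m - std_c$depth["center"]) / std_c$depth["scale"]
    ts_c <- (domain$temperature_C - std_c$temperature["center"]) /
      std_c$temperature["scale"]
    ss_c <- (domain$salinity_permille - std_c$salinity["center"]) /
      std_c$salinity["scale"]
    os_c <- (domain$oxygen_concentration - std_c$oxygen["center"]) /
      std_c$oxygen["scale"]
    att_c <- 0
    if (!is.null(prey) && (pa != 0 || pa_sd > 0)) {
      pd_all <- prey_density_at(domain, prey, domain$cell_id,
                                rep(truth$years[1], nrow(domain)))
      lpa <- log(pd_all)
      att_base <- (lpa - mean(lpa)) / stats::sd(lpa)
    }
    znorm <- numeric(ny)
    for (t in seq_len(ny)) {
      att_c <- if (!is.null(prey) && (pa != 0 || pa_sd > 0)) {
        if ("rect_id" %in% names(prey)) {
          pd_t <- prey_density_at(domain, prey, domain$cell_id,
                                  rep(truth$years[t], nrow(domain)))
          lp_t <- log(pd_t)
          a_t[t] * (lp_t - mean(lp_t)) / stats::sd(lp_t)
        } else a_t[t] * att_base
      } else 0
      s_c <- bm$quarter4_1 + bm$salinity * ss_c + bm$temperature * ts_c +
        bm$temperature2 * ts_c^2 +
        breakpoint_effect(os_c, bm$oxygen_b0, bm$oxygen_b1) +
        g_depth[t] * ds_c + g_depth2[t] * ds_c^2 +
        om_c + ep_c[, t] + ze_c + att_c
      znorm[t] <- log(mean(exp(s_c)))
    }

    eta1 <- bm$intercept1 + year_eff[year_i] + spat - znorm[year_i]
    eta2 <- bm$intercept2 + bm$quarter4_2 * q4
    pl <- poisson_link(eta1, eta2)
    dens <- rdelta_gamma(n, pl$p, pl$r, bm$gamma_shape)

    hauls <- data.frame(
      x_km = x, y_km = y, year = truth$years[year_i],
      quarter = quarter, month = month,
      biomass_density = dens,
      depth_m = domain$depth_m[cell],
      temperature_C = domain$temperature_C[cell],
      salinity_permille = domain$salinity_permille[cell],
      oxygen_concentration = domain$oxygen_concentration[cell])
    list(hauls = hauls,
         truth_effects = list(year_eff = year_eff, g_depth = g_depth,
                              g_depth2 = g_depth2, attraction = a_t,
                              znorm = znorm),
         fields = fld)
  })
}

#' Simulate stomach-content records
#'
#' Stomach sampling locations are uniform over the (optionally
#' year-restricted) domain; listed missing years receive no samples.
#' Relative prey mass is drawn from the diet model of the truth record:
#' AR(1) annual intercept, optional month random intercepts, linear depth
#' and predator-length effects, a breakpoint effect of local prey
#' density, and `omega` / `epsilon` Matern fields, with a Tweedie or
#' Poisson-link delta-gamma observation family.
#'
#' @param truth A [scenario_truth()].
#' @param domain A [make_domain()] grid.
#' @param prey Prey input from [simulate_prey_fields()] (either mode).
#' @param seed Seed.
#' @return List: `stomachs` (records), `truth_effects` (realized AR(1)
#'   series, month effects, prey standardization constants), `fields`.
#' @export
simulate_stomachs <- function(truth, domain, prey, seed = 1) {
  dt <- truth$diet
  ny <- length(truth$years)
  std <- domain_standardizers(domain)
  lm_par <- truth$length_mass
  with_seed(seed, {
    fld <- sim_fields(domain, dt$range_km, dt$sigma_omega, dt$sigma_epsilon, ny)
    gamma_t <- sim_ar1(ny, dt$ar1_rho, dt$ar1_sigma)
    alpha_m <- if (dt$month_sigma > 0) stats::rnorm(12, 0, dt$month_sigma)
               else rep(0, 12)
    cond <- lm_par$condition_base *
      (1 + lm_par$condition_amp * sin(seq_len(ny) / ny * 2 * pi))

    keep_years <- setdiff(seq_len(ny), truth$missing_years)
    n <- truth$n_stomachs_per_year * length(keep_years)
    year_i <- rep(keep_years, each = truth$n_stomachs_per_year)
    extent_x <- attr(domain, "nx") * attr(domain, "cell_km")
    extent_y <- attr(domain, "ny") * attr(domain, "cell_km")
    xw <- t(vapply(year_i, coverage_window, numeric(2),
                   unbalanced = truth$unbalanced, extent = extent_x))
    x <- stats::runif(n, xw[, 1], xw[, 2])
    y <- stats::runif(n, 0, extent_y)
    quarter <- ifelse(stats::runif(n) < 0.6, 4L, 1L)  # most diet sampling in Q4
    month <- ifelse(quarter == 1L, sample(1:3, n, TRUE), sample(10:12, n, TRUE))
    cell <- nearest_cell(domain, x, y)

    ## local prey covariate: rectangle biomass density or static raster
    prey_cov <- if ("rect_id" %in% names(prey)) {
      rect_area <- tapply(domain$area_km2, domain$rect_id, sum)
      dens_tab <- prey
      dens_tab$density <- dens_tab$biomass_kg /
        rect_area[as.character(dens_tab$rect_id)]
      key <- paste(domain$rect_id[cell], truth$years[year_i])
      dens_tab$density[match(key, paste(dens_tab$rect_id, dens_tab$year))]
    } else {
      prey$prey_density[match(cell, prey$cell_id)]
    }
    ## the prey covariate acts on the log scale: biomass densities span
    ## orders of magnitude, and a hockey stick on the raw scale would be
    ## dominated by the long right tail
    log_prey <- log(prey_cov)
    prey_std <- c(center = mean(log_prey), scale = stats::sd(log_prey))
    ps <- (log_prey - prey_std["center"]) / prey_std["scale"]

    len <- pmax(stats::rnorm(n, truth$predator_length_mean,
                             truth$predator_length_sd), 12)
    mass <- length_mass(len, condition_factor = cond[year_i],
                        exponent = lm_par$exponent)
    ds <- (domain$depth_m[cell] - std$depth["center"]) / std$depth["scale"]
    ls <- (len - truth$predator_length_mean) / truth$predator_length_sd

    As <- project(fld$mesh, cbind(x, y))
    om <- if (is.null(fld$omega)) 0 else as.vector(As %*% fld$omega)
    ep <- if (is.null(fld$epsilon)) 0 else
      as.matrix(As %*% fld$epsilon)[cbind(seq_len(n), year_i)]

    base_eta <- gamma_t[year_i] + alpha_m[month] + dt$depth_slope * ds +
      dt$length_slope * ls + breakpoint_effect(ps, dt$b0, dt$b1) + om + ep

    if (dt$family == "tweedie") {
      mu <- exp(dt$intercept + base_eta)
      rpm <- rtweedie(n, mu, dt$tweedie_power, dt$tweedie_phi)
    } else {
      pl <- poisson_link(dt$dg_intercept1 + base_eta,
                         dt$dg_intercept2 + 0.5 * base_eta)
      rpm <- rdelta_gamma(n, pl$p, pl$r, dt$dg_shape)
    }

    stomachs <- data.frame(
      x_km = x, y_km = y, year = truth$years[year_i],
      quarter = quarter, month = month,
      predator_length_cm = len, predator_mass_g = mass,
      prey_mass_g = rpm * mass,
      relative_prey_mass = rpm,
      prey_density = prey_cov,
      log_prey_density = log_prey,
      depth_m = domain$depth_m[cell])
    list(stomachs = stomachs,
         truth_effects = list(gamma_t = gamma_t, alpha_m = alpha_m,
                              prey_std = prey_std,
                              condition_factors = cond),
         fields = fld)
  })
}

#' Length-mass conversion
#'
#' `mass_g = c * length_cm^b` with a species-specific condition factor
#' `c` and exponent `b`; an optional year-indexed condition table lets the
#' condition factor vary annually.
#'
#' @param length_cm Predator length (cm).
#' @param condition_factor Condition factor `c` (recycled), or use
#'   `condition_table`.
#' @param exponent Mass-length exponent `b`.
#' @param year,condition_table Optional: `condition_table` is a data
#'   frame with columns `year` and `c`; each record's year selects its
#'   factor.
#' @return Mass in grams.
#' @export
length_mass <- function(length_cm, condition_factor = 0.0085,
                        exponent = 3, year = NULL, condition_table = NULL) {
  stopifnot(all(length_cm > 0), all(condition_factor > 0), exponent > 0)
  if (!is.null(condition_table)) {
    if (is.null(year)) stop("`year` is required with a condition table")
    idx <- match(year, condition_table$year)
    if (anyNA(idx)) stop("year(s) missing from the condition table")
    condition_factor <- condition_table$c[idx]
  }
  condition_factor * length_cm^exponent
}

#' Scenario library
#'
#' Canned synthetic scenarios with known ground truth:
#' `scenario_strong_coupling` has a strongly saturating positive effect of
#' local prey density on the diet (`b0 = 0.5`, `b1 = 0.5`);
#' `scenario_no_coupling` sets `b0 = 0` (diet independent of prey);
#' `scenario_missing_year` drops all stomach sampling in one year to
#' exercise AR(1) interpolation; `scenario_misspecified_family` generates
#' heavily zero-inflated delta-gamma diet data (to be mis-fit with a
#' Tweedie model in diagnostics checks).
#'
#' @param seed Integer seed controlling every random component.
#' @param n_years,n_hauls_per_year,n_stomachs_per_year Scale overrides.
#' @param ... Further arguments passed to [scenario_truth()].
#' @return List with `truth`, `domain`, `prey`, `hauls`, `stomachs`,
#'   `haul_truth`, `stomach_truth`.
#' @export
scenario_strong_coupling <- function(seed = 1, n_years = 15,
                                     n_hauls_per_year = 60,
                                     n_stomachs_per_year = 300, ...) {
  truth <- scenario_truth(n_years = n_years, b0 = 1.0, b1 = 0.8,
                          n_hauls_per_year = n_hauls_per_year,
                          n_stomachs_per_year = n_stomachs_per_year, ...)
  build_scenario(truth, seed)
}

#' @rdname scenario_strong_coupling
#' @export
scenario_no_coupling <- function(seed = 1, n_years = 15,
                                 n_hauls_per_year = 60,
                                 n_stomachs_per_year = 300, ...) {
  truth <- scenario_truth(n_years = n_years, b0 = 0, b1 = 0.5,
                          prey_attraction = 0, prey_attraction_sd = 0,
                          n_hauls_per_year = n_hauls_per_year,
                          n_stomachs_per_year = n_stomachs_per_year, ...)
  truth$prey$depth_loading <- 0   # prey independent of the predator's
                                  # depth-structured distribution
  build_scenario(truth, seed)
}

#' @rdname scenario_strong_coupling
#' @export
scenario_missing_year <- function(seed = 1, n_years = 15, ...) {
  truth <- scenario_truth(n_years = n_years, b0 = 1.0, b1 = 0.8,
                          missing_years = ceiling(n_years * 2 / 3), ...)
  build_scenario(truth, seed)
}

#' @rdname scenario_strong_coupling
#' @export
scenario_misspecified_family <- function(seed = 1, n_years = 15, ...) {
  truth <- scenario_truth(n_years = n_years, b0 = 1.0, b1 = 0.8,
                          diet_family = "poisson_link_delta_gamma", ...)
  build_scenario(truth, seed)
}

build_scenario <- function(truth, seed) {
  domain <- make_domain(seed = seed)
  prey <- simulate_prey_fields(domain, truth, seed = seed + 1)
  sv <- simulate_predator_survey(truth, domain, prey, seed = seed + 2)
  st <- simulate_stomachs(truth, domain, prey, seed = seed + 3)
  list(truth = truth, domain = domain, prey = prey,
       hauls = sv$hauls, stomachs = st$stomachs,
       haul_truth = sv$truth_effects, stomach_truth = st$truth_effects)
}

#' Serialize a scenario truth record
#'
#' @param truth A `scenario_truth`.
#' @param path File path for the JSON text.
#' @export
write_scenario_truth <- function(truth, path) {
  jsonlite::write_json(unclass(truth), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_scenario_truth
#' @export
read_scenario_truth <- function(path) {
  out <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(out, class = "scenario_truth")
}
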