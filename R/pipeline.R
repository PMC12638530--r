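#' Validate pipeline input tables
#'
#' Schema checks for the survey-haul, stomach, grid and (optional)
#' rectangle-biomass tables: required columns, finite coordinates,
#' quarter/month ranges, non-negative responses.  Schema violations stop
#' with an informative error; suspicious but legal values produce
#' warnings collected in the report.
#'
#' @param hauls,stomachs,grid,rect_biomass Input data frames (any may be
#'   `NULL` to skip its checks).
#' @return A list of class `validation_report` with `ok = TRUE` and any
#'   `warnings`.
#' @export
validate_inputs <- function(hauls = NULL, stomachs = NULL, grid = NULL,
                            rect_biomass = NULL) {
  warns <- character(0)
  need <- function(df, cols, what) {
    miss <- setdiff(cols, names(df))
    if (length(miss))
      stop(what, ": missing column(s): ", paste(miss, collapse = ", "))
  }
  check_coords <- function(df, what) {
    bad <- !is.finite(df$x_km) | !is.finite(df$y_km)
    if (any(bad))
      stop(what, ": non-finite coordinates in rows ",
           paste(utils::head(which(bad), 10), collapse = ", "))
  }
  check_nonneg <- function(df, col, what) {
    bad <- which(df[[col]] < 0 | !is.finite(df[[col]]))
    if (length(bad))
      stop(what, ": negative or non-finite `", col, "` in rows ",
           paste(utils::head(bad, 10), collapse = ", "))
  }
  if (!is.null(hauls)) {
    need(hauls, c("x_km", "y_km", "year", "quarter", "biomass_density",
                  "depth_m"), "hauls")
    check_coords(hauls, "hauls")
    check_nonneg(hauls, "biomass_density", "hauls")
    if (!all(hauls$quarter %in% 1:4)) stop("hauls: quarter must be in 1..4")
    if (mean(hauls$biomass_density == 0) > 0.95)
      warns <- c(warns, "hauls: >95% zero biomass densities")
  }
  if (!is.null(stomachs)) {
    need(stomachs, c("x_km", "y_km", "year", "month", "predator_length_cm",
                     "relative_prey_mass"), "stomachs")
    check_coords(stomachs, "stomachs")
    check_nonneg(stomachs, "relative_prey_mass", "stomachs")
    if (!all(stomachs$month %in% 1:12)) stop("stomachs: month must be in 1..12")
    if (any(stomachs$relative_prey_mass > 1))
      warns <- c(warns,
                 "stomachs: relative prey mass > 1 kg/kg present (will be screened at prediction)")
  }
  if (!is.null(grid)) {
    need(grid, c("cell_id", "x_km", "y_km", "area_km2", "depth_m"), "grid")
    check_coords(grid, "grid")
    if (any(grid$area_km2 <= 0)) stop("grid: non-positive cell areas")
  }
  if (!is.null(rect_biomass)) {
    need(rect_biomass, c("rect_id", "year", "biomass_kg"), "rect_biomass")
    check_nonneg(rect_biomass, "biomass_kg", "rect_biomass")
  }
  structure(list(ok = TRUE, warnings = warns), class = "validation_report")
}

#' Pipeline configuration
#'
#' Bundles every tunable of the end-to-end run, with defaults matching
#' the reference analysis: mesh cutoffs of 8 km (diet) and 10 km
#' (biomass), 500 joint-precision draws, screening at the 99.99th density
#' percentile, a relative-prey-mass ceiling of 1 kg/kg, a 130 m depth
#' cutoff, predictions for a 33 cm predator, and fourth-quarter overlap.
#'
#' @param cutoff_diet_km,cutoff_biomass_km Mesh cutoffs (km).
#' @param extension_km Mesh extension-ring width (km).
#' @param n_draws Joint-precision draws for uncertainty propagation.
#' @param cod_pct,rpm_max,depth_max_m Prediction filters.
#' @param predator_length_cm Prediction length (cm).
#' @param overlap_quarter Quarter used for overlap (and index) predictions.
#' @param exclude_empty_stomachs Drop zero-prey stomach records before
#'   the diet fit (sensitivity switch; the default keeps all stomachs).
#' @param candidate_prey_models Prey-effect forms compared by marginal
#'   AIC.
#' @param seed Seed governing draws.
#' @param outdir Output directory (`NULL` = do not write files).
#' @export
pipeline_config <- function(cutoff_diet_km = 8, cutoff_biomass_km = 10,
                            extension_km = 45, n_draws = 500,
                            cod_pct = 99.99, rpm_max = 1.0,
                            depth_max_m = 130, predator_length_cm = 33,
                            overlap_quarter = 4,
                            exclude_empty_stomachs = FALSE,
                            candidate_prey_models = c("breakpoint",
                                                      "linear", "none"),
                            seed = 1, outdir = NULL) {
  as.list(environment())
}

## default model structures; kept lean in the second linear predictor so
## desk-scale runs stay fast (see the methods vignette)
default_biomass_spec <- function() {
  model_spec("biomass_density", "poisson_link_delta_gamma",
             fixed = ~ factor(year) + quarter4 + salinity_permille +
               temperature_C + I(temperature_C^2),
             breakpoint = "oxygen_concentration",
             time_varying = list(depth_m = "rw", depth2 = "rw"),
             svc = "quarter4",
             spatial_field = TRUE, spatiotemporal_field = TRUE,
             fixed2 = ~ quarter4,
             breakpoint2 = character(), time_varying2 = list(),
             svc2 = character(), spatial_field2 = FALSE,
             spatiotemporal_field2 = FALSE)
}

default_diet_spec <- function(prey_model = c("breakpoint", "linear", "none"),
                              family = "tweedie",
                              month_random_intercept = FALSE) {
  prey_model <- match.arg(prey_model)
  fixed <- switch(prey_model,
                  breakpoint = ~ depth_m + predator_length_cm,
                  linear = ~ depth_m + predator_length_cm + log_prey_density,
                  none = ~ depth_m + predator_length_cm)
  model_spec("relative_prey_mass", family, fixed = fixed,
             breakpoint = if (prey_model == "breakpoint") "log_prey_density"
                          else character(),
             time_varying = list(intercept = "ar1"),
             month_random_intercept = month_random_intercept,
             spatial_field = TRUE, spatiotemporal_field = TRUE)
}

#' Run the full predation-index pipeline
#'
#' Orchestrates the complete workflow: validate inputs, build meshes, fit
#' the predator biomass-density model, fit the candidate diet models
#' (breakpoint / linear / no-prey, compared by marginal AIC), predict
#' both responses on the grid for every year under joint-precision draws,
#' apply the screening filters, and compute annual predation indices,
#' predator-prey overlap, and their correlation.
#'
#' @param hauls,stomachs,grid Input tables (see [validate_inputs()]).
#'   The grid is the cell table (one row per cell); it is expanded
#'   internally to cell x year for the prediction quarter.
#' @param prey Prey input: a rectangle series (`rect_id`, `year`,
#'   `biomass_kg`) or a static raster (`cell_id`, `prey_density`).
#' @param config A [pipeline_config()].
#' @param biomass_spec,diet_specs Optional overrides of the default model
#'   structures; `diet_specs` is a named list of [model_spec()]s, one per
#'   candidate prey-effect form.
#' @return List of class `spatdiet_pipeline`: fits, AIC table,
#'   predictions, filter report, index and overlap series, correlations,
#'   and the resolved configuration.
#' @export
run_pipeline <- function(hauls, stomachs, grid, prey,
                         config = pipeline_config(),
                         biomass_spec = NULL, diet_specs = NULL) {
  t_start <- Sys.time()
  rect_mode <- "rect_id" %in% names(prey)
  validate_inputs(hauls = hauls, stomachs = stomachs, grid = grid,
                  rect_biomass = if (rect_mode) prey else NULL)
  log_stage <- function(...) message(sprintf("[%s] ", format(Sys.time(), "%H:%M:%S")), ...)

  hauls$quarter4 <- as.numeric(hauls$quarter == 4)
  hauls$depth2 <- 0  # replaced after standardization inside the frame; see below

  ## depth^2 as a time-varying covariate needs an explicit column on the
  ## standardized scale; build it from the standardized depth
  sd_d <- stats::sd(hauls$depth_m); mu_d <- mean(hauls$depth_m)
  hauls$depth2 <- ((hauls$depth_m - mu_d) / sd_d)^2

  if (config$exclude_empty_stomachs)
    stomachs <- stomachs[stomachs$relative_prey_mass > 0, , drop = FALSE]

  ## attach the prey covariate to stomach records if absent; the models
  ## use it on the log scale (positive densities required)
  if (!"prey_density" %in% names(stomachs))
    stop("stomachs need a `prey_density` column (local prey density)")
  if (!"log_prey_density" %in% names(stomachs)) {
    if (any(stomachs$prey_density <= 0))
      stop("prey_density must be positive to form the log-scale covariate")
    stomachs$log_prey_density <- log(stomachs$prey_density)
  }

  log_stage("building meshes")
  mesh_b <- build_mesh(hauls[, c("x_km", "y_km")], config$cutoff_biomass_km,
                       config$extension_km)
  mesh_d <- build_mesh(stomachs[, c("x_km", "y_km")], config$cutoff_diet_km,
                       config$extension_km)

  if (is.null(biomass_spec)) biomass_spec <- default_biomass_spec()
  if (is.null(diet_specs))
    diet_specs <- list(breakpoint = default_diet_spec("breakpoint"),
                       linear = default_diet_spec("linear"),
                       none = default_diet_spec("none"))

  log_stage("fitting biomass-density model")
  fit_b <- fit_spatdiet(biomass_spec, hauls, mesh_b)
  if (!fit_b$convergence$converged)
    warning("biomass model did not meet the convergence criteria")

  log_stage("fitting ", length(diet_specs), " candidate diet models")
  fits_d <- lapply(diet_specs, fit_spatdiet, data = stomachs, mesh = mesh_d)
  aics <- vapply(fits_d, marginal_aic, numeric(1))
  conv <- vapply(fits_d, function(f) f$convergence$converged, logical(1))
  aic_table <- data.frame(model = names(fits_d), aic = aics,
                          delta_aic = aics - min(aics[conv], aics),
                          converged = conv, row.names = NULL)
  aic_table <- aic_table[order(aic_table$delta_aic), ]
  best <- aic_table$model[which(aic_table$converged)[1]]
  if (is.na(best))
    stop("no candidate diet model met the convergence criteria; ",
         "indices are not computed from non-converged fits")
  fit_d <- fits_d[[best]]

  ## prediction rows: cell x year for the prediction quarter
  years <- fit_b$frame$year_levels
  pgrid <- grid[rep(seq_len(nrow(grid)), times = length(years)), ]
  pgrid$year <- rep(years, each = nrow(grid))
  pgrid$quarter <- config$overlap_quarter
  pgrid$quarter4 <- as.numeric(pgrid$quarter == 4)
  pgrid$depth2 <- ((pgrid$depth_m - mu_d) / sd_d)^2
  if (rect_mode) {
    prey_cells <- rectangle_prey_to_grid(prey, grid)
    pgrid$prey_density <- prey_cells$prey_density[
      match(paste(pgrid$cell_id, pgrid$year),
            paste(prey_cells$cell_id, prey_cells$year))]
  } else {
    prey_cells <- prey
    pgrid$prey_density <- prey$prey_density[match(pgrid$cell_id, prey$cell_id)]
  }
  pgrid$log_prey_density <- log(pgrid$prey_density)

  log_stage("predicting on the grid (", config$n_draws, " draws)")
  pred_d <- predict_grid(fit_d, pgrid, n_draws = config$n_draws,
                         seed = config$seed,
                         predator_length_cm = config$predator_length_cm)
  pred_b <- predict_grid(fit_b, pgrid, n_draws = config$n_draws,
                         seed = config$seed + 1)

  log_stage("filtering and computing indices")
  filtered <- apply_filters(pred_d, pred_b, cod_pct = config$cod_pct,
                            rpm_max = config$rpm_max,
                            depth_max_m = config$depth_max_m)
  indices <- predation_indices(filtered)
  overlap <- overlap_indices(filtered, prey_cells,
                             quarter = config$overlap_quarter)

  safe_cor <- function(a, b) {
    tryCatch(index_correlation(a, b), error = function(e) {
      warning("index correlation unavailable: ", conditionMessage(e))
      list(r = NA_real_, ci = c(NA_real_, NA_real_), n = length(a))
    })
  }
  cors <- list(
    overlap_vs_Pp = safe_cor(overlap$overlap$median, indices$Pp$median),
    overlap_vs_Pc = safe_cor(overlap$overlap$median, indices$Pc$median))

  out <- structure(list(
    fits = list(biomass = fit_b, diet = fits_d),
    best_diet_model = best, aic_table = aic_table,
    predictions = list(diet = pred_d, biomass = pred_b),
    filtered = filtered, indices = indices, overlap = overlap,
    correlations = cors, config = config,
    elapsed = as.numeric(difftime(Sys.time(), t_start, units = "secs"))
  ), class = "spatdiet_pipeline")

  if (!is.null(config$outdir)) write_pipeline_outputs(out, config$outdir)
  out
}

#' @export
print.spatdiet_pipeline <- function(x, ...) {
  cat("spatdiet pipeline run (", round(x$elapsed), "s )\n", sep = "")
  cat("best diet model:", x$best_diet_model, "\n")
  print(x$aic_table, digits = 4)
  cat("\nPer-capita predation (first years):\n")
  print(utils::head(x$indices$Pc, 4), digits = 3)
  cat("\nOverlap vs population predation: r =",
      round(x$correlations$overlap_vs_Pp$r, 3), " CI [",
      paste(round(x$correlations$overlap_vs_Pp$ci, 3), collapse = ", "),
      "]\n")
  invisible(x)
}

## write the artifact bundle as delimited text + JSON reports
write_pipeline_outputs <- function(res, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  wcsv <- function(df, name)
    utils::write.csv(df, file.path(outdir, name), row.names = FALSE)
  wcsv(res$aic_table, "aic_table.csv")
  wcsv(res$indices$Pp, "population_predation.csv")
  wcsv(res$indices$Pc, "per_capita_predation.csv")
  wcsv(res$overlap$overlap, "overlap.csv")
  cors <- do.call(rbind, lapply(names(res$correlations), function(nm) {
    cc <- res$correlations[[nm]]
    data.frame(pair = nm, r = cc$r, ci_lo = cc$ci[1], ci_hi = cc$ci[2],
               n = cc$n)
  }))
  wcsv(cors, "correlations.csv")
  jsonlite::write_json(res$filtered$report,
                       file.path(outdir, "filter_report.json"),
                       auto_unbox = TRUE, digits = NA)
  fit_report <- function(fit) list(
    response = fit$spec$response, family = fit$spec$family,
    loglik = fit$loglik, k = fit$k, aic = fit$aic,
    convergence = fit$convergence[c("max_gradient", "pd_hess", "converged")],
    parameters = tidy_fixed(fit))
  jsonlite::write_json(
    list(biomass = fit_report(res$fits$biomass),
         diet = lapply(res$fits$diet, fit_report)),
    file.path(outdir, "fit_reports.json"), auto_unbox = TRUE, digits = NA,
    dataframe = "rows")
  cfg <- res$config
  jsonlite::write_json(cfg[!vapply(cfg, is.null, TRUE)],
                       file.path(outdir, "resolved_config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(outdir)
}
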