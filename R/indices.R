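#' Filter grid predictions before index computation
#'
#' Applies the three screening rules used before predation indices are
#' summed: (i) grid cells deeper than `depth_max_m` are removed entirely;
#' (ii) predator-density entries above the `cod_pct` percentile, computed
#' jointly over all draws and cells that survive the depth filter, are
#' removed; (iii) relative-prey-mass entries greater than `rpm_max` are
#' removed.  Rules (ii) and (iii) act entry-wise (draw x row); a removed
#' entry drops out of both the numerator and denominator of the indices.
#'
#' @param rpm A `grid_prediction` of relative prey mass (kg/kg).
#' @param density A `grid_prediction` of predator biomass density
#'   (kg/km^2) on the same grid rows and number of draws.
#' @param cod_pct Percentile (0-100) for the density screen; default
#'   99.99.
#' @param rpm_max Relative-prey-mass ceiling; default 1 kg/kg.
#' @param depth_max_m Depth cutoff in metres; default 130.
#'
#' @return Object of class `filtered_prediction`: list with `grid`, `R`,
#'   `D` (matrices with removed entries set `NA`), and `report` (counts
#'   removed per rule and the density threshold).
#' @export
apply_filters <- function(rpm, density, cod_pct = 99.99, rpm_max = 1.0,
                          depth_max_m = 130) {
  stopifnot(inherits(rpm, "grid_prediction"),
            inherits(density, "grid_prediction"))
  if (!identical(dim(rpm$values), dim(density$values)))
    stop("rpm and density predictions are not aligned")
  grid <- density$grid
  if (!"depth_m" %in% names(grid)) stop("grid lacks a `depth_m` column")

  keep_cell <- grid$depth_m <= depth_max_m
  n_depth <- sum(!keep_cell)
  R <- rpm$values[keep_cell, , drop = FALSE]
  D <- density$values[keep_cell, , drop = FALSE]
  grid <- grid[keep_cell, , drop = FALSE]

  d_thresh <- stats::quantile(D, probs = cod_pct / 100, type = 7,
                              names = FALSE, na.rm = TRUE)
  d_bad <- !is.na(D) & D > d_thresh
  r_bad <- !is.na(R) & R > rpm_max
  D[d_bad] <- NA_real_
  R[r_bad] <- NA_real_

  structure(list(grid = grid, R = R, D = D,
                 report = list(cells_removed_depth = n_depth,
                               entries_removed_density = sum(d_bad),
                               entries_removed_rpm = sum(r_bad),
                               density_threshold = d_thresh,
                               depth_max_m = depth_max_m,
                               cod_pct = cod_pct, rpm_max = rpm_max)),
            class = "filtered_prediction")
}

#' Population-level predation for one draw
#'
#' `P_p = sum_j R_j * D_j * A_j` in kilograms: an instantaneous snapshot
#' of the total prey mass in predator stomachs over the domain.
#'
#' @param R Relative prey mass per cell (kg/kg).
#' @param D Predator biomass density per cell (kg/km^2).
#' @param A Cell areas (km^2).
#' @export
population_predation <- function(R, D, A) {
  if (length(R) != length(D) || length(D) != length(A))
    stop("R, D and A must have equal length")
  ok <- !is.na(R) & !is.na(D)
  sum(R[ok] * D[ok] * A[ok])
}

#' Per-capita predation for one draw
#'
#' `P_c = P_p / sum_j D_j * A_j` (kg prey per kg predator): the
#' density-weighted mean relative prey mass, insensitive to overall
#' predator abundance.
#'
#' @inheritParams population_predation
#' @export
per_capita_predation <- function(R, D, A) {
  if (length(R) != length(D) || length(D) != length(A))
    stop("R, D and A must have equal length")
  ok <- !is.na(R) & !is.na(D)
  denom <- sum(D[ok] * A[ok])
  if (denom <= 0) stop("total predator biomass is zero")
  sum(R[ok] * D[ok] * A[ok]) / denom
}

#' Local index of collocation
#'
#' Overlap between two non-negative density fields on a common grid:
#' each field is converted to proportions of its total and the index is
#' `sum(p q) / sqrt(sum(p^2) sum(q^2))`, which is 1 when the fields are
#' proportional (Cauchy-Schwarz equality) and 0 when their supports are
#' disjoint.  The unsummed per-cell products are attached as attribute
#' `"cellwise"` for mapping.
#'
#' @param pred,prey Non-negative vectors with positive totals.
#' @return Scalar in `[0, 1]` with attribute `cellwise`.
#' @export
collocation_overlap <- function(pred, prey) {
  if (length(pred) != length(prey)) stop("fields must have equal length")
  ok <- !is.na(pred) & !is.na(prey)
  pred <- pred[ok]; prey <- prey[ok]
  if (any(pred < 0) || any(prey < 0)) stop("densities must be non-negative")
  if (sum(pred) <= 0 || sum(prey) <= 0)
    stop("each field must have a positive total")
  p <- pred / sum(pred)
  q <- prey / sum(prey)
  denom <- sqrt(sum(p^2) * sum(q^2))
  out <- sum(p * q) / denom
  attr(out, "cellwise") <- p * q / denom
  out
}

#' Spread rectangle-level prey biomass onto grid cells
#'
#' Converts a rectangle-by-year biomass table to a per-cell density by
#' spreading each rectangle's biomass uniformly over its retained grid
#' cells (density = biomass / total cell area), conserving total biomass.
#' Cells whose rectangle is absent from the table are dropped with a
#' warning.
#'
#' @param rect_biomass Data frame with columns `rect_id`, `year`,
#'   `biomass_kg`.
#' @param grid Data frame of cells with `cell_id`, `rect_id`, `area_km2`.
#' @return Data frame `cell_id`, `year`, `prey_density` (kg/km^2).
#' @export
rectangle_prey_to_grid <- function(rect_biomass, grid) {
  need <- c("rect_id", "year", "biomass_kg")
  if (!all(need %in% names(rect_biomass)))
    stop("rect_biomass needs columns: ", paste(need, collapse = ", "))
  if (!all(c("cell_id", "rect_id", "area_km2") %in% names(grid)))
    stop("grid needs columns cell_id, rect_id, area_km2")
  grid <- unique(grid[, c("cell_id", "rect_id", "area_km2")])
  unmapped <- !grid$rect_id %in% rect_biomass$rect_id
  if (any(unmapped)) {
    warning(sum(unmapped), " grid cell(s) in rectangles absent from the ",
            "biomass table were excluded: ",
            paste(utils::head(grid$cell_id[unmapped], 5), collapse = ", "))
    grid <- grid[!unmapped, , drop = FALSE]
  }
  rect_area <- tapply(grid$area_km2, grid$rect_id, sum)
  out <- merge(grid, rect_biomass, by = "rect_id")
  out$prey_density <- as.vector(out$biomass_kg /
                                  rect_area[as.character(out$rect_id)])
  out[order(out$year, out$cell_id), c("cell_id", "year", "prey_density")]
}

#' Summarize per-draw annual index values
#'
#' @param x Matrix of index values, years in rows (rownames = year) and
#'   draws in columns.
#' @return Data frame `year`, `median`, `mean`, `cv`, `p10`, `p90`.
#'   Percentiles use linear interpolation between order statistics
#'   (`quantile` type 7).
#' @export
summarize_draws <- function(x) {
  x <- as.matrix(x)
  if (ncol(x) < 2) stop("need at least 2 draws")
  yr <- rownames(x)
  if (is.null(yr)) yr <- seq_len(nrow(x))
  qs <- t(apply(x, 1, stats::quantile, probs = c(0.1, 0.5, 0.9), type = 7,
                na.rm = TRUE, names = FALSE))
  mn <- rowMeans(x, na.rm = TRUE)
  sdv <- apply(x, 1, stats::sd, na.rm = TRUE)
  data.frame(year = as.numeric(yr), median = qs[, 2], mean = mn,
             cv = ifelse(mn == 0, NA_real_, sdv / mn),
             p10 = qs[, 1], p90 = qs[, 3], row.names = NULL)
}

#' Pearson correlation between two annual index series
#'
#' @param a,b Numeric vectors (paired years, length >= 4).
#' @param conf_level Confidence level for the Fisher-z interval.
#' @return List with `r`, `ci` (length 2), `n`.
#' @export
index_correlation <- function(a, b, conf_level = 0.95) {
  ok <- stats::complete.cases(a, b)
  a <- a[ok]; b <- b[ok]
  n <- length(a)
  if (n < 4) stop("need at least 4 paired years")
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("zero variance in one of the series")
  r <- stats::cor(a, b)
  z <- atanh(r)
  hw <- stats::qnorm(1 - (1 - conf_level) / 2) / sqrt(n - 3)
  list(r = r, ci = tanh(c(z - hw, z + hw)), n = n)
}

#' Annual predation indices from filtered grid predictions
#'
#' Computes, per draw and per year, population-level predation
#' (`P_p`, kg) and per-capita predation (`P_c`, kg/kg), then summarizes
#' draws into annual series.  Indices are computed draw-by-draw first and
#' only then summarized.
#'
#' @param filtered A `filtered_prediction` from [apply_filters()].
#' @return List with data frames `Pp` and `Pc` ([summarize_draws()]
#'   format) and matrices `Pp_draws`, `Pc_draws` (year x draw).
#' @export
predation_indices <- function(filtered) {
  stopifnot(inherits(filtered, "filtered_prediction"))
  grid <- filtered$grid
  years <- sort(unique(grid$year))
  nd <- ncol(filtered$R)
  Pp <- Pc <- matrix(NA_real_, length(years), nd,
                     dimnames = list(years, NULL))
  for (yi in seq_along(years)) {
    rows <- which(grid$year == years[yi])
    A <- grid$area_km2[rows]
    for (j in seq_len(nd)) {
      Pp[yi, j] <- population_predation(filtered$R[rows, j],
                                        filtered$D[rows, j], A)
      Pc[yi, j] <- per_capita_predation(filtered$R[rows, j],
                                        filtered$D[rows, j], A)
    }
  }
  list(Pp = summarize_draws(Pp), Pc = summarize_draws(Pc),
       Pp_draws = Pp, Pc_draws = Pc)
}

#' Annual predator-prey overlap from grid predictions
#'
#' Local index of collocation between predicted predator density and a
#' prey density field, per draw and year, then summarized.  Restrict the
#' predictions to fourth-quarter rows (the season of the prey survey)
#' before calling this, or pass `quarter` to have it done here.
#'
#' @param filtered A `filtered_prediction` (predator side in `$D`).
#' @param prey Data frame `cell_id`, `year`, `prey_density` (a static
#'   field may omit `year`; it is then recycled to every year).
#' @param quarter If not `NULL` and the grid has a `quarter` column, use
#'   only rows of that quarter (default 4).
#' @return List with `overlap` (summary data frame) and `overlap_draws`.
#' @export
overlap_indices <- function(filtered, prey, quarter = 4) {
  stopifnot(inherits(filtered, "filtered_prediction"))
  grid <- filtered$grid
  D <- filtered$D
  if (!is.null(quarter) && "quarter" %in% names(grid)) {
    keep <- grid$quarter == quarter
    grid <- grid[keep, , drop = FALSE]
    D <- D[keep, , drop = FALSE]
  }
  static_prey <- !"year" %in% names(prey)
  years <- sort(unique(grid$year))
  nd <- ncol(D)
  ov <- matrix(NA_real_, length(years), nd, dimnames = list(years, NULL))
  for (yi in seq_along(years)) {
    rows <- which(grid$year == years[yi])
    py <- if (static_prey) prey else prey[prey$year == years[yi], ]
    pd <- py$prey_density[match(grid$cell_id[rows], py$cell_id)]
    for (j in seq_len(nd)) {
      dv <- D[rows, j]
      ok <- !is.na(dv) & !is.na(pd)
      ov[yi, j] <- as.numeric(collocation_overlap(dv[ok], pd[ok]))
    }
  }
  list(overlap = summarize_draws(ov), overlap_draws = ov)
}
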