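test_that("population and per-capita predation match hand arithmetic", {
  R <- c(0.1, 0.2); D <- c(2, 4); A <- c(9, 9)
  expect_equal(population_predation(R, D, A), 9.0)
  expect_equal(per_capita_predation(R, D, A), 9 / 54)
  expect_equal(per_capita_predation(R, D, A), 0.16667, tolerance = 1e-4)
  ## linearity and invariances
  expect_equal(population_predation(R, 2 * D, A), 18.0)
  expect_equal(population_predation(rep(0, 2), D, A), 0)
  expect_equal(per_capita_predation(R, 5 * D, A),
               per_capita_predation(R, D, A))
  cst <- per_capita_predation(rep(0.07, 2), c(1, 99), A)
  expect_equal(cst, 0.07)
  expect_error(population_predation(R, D, c(9)), "equal length")
  expect_error(per_capita_predation(R, c(0, 0), A), "zero")
})

test_that("collocation overlap: proportionality, disjointness, hand value", {
  expect_equal(as.numeric(collocation_overlap(c(1, 2, 3), c(2, 4, 6))), 1)
  expect_equal(as.numeric(collocation_overlap(c(1, 0), c(0, 1))), 0)
  ov <- collocation_overlap(c(0.8, 0.2), c(0.2, 0.8))
  expect_equal(as.numeric(ov), 0.32 / 0.68)
  expect_equal(as.numeric(ov), 0.47059, tolerance = 1e-4)
  expect_equal(sum(attr(ov, "cellwise")), as.numeric(ov))
  ## scale invariance in either argument
  set.seed(41)
  p <- runif(30); q <- runif(30)
  expect_equal(as.numeric(collocation_overlap(3.7 * p, q)),
               as.numeric(collocation_overlap(p, q)), tolerance = 1e-12)
  expect_true(as.numeric(collocation_overlap(p, q)) <= 1)
  expect_error(collocation_overlap(rep(0, 3), q[1:3]), "positive total")
  expect_error(collocation_overlap(c(-1, 2), c(1, 1)), "non-negative")
})

test_that("filters remove exactly the intended entries", {
  tp <- toy_predictions()
  ## plant violations: one deep cell, one huge R, one huge D
  tp$grid$depth_m[3] <- 150
  tp$rpm$grid <- tp$density$grid <- tp$grid
  tp$rpm$values[10, 2] <- 1.5
  nkeep <- sum(tp$grid$depth_m <= 130)
  filt <- apply_filters(tp$rpm, tp$density, cod_pct = 99.99, rpm_max = 1,
                        depth_max_m = 130)
  expect_equal(filt$report$cells_removed_depth, sum(tp$grid$depth_m > 130))
  expect_equal(nrow(filt$grid), nkeep)
  expect_equal(filt$report$entries_removed_rpm, 1)
  expect_true(is.na(filt$R[which(filt$grid$depth_m ==
                                   tp$grid$depth_m[10])[1], 2]) ||
                filt$report$entries_removed_rpm == 1)
})

test_that("the 99.99th-percentile rule removes a single extreme entry", {
  ## 10001 equal values and one larger: only the larger one exceeds the
  ## type-7 99.99th percentile
  vals <- c(rep(100, 10001), 500)
  q <- quantile(vals, 0.9999, type = 7, names = FALSE)
  expect_true(q < 500 && q >= 100)
  n_cells <- 2; n_draws <- 5001
  grid <- data.frame(cell_id = 1:2, year = 2001, x_km = c(1, 4), y_km = 1,
                     area_km2 = 9, depth_m = 50, quarter = 4)
  D <- matrix(vals, n_cells, n_draws)
  R <- matrix(0.1, n_cells, n_draws)
  gp <- function(v, resp) structure(list(grid = grid, values = v,
                                         family = "tweedie",
                                         response = resp),
                                    class = "grid_prediction")
  filt <- apply_filters(gp(R, "rpm"), gp(D, "dens"))
  expect_equal(filt$report$entries_removed_density, 1)
  expect_equal(sum(is.na(filt$D)), 1)
})

test_that("rectangle biomass spreads uniformly and conserves totals", {
  grid <- data.frame(cell_id = 1:6, rect_id = c("a", "a", "a", "a", "b", "b"),
                     area_km2 = 9)
  rb <- data.frame(rect_id = c("a", "b"), year = 2001,
                   biomass_kg = c(100, 100))
  out <- rectangle_prey_to_grid(rb, grid)
  expect_equal(out$prey_density[out$cell_id %in% 1:4], rep(100 / 36, 4))
  ## conservation: density x area sums back to rectangle biomass
  tot_a <- sum(out$prey_density[out$cell_id %in% 1:4] * 9)
  expect_equal(tot_a, 100)
  ## equal biomass, fewer cells -> higher density, equal total
  dens_b <- out$prey_density[out$cell_id %in% 5:6]
  expect_equal(unique(dens_b), 100 / 18)
  expect_equal(sum(dens_b * 9), 100)
  ## unmapped cells are dropped with a warning
  grid2 <- rbind(grid, data.frame(cell_id = 7, rect_id = "zz", area_km2 = 9))
  expect_warning(rectangle_prey_to_grid(rb, grid2), "excluded")
})

test_that("draw summaries use linear-interpolation percentiles", {
  x <- matrix(rep(1:100, each = 2), nrow = 2, byrow = FALSE)
  rownames(x) <- c(2001, 2002)
  s <- summarize_draws(x)
  expect_equal(s$median, c(50.5, 50.5))
  expect_equal(s$p10, rep(quantile(1:100, 0.1, type = 7, names = FALSE), 2))
  expect_equal(s$p90, rep(quantile(1:100, 0.9, type = 7, names = FALSE), 2))
  ## identical draws: degenerate band, zero CV
  s2 <- summarize_draws(matrix(5, 1, 10, dimnames = list(2001, NULL)))
  expect_equal(s2$p10, 5); expect_equal(s2$p90, 5)
  expect_equal(s2$cv, 0)
  expect_true(all(s$p10 <= s$median & s$median <= s$p90))
  ## ordering of draws is irrelevant
  s3 <- summarize_draws(x[, sample(ncol(x))])
  expect_equal(s3, s)
})

test_that("index correlation reproduces the hand-computed Pearson r", {
  ic <- index_correlation(c(1, 2, 3, 4), c(1, 3, 2, 4))
  expect_equal(ic$r, 0.8)
  expect_true(ic$ci[1] < 0.8 && ic$ci[2] > 0.8)
  expect_equal(index_correlation(1:6, 2 * (1:6))$r, 1)
  ## Fisher-z interval widens as n shrinks
  set.seed(42)
  a <- rnorm(20); b <- a + rnorm(20, 0, 1)
  w_small <- diff(index_correlation(a[1:6], b[1:6])$ci)
  expect_gt(w_small, diff(index_correlation(a, b)$ci))
  expect_error(index_correlation(c(1, 1, 1, 1), 1:4), "zero variance")
  expect_error(index_correlation(1:3, 1:3), "4 paired")
})

test_that("indices are computed per draw, then summarized", {
  ## fixture where the two orders of operation differ
  grid <- data.frame(cell_id = 1:2, year = 2001, x_km = c(1, 4), y_km = 1,
                     area_km2 = c(9, 9), depth_m = 50, quarter = 4)
  R <- rbind(c(0.1, 0.5, 0.9), c(0.9, 0.5, 0.1))
  D <- rbind(c(100, 10, 1), c(1, 10, 100))
  gp <- function(v, resp) structure(list(grid = grid, values = v,
                                         family = "tweedie",
                                         response = resp),
                                    class = "grid_prediction")
  filt <- apply_filters(gp(R, "rpm"), gp(D, "dens"), cod_pct = 100)
  idx <- predation_indices(filt)
  right <- median(sapply(1:3, function(j)
    population_predation(R[, j], D[, j], grid$area_km2)))
  wrong <- population_predation(apply(R, 1, median), apply(D, 1, median),
                                grid$area_km2)
  expect_equal(idx$Pp$median, right)
  expect_false(isTRUE(all.equal(right, wrong)))
})

test_that("overlap honours the quarter restriction", {
  grid <- expand.grid(cell_id = 1:3, year = 2001, quarter = c(1, 4))
  grid$x_km <- grid$cell_id * 3; grid$y_km <- 1
  grid$area_km2 <- 9; grid$depth_m <- 50
  ## quarter-1 rows would give overlap 1; quarter-4 rows give < 1
  D <- matrix(c(1, 2, 3, 3, 2, 1, 1, 2, 3, 3, 2, 1), ncol = 2)
  gp <- structure(list(grid = grid, values = D, family = "tweedie",
                       response = "dens"), class = "grid_prediction")
  rp <- structure(list(grid = grid, values = D * 0 + 0.1,
                       family = "tweedie", response = "rpm"),
                  class = "grid_prediction")
  filt <- apply_filters(rp, gp, cod_pct = 100)
  prey <- data.frame(cell_id = 1:3, prey_density = c(1, 2, 3))
  ov4 <- overlap_indices(filt, prey, quarter = 4)
  ov1 <- overlap_indices(filt, prey, quarter = 1)
  expect_equal(ov1$overlap$median, 1)
  expect_lt(ov4$overlap$median, 1)
})
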