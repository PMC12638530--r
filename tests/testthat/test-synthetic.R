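test_that("domains are reproducible with the stated geometry", {
  d1 <- make_domain(nx = 12, ny = 10, cell_km = 3, seed = 77)
  d2 <- make_domain(nx = 12, ny = 10, cell_km = 3, seed = 77)
  expect_identical(d1, d2)
  expect_equal(nrow(d1), 120)
  expect_true(all(d1$area_km2 == 9))
  ## depth spans 10-150 m so the 130 m filter is exercised
  expect_true(any(d1$depth_m > 130))
  expect_true(all(d1$depth_m >= 10 & d1$depth_m <= 150.01))
  d3 <- make_domain(nx = 12, ny = 10, cell_km = 3, seed = 78)
  expect_false(identical(d1$depth_m, d3$depth_m))
})

test_that("prey fields respect their mode contracts", {
  tr <- scenario_truth(n_years = 5)
  dom <- make_domain(nx = 10, ny = 10, rect_cells = 5, seed = 3)
  ## static raster: non-negative, one value per cell
  st <- simulate_prey_fields(dom, tr, mode = "static_raster", seed = 4)
  expect_equal(nrow(st), nrow(dom))
  expect_true(all(st$prey_density > 0))
  ## rectangle series: within-rectangle density constant, totals conserved
  rs <- simulate_prey_fields(dom, tr, mode = "rectangle_series", seed = 4)
  expect_true(all(rs$biomass_kg > 0))
  expect_equal(nrow(rs), length(unique(dom$rect_id)) * 5)
  cells <- rectangle_prey_to_grid(rs[rs$year == tr$years[1], ], dom)
  per_rect <- tapply(cells$prey_density, dom$rect_id[match(cells$cell_id,
                                                           dom$cell_id)],
                     function(z) diff(range(z)))
  expect_true(all(per_rect < 1e-12))
  back <- sum(cells$prey_density * dom$area_km2[match(cells$cell_id,
                                                      dom$cell_id)])
  expect_equal(back, sum(rs$biomass_kg[rs$year == tr$years[1]]))
  expect_identical(simulate_prey_fields(dom, tr, seed = 9),
                   simulate_prey_fields(dom, tr, seed = 9))
})

test_that("survey zero proportion follows the Poisson-link identity", {
  ## no latent fields, no covariate effects: p = 1 - exp(-exp(intercept))
  tr <- scenario_truth(n_years = 4, n_hauls_per_year = 1500,
                       unbalanced = FALSE)
  tr$biomass[c("year_sd", "quarter4_1", "quarter4_2", "salinity",
               "temperature", "temperature2", "oxygen_b0",
               "depth_rw_sd", "depth2_rw_sd")] <- 0
  tr$biomass$depth_rw_start <- 0
  tr$biomass$depth2_rw_start <- 0
  tr$biomass[c("sigma_omega", "sigma_epsilon", "sigma_zeta")] <- 0
  dom <- make_domain(nx = 10, ny = 10, seed = 5)
  sv <- simulate_predator_survey(tr, dom, seed = 6)
  p_true <- 1 - exp(-exp(tr$biomass$intercept1))
  expect_equal(mean(sv$hauls$biomass_density > 0), p_true, tolerance = 0.03)
  ## and the mean equals the back-transformed intercepts
  expect_equal(mean(sv$hauls$biomass_density),
               exp(tr$biomass$intercept1 + tr$biomass$intercept2),
               tolerance = 0.05)
  expect_identical(simulate_predator_survey(tr, dom, seed = 6)$hauls,
                   sv$hauls)
})

test_that("diet is independent of prey when b0 = 0 and saturates when low b1", {
  dom <- make_domain(nx = 12, ny = 12, rect_cells = 6, seed = 7)
  tr0 <- scenario_truth(n_years = 5, b0 = 0, n_stomachs_per_year = 1000,
                        unbalanced = FALSE)
  tr0$prey$depth_loading <- 0  # prey independent of the diet's own depth term
  prey <- simulate_prey_fields(dom, tr0, seed = 8)
  st0 <- simulate_stomachs(tr0, dom, prey, seed = 9)
  expect_lt(abs(cor(st0$stomachs$relative_prey_mass,
                    st0$stomachs$prey_density)), 0.05)
  ## strong effect saturating at a low threshold: binned means flat above
  tr1 <- scenario_truth(n_years = 5, b0 = 1.2, b1 = -0.5,
                        n_stomachs_per_year = 1000, unbalanced = FALSE)
  tr1$diet$sigma_omega <- 0.1; tr1$diet$sigma_epsilon <- 0.1
  st1 <- simulate_stomachs(tr1, dom, prey, seed = 10)
  ps <- scale(st1$stomachs$log_prey_density)[, 1]
  above <- ps > 0
  high <- ps > 1
  m_above <- mean(st1$stomachs$relative_prey_mass[above & !high])
  m_high <- mean(st1$stomachs$relative_prey_mass[high])
  ## saturated: no further increase beyond the threshold
  expect_lt(abs(m_high - m_above) / m_above, 0.35)
  expect_identical(simulate_stomachs(tr1, dom, prey, seed = 10)$stomachs,
                   st1$stomachs)
})

test_that("missing-year scenarios drop stomach sampling in that year", {
  sc <- scenario_missing_year(seed = 2, n_years = 6,
                              n_hauls_per_year = 10,
                              n_stomachs_per_year = 20)
  miss <- sc$truth$years[sc$truth$missing_years]
  expect_false(miss %in% unique(sc$stomachs$year))
  expect_true(miss %in% unique(sc$hauls$year))  # survey still covers it
})

test_that("length-mass conversion supports annual condition factors", {
  expect_equal(length_mass(33, condition_factor = 0.01, exponent = 3),
               359.37)
  expect_equal(length_mass(20, 0.01, 3) * 8, length_mass(40, 0.01, 3))
  tab <- data.frame(year = 2001:2003, c = c(0.009, 0.010, 0.011))
  m <- length_mass(c(30, 30, 30), exponent = 3,
                   year = c(2003, 2001, 2002), condition_table = tab)
  expect_equal(m, c(0.011, 0.009, 0.010) * 27000)
  expect_error(length_mass(30, exponent = 3, year = 1999,
                           condition_table = tab), "missing")
})

test_that("scenario truth serializes to structured text and back", {
  tr <- scenario_truth(n_years = 7, b0 = 0.3)
  path <- file.path(tempdir(), "truth.json")
  write_scenario_truth(tr, path)
  tr2 <- read_scenario_truth(path)
  expect_equal(tr2$diet$b0, 0.3)
  expect_equal(tr2$years, tr$years)
  expect_equal(tr2$biomass$oxygen_b0, tr$biomass$oxygen_b0)
})

test_that("the misspecified-family scenario produces delta-gamma diet data", {
  sc <- scenario_misspecified_family(seed = 4, n_years = 4,
                                     n_hauls_per_year = 10,
                                     n_stomachs_per_year = 50)
  expect_equal(sc$truth$diet$family, "poisson_link_delta_gamma")
  rpm <- sc$stomachs$relative_prey_mass
  expect_gt(mean(rpm == 0), 0.2)   # genuine zero inflation
  expect_gt(sum(rpm > 0), 10)      # and a continuous positive part
  expect_true(all(rpm >= 0))
  ## relative prey mass is prey mass over predator mass by construction
  expect_equal(sc$stomachs$prey_mass_g / sc$stomachs$predator_mass_g,
               rpm, tolerance = 1e-12)
})
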