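# Shared fixtures, built once per test run and cached.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(name, expr) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, force(expr), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

## small Tweedie dataset with a spatial field plus its fitted model
small_tweedie_fit <- function() {
  memo("small_tweedie_fit", {
    set.seed(401)
    n <- 500
    d <- data.frame(x_km = runif(n, 0, 70), y_km = runif(n, 0, 70),
                    year = sample(2001:2006, n, TRUE),
                    depth = runif(n, 10, 120))
    mp <- matern_params(28, 0.5)
    S <- dense_matern_covariance(d[, c("x_km", "y_km")], mp)
    om <- drop(t(chol(S + diag(1e-8, n))) %*% rnorm(n))
    ds <- (d$depth - mean(d$depth)) / sd(d$depth)
    d$rpm <- rtweedie(n, exp(0.3 - 0.4 * ds + om), 1.6, 1.0)
    spec <- model_spec("rpm", "tweedie", fixed = ~ depth,
                       spatial_field = TRUE, spatiotemporal_field = FALSE)
    mesh <- build_mesh(d[, c("x_km", "y_km")], cutoff_km = 9,
                       extension_km = 40)
    list(data = d, spec = spec, mesh = mesh,
         truth = list(intercept = 0.3, depth = -0.4, power = 1.6,
                      phi = 1.0, range = 28, sigma = 0.5),
         fit = fit_spatdiet(spec, d, mesh))
  })
}

## deterministic mini grid-prediction pair for index plumbing tests
toy_predictions <- function(n_cells = 6, n_years = 3, n_draws = 8,
                            seed = 99) {
  set.seed(seed)
  grid <- expand.grid(cell_id = seq_len(n_cells), year = seq_len(n_years))
  grid$x_km <- rep(seq_len(n_cells) * 3 - 1.5, n_years)
  grid$y_km <- 1.5
  grid$area_km2 <- 9
  grid$depth_m <- rep(c(40, 60, 80, 100, 120, 125), length.out = nrow(grid))
  grid$quarter <- 4
  R <- matrix(runif(nrow(grid) * n_draws, 0, 0.3), nrow(grid), n_draws)
  D <- matrix(runif(nrow(grid) * n_draws, 10, 400), nrow(grid), n_draws)
  list(grid = grid,
       rpm = structure(list(grid = grid, values = R, family = "tweedie",
                            response = "rpm"), class = "grid_prediction"),
       density = structure(list(grid = grid, values = D,
                                family = "poisson_link_delta_gamma",
                                response = "biomass_density"),
                           class = "grid_prediction"))
}
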