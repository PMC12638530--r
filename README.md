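# spatdiet

Spatiotemporal diet and predation-index models for marine predator–prey
systems.

Fisheries surveys measure predator biomass density (kg/km²) at trawl
stations; stomach-content programs measure *relative prey mass* — kg of a
prey species per kg of predator — in individual stomachs. `spatdiet`
models both data streams with geostatistical GLMMs and combines their
grid-level predictions into annual, uncertainty-quantified indices of

* **population-level predation** `P_p,i = Σ_j R_ij · D_ij · A_j` (kg of
  prey in predator stomachs, an instantaneous snapshot),
* **per-capita predation** `P_c,i = P_p,i / Σ_j D_ij · A_j` (kg/kg,
  insensitive to predator abundance), and
* **predator–prey spatial overlap** (local index of collocation,
  `Σ p_j q_j / √(Σ p_j² Σ q_j²)` on biomass proportions),

where `R` is predicted relative prey mass, `D` predicted predator
density, and `A_j` the grid-cell area.

## The models

Both responses share one GLMM skeleton

```
mu_st = f⁻¹( X·beta + alpha_month + X_tvc·gamma_t + X_svc·zeta_s + omega_s + eps_st )
```

with Matérn (ν = 1) Gaussian Markov random fields via the SPDE
finite-element construction (`Q = τ²(κ⁴C + 2κ²G + GC⁻¹G)`,
`κ = √8/range`), AR(1) or random-walk time-varying coefficients,
month random intercepts, spatially varying coefficients, and
hockey-stick (breakpoint) covariate effects `b0·min(x, b1)` — a
saturating functional response when applied to local prey density.
Observation families: Tweedie, or a Poisson-link delta–gamma with
encounter probability `p = 1 − exp(−exp(η1))` and unconditional mean
`exp(η1 + η2)`. Fitting is maximum marginal likelihood with the Laplace
approximation (TMB, sparse Cholesky); convergence requires a positive
definite Hessian and a max absolute gradient < 0.001, with a dedicated
subgradient check for breakpoint thresholds whose optimum sits on a
covariate kink. Uncertainty is propagated by (default 500) draws from
the joint parameter precision; every index is computed per draw, then
summarized (median, mean, CV, 10th–90th percentiles).

A synthetic-data module (`make_domain()`, `scenario_truth()`,
`simulate_predator_survey()`, `simulate_stomachs()`,
`simulate_prey_fields()`) generates survey hauls, stomach records, prey
rasters/rectangle series and prediction grids with exactly the
statistical structure the models assume, plus a serialized ground-truth
record — the basis of the package's recovery and end-to-end tests.

## Worked example

Simulate a small strong-coupling scenario (diet saturating in local prey
density) and run the full pipeline — fit the biomass and candidate diet
models, compare them by marginal AIC, predict on the grid, filter,
and compute indices:

```r
library(spatdiet)

sc <- scenario_strong_coupling(seed = 12, n_years = 6,
                               n_hauls_per_year = 25,
                               n_stomachs_per_year = 60)

bspec <- model_spec("biomass_density", "poisson_link_delta_gamma",
                    fixed = ~ factor(year) + quarter4,
                    spatial_field = TRUE, spatiotemporal_field = FALSE,
                    fixed2 = ~ 1, spatial_field2 = FALSE,
                    spatiotemporal_field2 = FALSE)
dspecs <- list(
  breakpoint = model_spec("relative_prey_mass", "tweedie",
                          fixed = ~ predator_length_cm,
                          breakpoint = "log_prey_density",
                          time_varying = list(intercept = "ar1"),
                          spatial_field = FALSE, spatiotemporal_field = FALSE),
  none = model_spec("relative_prey_mass", "tweedie",
                    fixed = ~ predator_length_cm,
                    time_varying = list(intercept = "ar1"),
                    spatial_field = FALSE, spatiotemporal_field = FALSE))

res <- run_pipeline(sc$hauls, sc$stomachs, sc$domain, sc$prey,
                    config = pipeline_config(n_draws = 25, seed = 5,
                                             cutoff_diet_km = 12,
                                             cutoff_biomass_km = 12,
                                             extension_km = 35),
                    biomass_spec = bspec, diet_specs = dspecs)
print(res)
```

```
spatdiet pipeline run (4s)
best diet model: breakpoint
       model    aic delta_aic converged
1 breakpoint -32.67      0.00      TRUE
2       none -10.43     22.24     FALSE

Per-capita predation (first years):
  year median   mean    cv    p10    p90
1 2001 0.0226 0.0231 0.152 0.0188 0.0278
2 2002 0.0227 0.0231 0.153 0.0188 0.0279
3 2003 0.0227 0.0230 0.151 0.0188 0.0277
4 2004 0.0227 0.0231 0.152 0.0188 0.0277

Overlap vs population predation: r = 0.035  CI [ -0.799, 0.823 ]
```

Reading the output: the saturating-prey diet model beats the no-prey
model by ΔAIC ≈ 22, correctly recovering the simulated coupling (the
no-prey model additionally fails the convergence diagnostics at this
toy size — its annual-intercept variance collapses — and the table says
so rather than hiding it). The per-capita predation index says a median
of roughly 0.023 kg of prey per kg of predator is in stomachs at any
instant, with the 10th–90th percentile band reflecting joint parameter
uncertainty from 25 draws. At this toy size (6 years, 25 draws) the
overlap–predation correlation is essentially uninformative — its CI
spans zero — which is exactly what the interval is for; the shipped
tests demonstrate the CI excluding zero at the reference scenario
scale.

Lower-level entry points: `fit_spatdiet()` for a single model,
`predict_grid()` + `apply_filters()` + `predation_indices()` /
`overlap_indices()` for the index chain, `sample_joint_precision()` for
draws, `randomized_quantile_residuals()` for diagnostics. The methods
vignette (`vignettes/predation-indices.Rmd`) documents the model, every
tunable default (mesh cutoffs 8/10 km, 500 draws, the 99.99%/1 kg·kg⁻¹/
130 m filters, 33 cm prediction length, quarter-4 overlap), and the
numerical choices.

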