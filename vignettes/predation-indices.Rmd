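---
title: "Spatiotemporal diet models and predation indices: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spatiotemporal diet models and predation indices: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Stomach-content samples tell us what an individual predator ate at one
place and time; survey hauls tell us how much predator biomass is where.
Neither alone says how much predation pressure a prey population
experiences, or whether that pressure tracks how strongly predator and
prey overlap in space. `spatdiet` bridges the two data streams with a
pair of geostatistical mixed models — one for stomach-content *relative
prey mass* (kg of a prey species per kg of predator) and one for
predator biomass density (kg/km²) — and combines their grid-level
predictions into annual indices of predation and spatial overlap with
full uncertainty propagation.

## The model

Both responses are modelled on a common spatiotemporal GLMM skeleton.
For observation at location $s$ and time $t$,

$$\mu_{s,t} = f^{-1}\!\left(X^{\mathrm{main}}_{s,t}\beta + \alpha_{m(s,t)}
  + X^{\mathrm{tvc}}_{s,t}\gamma_{g,t} + X^{\mathrm{svc}}_{s,t}\zeta_{k,s}
  + \omega_s + \epsilon_{s,t}\right),$$

where

* $X^{\mathrm{main}}\beta$ are ordinary fixed effects (standardized
  continuous covariates, year/quarter factors), possibly including
  *breakpoint* (hockey-stick) terms of the form $b_0\min(x, b_1)$ — a
  linear effect that saturates at threshold $b_1$, i.e. a type-I
  functional response with saturation when applied to prey density.
  The prey covariate enters on the log scale: biomass densities span
  orders of magnitude, and after standardizing the raw scale the
  sub-threshold part of a hockey stick would collapse into the narrow
  band left of the long right tail, with almost no usable contrast;
* $\alpha_m$ is an iid normal random intercept for calendar month;
* $\gamma_{g,t}$ are time-varying coefficients following either a
  stationary AR(1) — $\gamma_1 \sim N(0, \sigma_\gamma^2)$,
  $\gamma_t \sim N(\rho\gamma_{t-1}, (1-\rho^2)\sigma_\gamma^2)$ — or a
  random walk, $\gamma_t \sim N(\gamma_{t-1}, \sigma_\gamma^2)$. The
  AR(1) intercept lets the diet model interpolate a year with no stomach
  sampling from its neighbours; the random-walk depth and depth² terms
  let the predator's depth preference drift over decades;
* $\zeta_{k,s}$ are spatially varying coefficient fields (a quarter
  offset field in the biomass model);
* $\omega_s$ is a spatial field constant over time and
  $\epsilon_{s,t}$ are spatial fields drawn independently each year.

All fields are Gaussian Markov random fields with Matérn (smoothness
$\nu = 1$) covariance, discretized with the SPDE finite-element
construction on a triangulated mesh: the precision of the node values is
$Q = \tau^2(\kappa^4 C + 2\kappa^2 G + G C^{-1} G)$ with lumped mass
matrix $C$ and stiffness matrix $G$. We fix $\nu = 1$ (the standard
SPDE $\alpha = 2$ case) and define the *range* as the distance at which
correlation falls to $\sqrt{8}K_1(\sqrt 8) \approx 0.14$, so
$\kappa = \sqrt 8 / \mathrm{range}$, and
$\tau = 1/(\sqrt{4\pi}\,\kappa\,\sigma)$ fixes the marginal SD at
$\sigma$. Within one linear predictor all fields share $\kappa$ but
have separate $\tau$ (hence separate SDs).

Two observation families cover the zero-inflated continuous responses:

* **Tweedie**: compound Poisson–gamma with mean $\mu = e^\eta$, power
  $p \in (1,2)$ and dispersion $\phi$ (variance $\phi\mu^p$);
* **Poisson-link delta–gamma**: two log-linked linear predictors, group
  density $n = e^{\eta_1}$ and mass-per-group $w = e^{\eta_2}$, with
  encounter probability $p = 1 - e^{-n}$, positive-part gamma mean
  $r = nw/p$, and unconditional mean $pr = e^{\eta_1 + \eta_2}$
  exactly. For zero observations the log-likelihood contribution is
  $\log(1-p) = -n$.

A Gaussian family is included for verification: the Laplace
approximation is exact there, which gives a closed-form oracle.

## Fitting

The marginal likelihood integrates all latent vectors (fields,
time-varying coefficients, month intercepts) out by the Laplace
approximation, implemented with automatic differentiation and sparse
Cholesky factorization (TMB). The outer problem maximizes over fixed
effects and hyperparameters on transformed scales: log SDs and
dispersions, $\mathrm{logit}$-scaled Tweedie power on $(1,2)$, and AR(1)
correlation mapped through $2\,\mathrm{logit}^{-1}(x) - 1$.

Convergence is declared only when the Hessian is positive definite and
the maximum absolute marginal log-likelihood gradient over fixed and
hyperparameters is below $10^{-3}$ — with one important refinement. The
hockey-stick term makes the likelihood piecewise smooth in the
threshold $b_1$: its optimum frequently lies exactly at a covariate
value (a kink), where the one-sided gradient does not vanish no matter
how good the optimizer is. We observed gradients of order 0.4 at points
where every perturbation of $b_1$ by $10^{-3}$–$10^{-2}$ *increased*
the objective. `fit_spatdiet()` therefore (i) line-searches each
threshold across the covariate kinks near its current value, (ii)
re-converges all remaining (smooth) parameters with the thresholds held
fixed, and (iii) accepts the solution when the smooth-parameter gradient
criterion holds and the thresholds pass a local profile (subgradient)
optimality check. Both the raw and the smooth-parameter gradient, and
the kink flag, are recorded in the fit's convergence block. Failing
fits trigger deterministic jittered restarts and are flagged, never
silently accepted.

Model comparison uses marginal AIC, $2k - 2\log L$, with $k$ counting
fixed effects plus hyperparameters (latent modes are integrated out and
not counted). Diagnostics use simulation-based randomized quantile
residuals in which replicate data are simulated conditional on a single
draw of the random effects from their estimated joint distribution —
not the empirical-Bayes modes — acknowledging that the random effects
are themselves estimates.

## Prediction and uncertainty

Predictions are made on a regular grid (3 × 3 km cells in the reference
configuration) for every year, at a fixed predator length of 33 cm (the
mean in the diet data the models emulate) and with the month intercept
set to zero. Uncertainty is propagated by drawing (500 by default)
joint samples of all fixed effects, hyperparameters and latent modes
from the inverse of the joint precision matrix at the mode; every index
below is computed per draw and only then summarized by the median,
mean, CV and the 10th/90th percentiles (linear interpolation between
order statistics, `quantile` type 7 — the documented tie-break since no
convention is otherwise fixed). The spatiotemporal field of a year with
no diet samples has no data contribution, so its draws come from the
process distribution conditioned through the AR(1) intercept — exactly
the mechanism that interpolates the missing year.

## Indices

Before any index is summed, three screens are applied: grid cells
deeper than 130 m are dropped (trawl surveys do not sample there);
predator-density entries above the 99.99th percentile across all draws
and cells are dropped; relative-prey-mass entries above 1 kg/kg are
dropped. The screens act entry-wise per draw and are reported.

With $R_{i,j}$ the predicted relative prey mass and $D_{i,j}$ the
predicted predator density in cell $j$ and year $i$, and $A_j$ the cell
area,

$$P_{p,i} = \sum_j R_{i,j} D_{i,j} A_j \qquad
  P_{c,i} = \frac{\sum_j R_{i,j} D_{i,j} A_j}{\sum_j D_{i,j} A_j},$$

population-level predation (an instantaneous snapshot of prey mass in
predator stomachs, kg) and per-capita predation (kg prey per kg
predator, insensitive to overall predator abundance). Overlap uses the
local index of collocation on proportions $p_j, q_j$ of predator and
prey biomass: $\sum_j p_j q_j / \sqrt{\sum_j p_j^2 \sum_j q_j^2}$,
which is 1 for proportional fields and 0 for disjoint ones. Overlap
(and the index predictions) use fourth-quarter predictions, the season
of the acoustic prey survey. Rectangle-level prey biomass is spread
uniformly over the rectangle's retained grid cells (biomass conserved);
that uniform spreading is an explicit assumption, as is re-using a
single static raster across years for benthic prey (overlap changes are
then driven solely by the predator field). Annual index series are
correlated (Pearson, Fisher-z 95% CI) to ask whether predation tracks
overlap.

## The synthetic-data generator

`make_domain()` builds a 30 × 30 grid of 3 × 3 km cells with smooth
Matérn-field bathymetry rescaled to 10–150 m (so the 130 m screen always
binds), correlated temperature/salinity/oxygen fields, and 10 × 10-cell
reporting rectangles. `scenario_truth()` fixes the reference study
conditions: 15 survey years, quarters 1 and 4, 60 hauls and 300
stomachs per year, unbalanced spatial coverage (years alternate between
full coverage and opposite two-thirds windows, mimicking uneven
historical sampling), Matérn range 30 km (safely above the 8–10 km mesh
cutoffs), diet intercept −4.2 on the log scale (mean relative prey mass
near 0.02 kg/kg, roughly 70% empty stomachs), AR(1) intercept with
$\rho = 0.7$, $\sigma = 0.1$, and a saturating effect of standardized
log prey density. The biomass truth uses the full first linear
predictor of the reference model (year and quarter factors, salinity,
temperature and temperature², an oxygen breakpoint, random-walk depth
and depth² effects, a quarter SVC field, $\omega$ and $\epsilon$) and a
lean second predictor (intercept and quarter only, no fields):
per-component term placement is not otherwise pinned down, and the lean
second component keeps desk-scale fits within minutes. Field values are
simulated as GMRFs on a simulation mesh and projected; tests of the
SPDE construction use an independent dense-covariance route. Generator
covariates are standardized by domain-wide constants stored in the
truth record, so fitted (sample-standardized) coefficients are
comparable to truth up to $O(n^{-1/2})$ scale error.

The *coupling design* of the reference scenario deserves its own note,
because it was the genuinely open part of the generator. Coupling has
two stated ingredients: the diet tracks local prey density (a steep
breakpoint effect, $b_0 = 1$, saturating at $b_1 = 0.8$ on the
standardized log-prey scale), and the predator and prey distributions
co-vary. The second ingredient is *depth-mediated*: the static benthic
prey map loads on bathymetry (log prey = $-0.7 \tilde d$ plus a smooth
field, $\tilde d$ standardized depth), and the predator's random-walk
depth preference (innovation SD 0.2 on the first-order term) drifts
across years — the stock moves on and off the prey beds as its depth
distribution shifts. A mild constant aggregation on prey (slope 0.3)
rides along. This channel was chosen over free-form alternatives for an
estimation-theoretic reason: a yearly distribution shift expressed
through a covariate the model tracks with a time-varying coefficient is
*recoverable* from ~60 hauls per year, whereas the same shift written
into the yearly `epsilon` fields is almost entirely smoothed away by
the posterior (free fields need far more data per year), leaving
predicted overlap nearly constant no matter how strong the true
coupling.

Four further structural facts shaped the scenario, all verified on
truth-level simulations. First, collocation overlap is a *cosine
similarity*: it responds non-monotonically to aggregation (a predator
that out-concentrates the prey map makes overlap fall again), so shifts
must stay in the rising regime. Second, with a *dynamic* prey field the
per-year realized prey variance raises predation totals (Jensen's
inequality on the log scale) while lowering the cosine — an
anti-channel that erodes any overlap–predation correlation; a static
prey field removes it, which is also why the analogous empirical
correlation is clearest for sedentary benthic prey. Third, a
distribution shift must not manufacture stock biomass: the exponential
link makes yearly totals grow with any concentration of the field
(convexity), which anti-correlates $P_p$ with overlap; the generator
therefore normalizes each year's density surface so totals follow the
year effects alone — a per-year constant that fitted year factors
absorb exactly. Fourth, independent annual noise (diet AR(1)
intercept, biomass year effects, $\epsilon$ fields) dilutes the
correlation linearly, so their SDs are kept moderate (0.1, 0.1,
0.15–0.3). Under these conditions the truth-level overlap–$P_p$
correlation across independent domain seeds spans roughly 0.4–0.85.

Four canned scenarios ship with the package: strong coupling
($b_0 = 1$ with attraction), no coupling ($b_0 = 0$, no attraction,
independent distributions), a missing stomach-sampling year (AR(1)
interpolation), and a misspecified-family scenario (delta-gamma truth
to be mis-fit with Tweedie; residual checks must flag it). The
rectangle-series prey mode (pelagic-type, log-normal annual
innovations over a fixed gradient) remains available and tested; it is
simply not the reference coupling scenario.

What the generator does *not* emulate: real bathymetry or coastline
geometry, gear standardization and catchability, true ICES rectangle
geodesy, prey stock dynamics, regurgitation or digestion-state biases.
Passing recovery tests on these scenarios therefore demonstrates the
estimator's correctness under the model's own assumptions, not
robustness to the full messiness of survey data.

## Problem sizes used in the tests

The shipped checks run at sizes chosen to finish in minutes on one CPU:
parameter recovery fits the strong-coupling scenario at its default
sampling effort (900 hauls, 4,500 stomachs over 15 years); Wald
coverage pools the intercept and slope over 25 replicates of an
800-observation spatial Tweedie model simulated at a fixed set of
stations (one mesh and one covariance factor serve all replicates);
AIC model selection uses 20 strong-effect and 12 null replicates of
900 stomachs each — the
strong-effect arm uses a steep response ($b_0 = 1.2$) saturating at the
covariate median over a continuous raster prey field, because a weak or
late-saturating effect makes the breakpoint and nested linear forms
genuinely indistinguishable and AIC then correctly prefers parsimony;
the end-to-end coupling check uses 100 draws, and its no-coupling arm
three replicates of an 8-year scenario with 40 draws; the SPDE/dense
oracle comparison uses a ~430-node mesh with cutoff 1/16 of the range
and a two-range extension. The same computations at larger sizes only
tighten the Monte-Carlo noise.

## Numerical choices and degenerate inputs

* Mass lumping (diagonal $C$) keeps $Q$ sparse; the dense-oracle test
  bounds the induced correlation error at 5% on a fine mesh.
* The mesh extension uses graded concentric rings whose spacing grows
  geometrically from 1.5 × cutoff: an abrupt jump in triangle size at
  the data hull measurably distorts interior correlations (up to ~20%
  with a naive two-ring extension in our refinement study).
  A mild deterministic radial modulation avoids cocircular Delaunay
  degeneracies.
* Greedy cutoff thinning is performed in input order (deterministic);
  a cutoff exceeding the domain diameter is an error, as are zero-area
  triangles (reported with the triangle index).
* Breakpoint thresholds start at 0 — the approximate median of a
  standardized covariate — and are line-searched across kinks during
  refinement because the likelihood can be multimodal in $b_1$.
* Constant covariates cannot be standardized and are rejected;
  prediction-time standardization always reuses the stored centers and
  scales, never the grid's own statistics.
* The outer optimizer is box-bounded: the Matérn range cannot drop
  below the mesh cutoff (nothing below the mesh resolution is
  estimable) or exceed twenty domain diameters, and log-scale
  parameters stay within generous decades. Gradient-based convergence
  is assessed one-sidedly at an active bound. Without these rails we
  observed occasional runs onto degenerate ridges (range → 0 with
  exploding field SDs). A variance component that collapses to its
  boundary can leave a numerically flat row in the joint Hessian; the
  uncertainty-propagation draws then apply an escalating relative ridge
  (10⁻⁸–10⁻⁴) with a warning.
* `quantile` type 7 everywhere a percentile is taken (draw summaries
  and the 99.99% density screen).

## Known limitations

* One shared Matérn range per linear predictor (no anisotropy, no
  barrier effects, no smoothness estimation).
* The Matérn range itself is weakly identified at the reference scale:
  a single constant-in-time field realization on a 90 km domain with a
  30 km range carries few effective degrees of freedom, and replicate
  fits show single-realization range errors well beyond ±30% (with the
  usual drift along the range–SD ridge) even when the field SDs are
  recovered accurately. Range point estimates should be read with their
  (wide) intervals, not as precise quantities.
* The delta-family second predictor mirrors the first by default;
  sparse positive observations can leave its variance components
  collapsing to zero, which the convergence diagnostics surface as
  near-boundary hyperparameters.
* Index filters follow fixed reference thresholds; they are
  configurable but no sensitivity machinery beyond the empty-stomach
  switch is provided.
* The overlap metric is the local index of collocation only; other
  overlap measures from the literature are out of scope.
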