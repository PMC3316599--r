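---
title: "Territorial central-place foragers: model, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Territorial central-place foragers: model, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6,
                      fig.height = 4)
library(terriforage)
```

## The model

Many terrestrial mammals maintain territories through scent marks rather
than by patrolling: a mark deposited at a site is avoided by conspecifics
for a finite *active scent time* `T_AS`, after which it is ignored even if
it is still chemically detectable. `terriforage` implements a lattice
agent-based model of this process for *central-place foragers* — animals
whose movement is random but biased towards a fixed den or nest site (the
central place, CP).

Each animal is a nearest-neighbour random walker on a ring (1D) or a
rectangular torus (2D). At every attempted move it

1. draws a target site from a biased kernel: in 1D it steps towards its CP
   with probability `p` and away with probability `1 - p`; in 2D the four
   move probabilities are `1/4 + ((2p - 1)/4) * (u . e)`, where `u` is the
   unit vector from the animal to its CP and `e` the move direction, so the
   drift always points at the CP with a speed independent of the distance
   to it;
2. moves only if the target carries no *foreign* active scent (age below
   `T_AS`); a blocked attempt leaves the animal in place;
3. marks the site it ends up on.

Updates are random-sequential sweeps (a fresh permutation of the animals
per sweep), and time advances by `1/(n_animals * F)` per attempt, `F` being
the jump rate. A blocked move costing time, and a single `(owner,
timestamp)` scent record per site with lazy expiry, are the simplest rules
consistent with the exclusion mechanism; occupancy itself keeps a site's
scent fresh, so two animals can never meet on a site. Animals are
counter-markers: encountering foreign scent does not change their marking
rate. Animals start on their CPs with an empty scent field (initial
conditions are not otherwise constrained by the model).

Because foreign scent expires, territories are not static: their borders
ebb and flow. Without central-place bias the border wanders; the bias
anchors every animal, the border's mean square displacement (MSD)
saturates, and a *stable home range* emerges. The saturation MSD of the
dimensionless border position, as a surface over the drift strength and
the scent lifetime, is the quantitative bridge between microscopic
behaviour and observable space use, and inverting it is what lets the
package estimate `T_AS` from relocation data.

## Dimensionless conventions

All results are organised by two dimensionless numbers (recorded in every
run manifest):

* `beta = v L / D`, the normalised drift. `D` is the walker's diffusion
  constant: `F a^2 / 2` in 1D and `F a^2 / 4` in 2D (on a square lattice a
  jump goes to one of four neighbours, so each axis receives half the
  jumps; this quarter, not half, is what makes the simulated walker agree
  with the continuum drift-diffusion model — we verified it against the
  free-walker MSD). The drift speed is `v = F a (2p - 1)` in 1D and
  `F a (2p - 1) / 2` in 2D, so `beta = 2 (2p - 1) L / a` in both, and `L`
  is the distance between neighbouring CPs.
* `Z = T_AS / K`, the scent lifetime over the diffusive time
  (`K1 = 1/(2 D rho^2)` in 1D, `K2 = 1/(4 D rho)` in 2D, `rho` the animal
  density). `K` is a traversal time; covering a territory takes
  substantially longer, which is why confinement phenomena appear at
  `Z` of order 1 in 1D but only for `Z` of roughly 10 and above in 2D
  (see "Phenomenology" below).

The analytic models use CP-centred coordinates with all lengths divided by
`L`: the focal CP at 0 and the neighbouring CPs at -1 and +1 (1D), or a
disc territory of dimensionless mean radius 1/2 (2D).

## The reduced adiabatic model

Borders move much more slowly than animals, so the joint distribution of
animal and borders factorises into a border distribution times the
animal's conditional distribution inside fixed borders (the adiabatic
approximation).

**Borders.** Each border (1D) or the territory radius (2D) relaxes in a
quadratic potential centred on the inter-CP midpoint (radius 1/2), with a
generalised diffusion constant `K_b` and restoring rate `lambda`. At
steady state these collapse into one spread parameter,
`eps^2 = K_b / lambda`: the border density is a Gaussian
`exp(-x^2 / eps^2)` about the midpoint, reflected at the CPs by the method
of images (`border_pdf()`, `radius_pdf()`). The reflected families tile
the line, so the normaliser is exactly `1/(sqrt(pi) eps)`. For transient
work `border_pdf_transient()` evaluates the relaxing solution in two
algebraically equivalent forms — the image series and its
Poisson-summation (cosine) resummation — which agree to machine precision;
the time dependence uses the Ornstein-Uhlenbeck variance
`s^2(t) = (eps^2/2)(1 - exp(-4 lambda t))`, i.e. an effective constant
border diffusion coefficient. The adiabatic steady state, which is all the
inference uses, does not depend on that choice.

**Animal inside fixed borders.** The continuum limit of the biased walk is
the classic localising-tendency model: diffusion plus a constant-magnitude
drift towards the CP. Its steady state decays exponentially with distance,
giving `animal_conditional_pdf()` (`~ exp(-beta |z|)`, normalised in
closed form between the borders) and `animal_conditional_pdf_2d()`
(`~ exp(-beta r)` per unit area on the disc, normalising integral
`psi(x) = 1 - (1 + x) e^{-x}` over `beta^2`).

**Marginals.** Integrating the product over border positions gives the
stationary utilisation distributions `marginal_pdf_1d()` (vanishing at the
conspecific CPs) and `marginal_pdf_2d()`. The 2D marginal per unit area
diverges (integrably) at the CP whenever `eps > 0`, because arbitrarily
small territories concentrate all their mass there; with a frozen border
it is finite. For the comparison with the reaction-diffusion model the
left border is pinned at the CP by a Dirac mass, giving the half-territory
marginal `reduced_marginal_half()`; its one-parameter collapse as
`beta -> 0` evaluates through the cosine integral
(`reduced_marginal_limit()`) and integrates to exactly 1 term by term — a
useful internal consistency check.

**Radius variance.** `radius_msd_from_params()` maps `eps` to the
stationary MSD of the territory radius about its mean, in closed form via
folded-normal moments (small-`eps` limit `eps^2/2`); this is the analytic
analogue of the simulated border MSD and the hinge of the inference
programme. `eps_from_radius_msd()` and the 1D analogue
`eps_from_border_msd_1d()` invert it.

## The inference programme

Given relocations of one or more animals (CSV: `animal_id, x, y, t`):

1. `check_msd_saturation()` — the time-averaged MSD over lags must flatten
   (a stable home range). Non-saturating data (dispersers, itinerant
   males) cannot be fitted with a steady-state marginal and the pipeline
   stops with guidance.
2. `fit_marginal()` — maximum likelihood of the dimensionless radii `r/L`
   under the 2D marginal, over `(beta, eps)`. CP defaults to the per-animal
   coordinate-wise median, `L` to the mean nearest-neighbour CP distance
   (`estimate_cp_and_L()`). Fixes are treated as independent; an
   effective-sample-size diagnostic reports how optimistic that is.
3. `radius_msd_from_params()` — the fitted `eps^2` becomes a saturation
   border MSD.
4. `lookup_Z()` on a `calibrate_saturation_map()` surface — invert the
   regenerated simulation calibration for `Z`.
5. `T_AS = Z / (4 D rho)` with the user's `D` and `rho`
   (`infer_active_scent_time()`), with delta-method intervals combining
   fit and calibration uncertainty.

Two calibration estimators are provided. `estimator = "ray"` stores the
stationary variance of the radial border observable itself (the midpoint
of the interstitial gap between own and foreign scent along each bearing —
the same midpoint definition as the 1D border); it is the transparent
saturation-MSD surface and is what the monotonicity checks run on.
`estimator = "fit"` (the default for inference) instead fits the analytic
marginal to the simulated positions of a tracked subset of animals at
every grid point and stores the implied radius MSD. The reason is
geometric: simulated territories tile hexagonally rather than as discs, so
the position-visible border spread carries a geometric floor that the ray
observable does not. Measuring the grid with the same operator that will
be applied to the field data keeps the programme self-consistent; for the
same reason the fitted drift also shifts with `Z`, so the `"fit"` surface
is inverted jointly in `(beta_hat, log msd)` rather than along per-beta
lines. Both the grid and the regression inverse are regenerated by
simulation — nothing is transcribed from published figures.

## Phenomenology that shaped the defaults

These are empirical properties of this implementation, established while
validating it (the test suite recomputes them):

* **1D subdiffusion window.** With no bias, the border MSD shows the
  single-file-like exponent near 1/2 only when the scent lifetime is of
  the order of the diffusive time (`Z ~ 1-2`; we use `Z = 2`, i.e.
  `T_AS = 5000` sweeps on a 100-site ring). Far below, whole-pattern drift
  dominates (exponent near 1); far above, borders freeze (exponent near
  0).
* **2D confinement threshold.** Animals remain inside well-defined
  territories for `Z` of roughly 10 and above at moderate drift; for
  `Z <= 4` they leak through expired terrain unless the drift is strong.
* **Saturation MSD decreases with `Z`** (and with `beta`) in this
  implementation: longer-lived scent stabilises borders. Both directions
  are asserted in the tests; the inversion only needs monotonicity.
* **Adiabatic quality tracks border mobility.** The analytic marginals
  match simulated space use very well in 1D across all tested parameters
  (KS distances 0.02-0.05); in 2D the match is good where borders
  fluctuate little (stable-border pair: KS < 0.08) and degrades where
  they fluctuate strongly, which is also where territories are most
  hexagonal.

Default study conditions: 1D — 2 animals, `L = 50 a`, ring of 100 sites;
2D — 30 animals on an 80 x 84 torus tiling a staggered hexagonal CP grid
with `L = 16 a` (nearest-CP distances within 1% of `L`). Ensembles are
scaled to tens-to-hundreds of replicates, which keeps every check well
inside a desktop minute-scale budget while leaving the conclusions
unchanged.

## Numerical choices

* Image series are truncated adaptively with an absolute tail below
  1e-12; the Poisson representation errors out (reporting the achieved
  bound) if its truncation budget is exceeded.
* Nested integrals use fixed-order Gauss-Legendre panels. Densities with
  narrow border spikes (`eps < 0.08`) are integrated in the scaled
  variable `border = midpoint + eps * u` so the spike is always resolved;
  the 2D marginal adds a log-spaced inner panel for the `1/R^2`
  contribution of small nascent territories. All densities integrate to 1
  within 1e-5 over randomised parameter draws.
* The saturation test fits a least-squares slope over the trailing half of
  an MSD curve and declares saturation unless the slope is both
  practically large (relative slope at least 0.12 over the window) and
  statistically significant; the window and tolerance were set on pilot
  ensembles so that square-root growth and plateaus separate cleanly.
* `mass_radius()` brackets the probability-mass radius by bisection to
  1e-8; the exclusive-area fraction uses the exact circle-circle lens
  formula where pairwise overlaps are disjoint (`R < 1/sqrt(3)`) and exact
  12-fold-symmetric polar integration beyond — a deterministic choice in
  place of a Monte-Carlo fallback; Monte-Carlo rasterisation is kept as
  the independent oracle in the tests.
* The sigmoid summary of home-range radius against drift is a 4-parameter
  logistic fitted with Levenberg-Marquardt; its coefficients are a
  package-level convention, not comparable across parameterisations.
* Optimisations are multi-start (marginal fit: four starts, box
  constraints, Hessian standard errors; likelihood evaluated on
  multiplicity-binned radii, which leaves it invariant for duplicated
  data).

## The reaction-diffusion comparison

With the over-marking response switched off (counter-marking), the
two-animal reaction-diffusion territory model on the unit interval has the
steady state `u(x) = C [1 - tanh(kappa C (x - 1/2))]`, `v(x) = u(1 - x)`,
with scent densities proportional to the animal densities and the free
constant fixed by probability conservation (the package solves for `C` by
bracketed root finding; analytically `C = 1`). `kappa` is a single
dimensionless compound of five dimensional parameters — which is exactly
why that model cannot separate scent longevity from movement, while the
mechanistic model can.

`best_fit_kappa()` and `best_fit_beta_eps()` minimise the integrated
squared difference between `u` and the half-territory marginal on a shared
2048-point grid (`eps` fixed at 0.01 for the inverse fit; lower border
spread never fits worse and does not move the best-fit drift). The models
agree closely only when `beta` and `eps` are both small, where both
approach the same step function — the mechanistic model as
`beta, eps -> 0` (scent never decays, weak drift), the reaction-diffusion
model as `kappa -> Inf`. Consequently the best-fit `beta` *decreases* as
`kappa` grows; away from that corner the best fits are qualitatively
different, and the fit objective grows with either `beta` or `eps`.

## What the synthetic data do and do not show

The generator draws i.i.d. fixes from the stationary analytic marginal
(`sample_relocations()`) or subsamples simulated tracks
(`generate_fixture()`). Real telemetry differs in ways the tests therefore
cannot vouch for: strong temporal autocorrelation at short fix intervals
(the likelihood ignores it; the ESS diagnostic flags it), measurement
error, habitat heterogeneity and anisotropic territories, drifting CPs,
and observation gaps. The hexagonal-tiling geometry is emulated; real
neighbourhoods are irregular, so `L` is itself an estimate. Recovered
`T_AS` values should be read with the reported intervals, which are wide
precisely where the data carry little information about border mobility.

## Known limitations

* The fitted border spread grows slowly with the observation window
  (borders retain a residual slow wander), so the calibration surface and
  the field data should be measured over comparable windows; the
  calibration metadata records the windows used. A strongly mismatched
  window biases the recovered `Z`.
* The active scent time is identifiable from positions only where border
  fluctuations are visible above the hexagonal-geometry floor of the
  position distribution; at large `Z` the calibration surface flattens
  and the interval on `T_AS` grows accordingly. The full-pipeline
  recovery check holds to within a factor of 1.5 (median over seeds) at
  the default study conditions.
* Fitted drift strengths are shrunk relative to the microscopic bias by
  the same geometry (the `"fit"` calibration keys its inverse on the
  fitted scale for exactly this reason); recovery of `beta` within 10%
  holds for data generated by the analytic model itself.
* Non-saturating home ranges (e.g. itinerant phases) are out of scope; the
  pipeline detects and refuses them rather than fitting.
* One spatial scale per system: unequal neighbour spacings, heterogeneous
  landscapes and over-marking behaviour are not modelled.

## A worked example

```{r example, eval = FALSE}
library(terriforage)

# simulate a 2D system of 30 territorial central-place foragers
base <- sim_config(dimension = 2, seed = 1)
cfg <- sim_config(dimension = 2,
                  active_scent_time = tas_for_Z(5, base),
                  bias_p = bias_p_for_beta(6, 16),
                  t_max = 6000, record_every = 10, seed = 42)
rec <- run_simulation(cfg)

# calibration surface (regenerated, never transcribed)
map <- calibrate_saturation_map(betas = c(5, 6, 8), Zs = c(2, 4, 8, 16),
                                replicates = 10, seed = 1)
autoplot(map)

# the inference programme on the tracked animals
rr <- dimensionless_radii(rec, burn_fraction = 0.5, animals = 1:6)
dat <- tibble::tibble(animal_id = 1L, x = rr, y = 0, t = seq_along(rr))
fit <- fit_marginal(dat, cp = c(0, 0), L = 1)
infer_active_scent_time(fit, map, D = 0.25, rho = 30 / 6720)
```
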