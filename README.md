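# terriforage

Territorial dynamics and stable home ranges for central-place foragers:
an agent-based lattice model of scent-mediated conspecific avoidance, its
reduced adiabatic space-use theory, and an inference programme that
recovers the **active scent time** — how long a scent mark keeps excluding
neighbours — from animal relocation data.

## The problem and who this is for

Scent marking is the dominant territorial signal in many terrestrial
mammals, yet the timescale over which a mark actually deters conspecifics
is nearly impossible to measure directly. This package is for movement
ecologists and spatial modellers who want to (i) simulate territory
formation mechanistically, (ii) understand when stable home ranges emerge,
and (iii) put a number (with an interval) on the scent-mark exclusion
time using nothing but telemetry.

## The model in brief

Animals are lattice random walkers with a step bias towards a central
place (CP, a den or nest): in 2D the four move probabilities are
`1/4 ± ((2p−1)/4)·û`, with `û` the unit vector to the CP, so the drift
speed `v` is independent of distance. Every occupied site is marked; a
site carrying *foreign* scent younger than the active scent time `T_AS`
cannot be entered. Territories emerge whose borders fluctuate slowly; with
CP attraction the border mean square displacement (MSD) saturates and a
stable home range appears.

Everything is organised by two dimensionless numbers,

* `β = vL/D` — normalised drift towards the CP (`L` the CP spacing, `D`
  the diffusion constant), and
* `Z = T_AS/K` — scent lifetime over the diffusive time
  (`K = 1/(2Dρ²)` in 1D, `1/(4Dρ)` in 2D, `ρ` the animal density).

At steady state the border density is an image-reflected Gaussian with
spread `ε` (the collapse of the border diffusion constant and restoring
rate, `ε² = K_b/λ`), the animal inside fixed borders follows the
exponential localising-tendency profile `∝ e^{−β|z|}`, and the marginal
utilisation distribution is their adiabatic product integrated over border
positions. The stationary radius MSD is a closed-form function of `ε`,
which is what links fitted positions back to the simulation calibration
surface and hence to `T_AS = Z/(4Dρ)`.

## A worked example

Simulate two territorial neighbours on a ring (`Z = 2`, `β = 4`), extract
the border MSD, convert its plateau into the border-spread parameter, and
summarise the implied home range:

```r
library(terriforage)

cfg <- sim_config(dimension = 1, cp_spacing = 50, active_scent_time = 5000,
                  bias_p = bias_p_for_beta(4, 50, 1, 1),
                  t_max = 5e4, record_every = 100, seed = 42)
rec <- run_simulation(cfg)
rec
#> <trajectory_record> 1D, 2 animals, 500 samples to t = 50000
#>   dimensionless: Z = 2, beta = 4

m <- compute_msd(rec$borders[rec$borders$defined, ], position,
                 time = time, series = border, scale = 50)
s <- detect_saturation(m)
c(value = s$value, saturated = s$saturated)
#> saturation value: 0.01804   saturated: TRUE

eps <- eps_from_border_msd_1d(s$value)   # 0.19
mcp_radius(analytic_params(4, eps))
#> <home_range> R95 = 0.52377 L;  buffer zone: FALSE;  exclusive fraction: 0.9308
```

The border MSD has plateaued at 0.018 `L²` — the signature of a stable
home range — which corresponds to a border-spread `ε ≈ 0.19`. The 95%
probability-mass radius of the stationary space-use distribution is then
0.524 `L`: just over half the CP spacing, so neighbouring home ranges
barely touch (no buffer zone) and 93% of the range is used exclusively.

For the full inference programme on telemetry (CSV with
`animal_id, x, y, t`): `read_relocations()` →
`check_msd_saturation()` → `fit_marginal()` →
`infer_active_scent_time()` against a `calibrate_saturation_map()`
surface. Fitted objects have `tidy()`/`glance()` methods and most results
have `autoplot()` methods. The methods vignette
(`vignettes/territorial-foragers.Rmd`) documents the model, all
dimensionless conventions, the two calibration estimators and the design
decisions.

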