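# abcalcium

Intracellular calcium signals — baseline levels, single-mode
oscillations, mixed-mode oscillations (MMOs) and sustained *aberrant*
(non-periodic) signals — are disrupted early in Alzheimer's disease by
accumulating amyloid-beta (Aβ) oligomers. `abcalcium` implements a
whole-cell dynamical model of this disruption for computational
neuroscientists and modellers: it simulates cytosolic and ER calcium
under three Aβ entry points (membrane pore influx, ryanodine-receptor
sensitisation, stimulated IP3 production), and ships the dynamical
systems machinery needed to map where signalling regimes change.

The core model couples a two-pool calcium balance

```
dc/dt  = J_IPR + J_RyR − J_SERCA + J_in − J_pm + J_vca
dce/dt = −γ (J_IPR + J_RyR − J_SERCA)
```

with six-state IP3-receptor gating (open probability
`P0 = (0.1 O + 0.9 A)^4`), calcium-induced calcium release
`J_RyR = (k1 + k2 c³ / ((kd + kα a)³ + c³))(ce − c)`, a bidirectional
SERCA pump, a Hill-2 plasma-membrane pump, and the Aβ pore term
`kβ a⁴` inside the membrane leak. Optional extensions add dynamic IP3
production/degradation and a Hodgkin–Huxley-style membrane compartment
whose T-type calcium current feeds back on the cytosol. On top of the
simulator:

* `scan_branch()` — equilibrium continuation with Hopf/fold detection
  (eigenvalue sign-change bisection) and divergence localisation;
* `find_orbit()` / `find_period_doubling()` — periodic orbits by
  Poincaré-section shooting, Floquet multipliers from the variational
  equations, period-doubling points by multiplier crossings of −1;
* `classify_trace()` — an operational taxonomy of traces into
  `steady` / `periodic` / `mmo` / `aberrant`, encoding "aberrant" as
  sustained non-periodic oscillation over a 100–200 s window.

Results are tibbles (with `tidy()`/`glance()` methods and `autoplot()`
figures), so everything chains with the pipe.

## Worked example

Where does the ryanodine receptor's Aβ-sensitivity parameter `kα`
destabilise calcium oscillations, at a fixed Aβ level `a = 0.25` and
clamped IP3 `p = 10` µM?

```r
library(abcalcium)

cfg <- model_config(p = 10, a = 0.25)

# sustained oscillations at the default kα
tr <- simulate_model(cfg)
classify_trace(tr, min_window = 100)
#> <ca_classification> periodic | peaks: 17 | amplitude classes: 1 |
#>   periodicity: 1 | period: 10.301 s

# continue the equilibrium in kα and locate the Hopf point
br <- scan_branch("kalpha", c(1.1, 1.5), steps = 20, config = cfg,
                  refine_tol = 1e-5)
tidy(br)
#> # A tibble: 1 × 5
#>   kind  parameter value    eig_re eig_im
#>   <chr> <chr>     <dbl>     <dbl>  <dbl>
#> 1 hopf  kalpha     1.32 0.0000213   2.59
```

The equilibrium loses stability through a Hopf bifurcation at
`kα ≈ 1.32` (complex eigenvalue pair, `|Im λ| ≈ 2.6`, crossing the
imaginary axis): above it the resting state is stable, below it calcium
oscillates. Tracking the periodic orbit downward in `kα` instead:

```r
pd <- find_period_doubling("kalpha", c(0.50, 0.62), steps = 6,
                           config = cfg, max_points = 1)
tidy(pd)
#> # A tibble: 1 × 4
#>   kind            parameter value multiplier
#>   <chr>           <chr>     <dbl>      <dbl>
#> 1 period_doubling kalpha    0.592      -1.01
```

A real Floquet multiplier crosses −1 near `kα ≈ 0.59`: the single-mode
oscillation period-doubles, the entrance to the mixed-mode regime that
produces aberrant signals at intermediate `kα` (simulate at
`model_params(kalpha = 1)` and classify to see one).

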