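---
title: "Methods: a whole-cell calcium model under amyloid-beta"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a whole-cell calcium model under amyloid-beta}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(abcalcium)
```

## The model

`abcalcium` simulates cytosolic calcium `c` and endoplasmic-reticulum (ER)
calcium `ce` in a spatially homogeneous cell:

$$\frac{dc}{dt} = J_{IPR} + J_{RyR} - J_{SERCA} + J_{in} - J_{pm} + J_{vca},
\qquad
\frac{dc_e}{dt} = -\gamma\,(J_{IPR} + J_{RyR} - J_{SERCA}),$$

with $\gamma$ the cytosol-to-ER volume ratio. The flux terms are

* **IP3 receptor**: $J_{IPR} = (k_f P_0 + J_{er})(c_e - c)$ with open
  probability $P_0 = (0.1\,O + 0.9\,A)^4$ from a six-state gating model
  (resting, open, active, shut and two inactive states) whose transition
  rates depend on `c` and the IP3 concentration `p`. The receptor opens
  only when IP3 binds, so low and high `p` both silence it.
* **Ryanodine receptor (CICR)**:
  $J_{RyR} = \left(k_1 + \frac{k_2 c^3}{(k_d + k_\alpha a)^3 + c^3}\right)(c_e - c)$.
  Cytosolic calcium accelerates its own release (calcium-induced calcium
  release); the amyloid-beta level `a` shifts the sensitivity through
  $k_\alpha a$.
* **SERCA pump** (bidirectional four-state reduction):
  $J_{SERCA} = \frac{c - K_1 c_e}{K_2 + K_3 c + K_4 c_e + K_5 c\,c_e}$,
  reversing exactly at $c = K_1 c_e$.
* **Membrane leak and amyloid pore**: $J_{in} = a_1 + a_2 p + k_\beta a^4$ —
  amyloid-beta oligomers form unregulated calcium-permeable membrane
  pores, modelled as a cooperative (`m = 4`) influx term.
* **Plasma-membrane pump**: Hill-2,
  $J_{pm} = V_{pm} c^2 / (K_{pm}^2 + c^2)$.
* **Voltage-gated calcium entry**:
  $J_{vca} = -p_s\,\bar g_{caT}\, m_{caT}^2 h_{caT}\,(V - V_{ca})$, active
  only in the membrane-coupled variant (`ps > 0`).

Three variants mirror the three study conditions: `constant_ip3` (clamped
`p`, 7 ODEs), `dynamic_ip3` (adds a PLC production / 3K+5P degradation
equation for `p`, 8 ODEs), and `with_membrane` (adds a Hodgkin–Huxley-style
voltage compartment with inward-rectifier K⁺, Na⁺, leak, delayed-rectifier
K⁺ and T-type Ca²⁺ currents, 13 ODEs). A single layout function
(`state_layout()`) owns the variable ordering for every variant.

The amyloid-beta level `a` is held constant within a run: its
accumulation in disease evolves over months to years, far slower than the
second-scale calcium dynamics simulated here, so `a` acts as a stage
parameter rather than a dynamic variable. Its units are treated as
numerically µM-like; the model uses it as a dimensionless control.

## Parameter provenance and open choices

All calcium-compartment constants carry the study's published values as
defaults (`model_params()`); every one can be overridden by name.
Several pieces are *not* fixed by the printed tables, and the package
resolves them as follows:

* **IPR gating constants.** The six-state receptor kinetics follow the
  Sneyd–Dufour formulation with its published rate constants; all
  seventeen are exposed (`ipr_*`) so an alternative calibration can be
  dropped in without touching the solver. The receptor's shut state is
  eliminated by conservation (five ODEs), and the default initial
  condition puts all receptors at rest (`R = 1`).
* **ER leak `Jer`.** The assembled calcium equation carries no separate
  ER leak (the RyR's `k1` plays the baseline-leak role), so `Jer`
  defaults to 0 but remains configurable so the IPR flux can be exercised
  in its general form.
* **PLC sensitivity denominator.** The dynamic-IP3 production term is
  implemented as $V_{PLC}(a)\,c^2/(K_{PLC}(a)^2 + c^2)$ by default
  (`squared_sensitivity = TRUE`); an unsquared variant is selectable
  because the two appear interchangeably in the source material. At the
  default $k_{PLC} = 1$ µM and $a = 0$ the two coincide; across the full
  `a` continuation both give the same Hopf structure to under 0.5%, so
  the squared (dimensionally Hill-like) form is the canonical default.
* **Membrane constants.** The sodium/potassium/leak kinetics are the
  classical Hodgkin–Huxley rates — the published initial conditions
  (`m = 0.05, n = 0.32, h = 0.6` at `V = -65`) are exactly the classical
  resting values, and the presence of an `n` gate implies a
  delayed-rectifier current, included as $g_k n^4 (V - V_k)$ behind the
  `include_ik` switch. T-type gating uses the standard low-threshold
  formulation (activation around -57 mV, slow inactivation around
  -81 mV). The printed Kir conductance (pS) and the HH conductances
  (mS-scale) live in different unit systems; `kir_scale` (default 1e-3)
  reconciles them so that the unstimulated membrane rests near -65 mV —
  the one testable anchor — while a sustained strong current pulse
  drives a saturating depolarised plateau. `gcaT` and `ps` are effective
  coefficients: the current-to-flux conversion $1/(2Fw)$ is folded into
  `ps`, the single calibration knob for membrane-to-calcium coupling.
  Membrane-coupled results should be read qualitatively.

## Numerics

* **Integration.** `deSolve::lsoda` with `rtol = 1e-8`, `atol = 1e-10`:
  adaptive, dense output, automatic stiff/non-stiff switching — the
  system mixes millisecond gating with 100-second calcium cycling.
  Stimulus pulses are integrated piecewise so the boxcar edges never fall
  inside an adaptive step. Halving the tolerances changes trace values by
  under 1e-5 relative (asserted in the suite). Concentrations that go
  transiently negative inside a trial step are clamped to zero in flux
  evaluations only; stored states are never altered, so unphysical
  trajectories remain visible.
* **Equilibria.** At any steady state the plasma-membrane balance
  $J_{in} = J_{pm}$ decouples from the ER balance
  $J_{IPR} + J_{RyR} = J_{SERCA}$. `find_steady_state()` exploits this:
  a semi-analytic guess (scalar root solves plus the receptor's
  stationary distribution from the null space of its generator) is
  polished by a damped Newton iteration to residual 1e-10.
* **Stability and continuation.** Eigenvalues come from a central
  finite-difference Jacobian with per-variable steps; an analytic
  Jacobian (used by the variational integration) cross-checks it in the
  tests. `scan_branch()` performs natural-parameter continuation with
  warm starts; stability changes are detected on the overall max
  $\mathrm{Re}\,\lambda$ and bisected to 1e-4 in the parameter, then
  classified by the imaginary part of the critical eigenvalue (Hopf vs
  fold-type neutral point, threshold $|\mathrm{Im}| > 10^{-3}$).
  Tracking the overall maximum rather than "the complex pair" matters:
  just past a Hopf the critical pair can collide on the real axis and
  split, which defeats per-class tracking. Branch divergence is
  localised by bisection on equilibrium existence; for the membrane-off
  model it admits a closed form, influx exceeding pump capacity at
  $a^\ast = (V_{pm} - a_1 - a_2 p)^{1/4}$, used as a cross-check.
* **Periodic orbits.** Single shooting against a Poincaré section
  anchored to `c` (mid-range level, positive crossings), with closure in
  the full state norm so mixed-mode cycles close at their true period.
  The monodromy matrix is accumulated by integrating the variational
  equations with the analytic Jacobian; it supplies both the Newton
  step and the Floquet multipliers, and the trivial multiplier's
  deviation from +1 (kept under 1e-3) certifies the integration.
  Orbit continuation is adaptive: steps are halved whenever shooting
  fails or the period jumps by more than 25%, because the transition
  into the mixed-mode regime is canard-sharp — the critical multiplier
  moves from -0.1 to beyond -1 within a parameter window of order 1e-2.
  Period-doubling points are bisected on the multiplier's crossing of
  -1, guarded by a continuity condition so a discontinuous multiplier
  jump at branch loss is not mistaken for a crossing.
* **Degenerate inputs.** Flux functions reject negative concentrations;
  non-finite fluxes abort with the offending term named; configuration
  files reject unknown keys listing the offenders.

## Signal taxonomy

`classify_trace()` encodes the study's operational definition of
aberrance — sustained non-periodic oscillation over a 100–200 s window —
as follows: discard the transient (default the first 40%), smooth with a
0.5 s moving average (suppresses sample-scale noise, leaves second-scale
calcium peaks intact), detect peaks with prominence ≥ `eps_peak`
(default 0.01 µM), cluster peak amplitudes with a deterministic 1-D
largest-gap rule (`delta_amp`, default 20% of the window amplitude), and
score periodicity as the maximal nonzero-lag normalised autocorrelation
of the joint standardised peak-amplitude/peak-interval sequence. Labels:
*steady* (window amplitude < 0.005 µM), *periodic* (one amplitude class,
score ≥ 0.9), *mmo* (≥ 2 classes, score ≥ 0.9), *aberrant* (≥ 5 peaks,
score < 0.9). All thresholds are arguments because the source defines
the classes only informally. The classification is invariant to uniform
amplitude rescaling and time shifts, exact on noiseless synthetic
waveforms, and degrades gracefully (> 95%) under 1% additive noise.

The synthetic generator (`make_periodic_wave()`, `make_mmo_wave()`,
`make_aberrant_wave()`) builds Gaussian-spike trains with known cycle
composition. It emulates the *peak structure* of calcium signals — not
their relaxation-oscillation asymmetry, baseline drift, or
state-dependent noise — so classifier tests against it certify the
decision logic, not performance on experimental recordings.

## Problem sizes and reproduction

The test suite and the acceptance script run everything at desk scale:
continuations use 60–120 steps with bisection refinement to 1e-4–1e-5,
orbit continuation tracks ~15–25 orbits, and trace classifications use
500 s simulations (transient discarded). These sizes were chosen so each
landmark is resolved well inside its comparison tolerance; doubling them
moves detected points by less than 1e-3 (asserted in the suite).

## Known limitations

* The equilibrium structure of the dynamic-IP3 variant is pinned by the
  plasma-membrane balance: with the default transport constants
  (`a2 = 0.02`, `Vpm = 2.8`) the resting cytosolic calcium stays below
  ~0.08 µM for any reachable IP3 fixed point, and IP3 production (gated
  by $c^2/(K_{PLC}^2+c^2)$) then stays small. Consequently the variant
  exhibits a single high-`a` oscillatory region (driven by the amyloid
  pore term, Hopfs near 1.10 and 1.26 with termination near 1.29) and no
  separate low-`a` region; the acceptance suite documents which
  published landmarks this reproduces and which it cannot.
* Spatial structure, explicit buffering, mitochondria, stochastic
  channel gating and time evolution of the amyloid-beta level are out of
  scope by design.
* Membrane-coupled predictions are qualitative (see parameter
  provenance above).
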