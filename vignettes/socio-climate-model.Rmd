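---
title: "A coupled socio-climate model: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A coupled socio-climate model: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(socioclim)
```

## The model

Climate projections are usually driven by prescribed emission pathways, but
the emissions themselves are produced by people whose behaviour responds to
the climate they experience. `socioclim` closes that loop with a minimal
coupled system: an imitation-dynamics model of mitigative behaviour feeding
back on a reduced Earth-system model.

### Behaviour: imitation dynamics with social norms

Each individual is a *mitigator* or a *non-mitigator*; $x$ is the mitigator
fraction. Individuals sample others at the social learning rate $\kappa$
(per year) and imitate a strategy whose utility is higher, with probability
proportional to the utility gap. The utilities are

$$e_M = -\alpha + c\,\tilde f(T_f) + \delta x, \qquad
  e_N = -\gamma - \tilde f(T_f) + \delta (1 - x),$$

where $\alpha$ is the cost of mitigating, $\gamma$ the levy on
non-mitigative behaviour (a carbon tax, say), $\delta$ the strength of
social norms (a conformity bonus weighted by each strategy's own
prevalence), and $\tilde f(T)$ the perceived cost of climate change. The
net population dynamic is the replicator equation

$$\frac{dx}{dt} = \kappa x (1 - x)\,(e_M - e_N)
  = \kappa x (1 - x)\left[-\beta + f(T_f) + \delta(2x - 1)\right],$$

with the reduced parameters $\beta = \alpha - \gamma$ (net mitigation cost)
and $f = (c + 1)\tilde f$. The package stores parameters in reduced form
and accepts the raw quadruple through the same constructor; the equivalence
of the two forms is exercised in the test suite on randomly drawn tuples.
The boundaries $x = 0, 1$ are analytically invariant, so integrator output
is snapped to them within $10^{-12}$.

Perceived cost is a sigmoid,
$f(T) = f_{\max} / (1 + e^{-\omega (T - T_c)})$: negligible below the
critical anomaly $T_c$, saturating at $f_{\max}$ above it — climate damages
are expected to escalate nonlinearly with warming.

Decisions use a *projected* anomaly rather than the current one:
individuals extrapolate the trend of the last $t_p$ years $t_f$ years
forward,
$$T_f(t) = T(t) + \frac{t_f}{t_p}\left(T(t) - T(t - t_p)\right),$$
which makes the coupled system a delay differential equation with a single
scalar delayed quantity.

### Climate: four carbon pools and an energy balance

Carbon (GtC, as deviations from pre-industrial values) moves between
atmosphere, vegetation, soil and an effective ocean pool:

$$\frac{dC_{at}}{dt} = \epsilon(t)(1 - x) - P + R_{veg} + R_{so} - F_{oc},$$

with gross photosynthesis $P$ (Michaelis–Menten CO2 fertilisation above a
compensation point of 29 ppm with half-saturation 120 ppm, and a weak
linear temperature modifier), Q10 = 2 vegetation and soil respiration,
litter fall transferring carbon from vegetation to soil, and a linear
air–sea exchange damped by warming (solubility). Photosynthetic uptake is
treated as light/area-limited rather than proportional to standing
biomass, so the land sink equilibrates instead of compounding. Because
ocean uptake flows into an explicit pool, total modelled carbon changes
only through the anthropogenic source $\epsilon(t)(1 - x)$ — the
conservation test asserts exactly this. Full mitigation ($x = 1$) shuts
the source off identically.

Surface temperature follows a zero-dimensional energy balance,

$$c_{\mathrm{eff}}\,\frac{dT_{abs}}{dt} = F_d - \sigma T_{abs}^4,$$

written on the *absolute* temperature $T_{abs} = T_{pre} + T$ (only the
absolute form is physical; the anomaly $T$ is reported). $F_d$ is absorbed
shortwave plus greenhouse back-radiation growing logarithmically in CO2;
its constant part is derived at construction so the pre-industrial state
is an exact radiative equilibrium at the reference solar flux. The
planet's area and surface thermal capacity are folded into one effective
areal heat capacity $c_{\mathrm{eff}}$, removing a unit trap while keeping
the printed structure of the balance. The log-CO2 coefficient is set by
the equilibrium warming per CO2 doubling (`climate_sens`), which folds all
fast feedbacks into the forcing term against a bare Planck response.

### Emission forcing

The baseline emission rate $\epsilon(t)$ interpolates an annual historical
series linearly up to 2014 and then follows a saturating increment,
$$\epsilon(t) = \epsilon_{2014} + (t - 2014)\,
  \frac{\epsilon_{\max}}{(t - 2014) + s},$$
mirroring saturating population and energy demand. It is continuous at the
handover, monotone, and approaches (never exceeds) the ceiling
$\epsilon_{2014} + \epsilon_{\max}$.

## Simulation protocol

1. **Spin-up, 1800–2014.** Climate variables start at zero deviation and
   are forced with the full historical emission rate; the social component
   is frozen (implemented as $x = 0$, so $\epsilon$ enters unscaled).
2. **Coupled phase, 2014 onward.** The mitigator fraction is initialised
   at $x_0 = 0.05$ and evolves freely. The delayed temperature
   $T(t - t_p)$ is served from the spin-up interpolant while
   $t - t_p < 2014$ and from the solver's own dense history afterwards
   (method of steps via `deSolve::dede`). The jump from the frozen spin-up
   state to $x_0$ at 2014 is a deliberate state reset.

The integrator is adaptive `lsoda` with relative tolerance $10^{-8}$
(replicator dynamics near the boundaries are stiff-ish); output is stored
every 0.25 years and evaluated off-grid by splines. Halving the tolerances
moves the baseline peak anomaly by well under 0.01 °C (asserted in the
suite).

## Parameters

Baselines and triangular uncertainty bounds ship in
`inst/extdata/default_config.yaml` (the same file
`read_scenario_config()` reads), not hard-coded. The behavioural
baselines: $\kappa = 0.05$/yr (bounds 0.02–0.2, generational to very rapid
learning), $\beta = 1$ (0.5–1.5), $\delta = 1$ (0.5–1.5),
$f_{\max} = 5$ (4–6), $\omega = 3$/°C, $T_c = 2.5$ °C, $t_p = 10$ yr,
$t_f = 40$ yr (30–50), $x_0 = 0.05$ (0.01–0.1). Costs are scaled so that
the perceived cost of strong warming comfortably exceeds the net cost of
mitigating, reflecting the standard argument that preventative action is
far cheaper than unchecked warming.

Climate and forcing constants were calibrated once, jointly, against three
anchors: the historical record at the behavioural start (about 399 ppm and
+1.2 °C in 2014 under the shipped forcing), an RCP8.5-like no-mitigation
pathway (fixed behaviour reaches about +3.8 °C at 2100, with emissions
saturating near 36 GtC/yr), and CMIP-range scenario ordering under the
stylised RCP-like pathways. That yields `climate_sens` 3.2 °C,
`heat_capacity` 4e9 J m⁻² K⁻¹ (an effective value emulating ocean heat
uptake; it sets a multi-decadal surface lag), air–sea exchange 0.035/yr
with back-flux 0.012/yr, and $\epsilon_{\max} = 25$ GtC/yr with
$s = 50$ yr. Solar-flux bounds are ±20 W m⁻² around 1368.

## The synthetic emission fixture

`synth_historical_emissions()` replaces the historical download so the
package builds and tests offline: a power-law backbone
$\epsilon(t) \propto u^3$ (scaled time $u$), pinned to 10.7 GtC/yr at 2014
— which also reproduces the historical cumulative total of roughly 570 GtC
— plus a small seeded smooth perturbation, forced monotone. It emulates
the level, growth shape and cumulative mass of the fossil + land-use
record, but none of its real structure: no wars, depressions or oil
shocks, and no land-use plateau. Tests passing on this fixture therefore
validate the model mechanics and calibration anchors, not agreement with
the observed year-by-year record; `load_historical_emissions()` accepts
the real series (including a land-use column that ends early, extended by
a least-squares line through its last 20 available years — the window is
an argument).

## Experiments

* **Ensembles** (`run_ensemble()`): all uncertain parameters drawn from
  triangular distributions peaking at baseline. The quoted 95% bands are
  pointwise 2.5/97.5 ensemble percentiles (a definitional choice; they are
  uncertainty envelopes, not formal confidence intervals). A master seed
  spawns per-realisation child seeds, so results are reproducible and
  independent of execution order. The spin-up is shared across
  realisations unless a sampled parameter touches climate or forcing, in
  which case it is recomputed per realisation (parameters are fixed in
  time, including before 2014).
* **Tornado** (`tornado()`): each parameter individually to each bound,
  others at baseline; upper and lower deviations are reported separately
  because responses are asymmetric and occasionally one-signed (solar
  flux).
* **Contour and descent** (`contour_grid()`,
  `steepest_descent_path()`): peak anomaly over a $(\beta, \kappa)$ grid;
  the descent follows the negative gradient (central differences on the
  grid, bilinearly interpolated) in a z-scored coordinate system — the
  surface defines no metric between a cost and a rate, so each axis is
  scaled by its grid spread before directions are compared. Steps have
  fixed scaled length; the path stops at the hull or when the scaled
  gradient norm drops below tolerance.
* **Horizon sweep** (`horizon_sweep()`): the ensemble repeated with
  $t_f$ pinned at each sweep value ($t_f = 0$ is legal: decisions on the
  current anomaly only), sharing the master seed across values so the
  sweep isolates the horizon effect.

Peak anomaly is the maximum of $T$ over a window, refined off the storage
grid through the spline interpolant. The default window 1800–2200 is a
declared convention (the dynamics of interest play out within two
centuries of the behavioural start); it is configurable, and peaks under
baseline-like parameters occur a century before its end.

## Numerical and degenerate-input choices

* `max(Δe, 0)` in the switching rates is exact (no smoothing); the net
  reduced form is what enters the integrator, the one-sided rate pair
  exists for inspection and testing, and the two agree identically.
* Degenerate triangular distributions (lower = mode = upper) are legal and
  always return the baseline; a degenerate tornado bar is exactly zero on
  both sides.
* $t_f = 0$ reduces the projection to the current anomaly; $t_p$ must be
  positive and is validated against the available history (a projection
  reaching before 1800 is an error, not an extrapolation).
* Contour-grid node failures are recorded as `NA` with a warning (the grid
  survives); a descent on a grid with `NA` nodes refuses to start.
* Emission schedules reject queries before their first historical year;
  simulations start at the first data year.

## Problem sizes

Single runs integrate 6 state variables over 400 years and take well under
a second; the shipped experiments use 100-realisation ensembles, 9×9
contour grids and one run per tornado bound. The test suite relies on
smaller ensembles (n ≤ 3) and coarse grids where a property does not need
the full design; the acceptance script runs the full 100-member ensemble.

## Limitations

The population is homogeneous — no heterogeneous utilities, social
structure, networks or echo chambers — and the temperature extrapolation
is linear by assumption. The climate core is a deliberately reduced box
model: no spatial resolution, ice/albedo dynamics or ocean circulation,
and its constants are effective values calibrated to a few aggregate
anchors rather than fitted to observational time series. Conclusions
supported here are qualitative and comparative (orderings, signs,
pathway shapes), not quantitative projections.
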