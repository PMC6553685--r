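# socioclim

Climate projections usually treat greenhouse-gas emissions as a prescribed
input. `socioclim` treats them as the output of a human population whose
behaviour responds to the climate it experiences: a minimal coupled
socio-climate simulator for researchers studying human–environment
feedbacks, and for anyone who wants a transparent sandbox in which social
levers (learning rates, norms, mitigation costs) can be compared against
physical ones.

## The model in brief

The proportion of mitigators `x` follows imitation (replicator) dynamics
with social norms:

    dx/dt = κ x (1 − x) [ −β + f(T_f) + δ (2x − 1) ]

where κ is the social learning rate, β the net cost of mitigation, δ the
strength of social norms, and `f(T) = fmax / (1 + exp(−ω (T − Tc)))` the
perceived cost of climate change, evaluated at a projected anomaly
`T_f(t) = T(t) + (t_f/t_p)(T(t) − T(t − t_p))` — a linear extrapolation of
the recent trend, which makes the system a delay differential equation.

The climate side is a reduced Earth-system model: four carbon pools
(atmosphere, vegetation, soil, ocean) exchanging via photosynthesis,
respiration, litter fall and ocean uptake, with the anthropogenic source
scaled by the non-mitigating fraction,

    dC_at/dt = ε(t) (1 − x) − P + R_veg + R_so − F_oc

and a zero-dimensional energy balance `c_eff dT_abs/dt = F_d − σ T_abs⁴`
whose downward flux grows logarithmically with CO2. Emissions follow the
historical record to 2014 and a saturating baseline afterwards. See the
methods vignette (`vignettes/socio-climate-model.Rmd`) for the full
formulation, parameter table and design rationale.

## Worked example

```r
library(socioclim)

cfg  <- scenario_config()          # shipped baselines + synthetic forcing
traj <- run_coupled(cfg)           # spin-up 1800-2014, coupled to 2200
print(traj)
summary(traj)
```

```
Socio-climate trajectory 1800-2200 (1601 points)
  final state: x = 1.000, T = 2.11 C, CO2 = 441 ppm
Peak temperature anomaly: 2.65 C in 2082
At behaviour start: T = 1.16 C, CO2 = 399 ppm
Mitigators in 2060: 64.8%; at horizon end: 100.0% (T = 2.11 C)
```

Read: under baseline parameters the spin-up reaches +1.16 °C and 399 ppm
by 2014; social dynamics then spread mitigative behaviour (65% of the
population by 2060), emissions fall, and the anomaly peaks at 2.65 °C in
2082 before relaxing. A one-at-a-time sensitivity scan of three key
parameters:

```r
tor <- tornado(cfg, default_distributions()[c("kappa", "beta", "tf")])
print(as.data.frame(tor), digits = 3)
```

```
  parameter lower upper dev_lower dev_upper
1     kappa  0.02   0.2     0.805    -0.495
3        tf 30.00  50.0     0.312    -0.252
2      beta  0.50   1.5    -0.209     0.276
```

Each row gives the change in peak anomaly (°C) when that parameter sits at
its lower/upper bound: slow social learning costs +0.81 °C while fast
learning saves only 0.50 °C — the responses are strongly asymmetric, and
the social learning rate dominates.

Other entry points: `run_ensemble()` (triangular-distribution Monte
Carlo), `horizon_sweep()` (effect of the forecast horizon t_f),
`contour_grid()` + `steepest_descent_path()` (intervention pathways over
the (β, κ) plane), `fixed_behaviour_run()` (the no-adaptation null), and
`read_scenario_config()` for YAML-driven use. A thin command-line wrapper
lives at `inst/cli/socioclim.R`:

```sh
Rscript inst/cli/socioclim.R run --out-dir out/
Rscript inst/cli/socioclim.R ensemble --n 100 --seed 1 --out-dir out/
```

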