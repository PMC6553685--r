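# Baseline socio-climate scenario: every value here equals the package
# default, so this file doubles as the editable parameter table.
social:
  kappa: 0.05      # social learning rate (/yr)
  beta: 1          # net mitigation cost (utility)
  delta: 1         # social norm strength (utility)
  fmax: 5          # perceived-cost ceiling (utility)
  omega: 3         # sigmoid steepness (/C)
  Tc: 2.5          # sigmoid midpoint (C anomaly)
  tf: 40           # forward projection horizon (yr)
  tp: 10           # backward trend window (yr)
  x0: 0.05         # mitigator proportion at behaviour start
climate:
  solar_flux: 1368       # W/m2
  albedo: 0.3
  climate_sens: 3.2      # C per CO2 doubling
  heat_capacity: 4.0e+9  # effective areal heat capacity (J/m2/K)
  co2_preind: 280        # ppm
  k_ao: 0.035            # air->ocean exchange (/yr)
  k_oa: 0.012            # ocean back-flux (/yr)
forcing:
  synthetic:
    end_rate: 10.7   # GtC/yr at 2014
    start_year: 1800
    end_year: 2014
    shape: 3
    jitter: 0.02
    seed: 1
  eps_max: 25        # saturating increment (GtC/yr)
  s: 50              # half-saturation (yr)
experiment:
  start_year: 1800
  behaviour_start_year: 2014
  horizon_end: 2200
  rtol: 1.0e-8
  atol: 1.0e-10
  step_out: 0.25
  peak_window: [1800, 2200]
distributions:   # triangular (lower, mode=baseline, upper)
  - {name: kappa, lower: 0.02, mode: 0.05, upper: 0.2}
  - {name: beta, lower: 0.5, mode: 1, upper: 1.5}
  - {name: delta, lower: 0.5, mode: 1, upper: 1.5}
  - {name: fmax, lower: 4, mode: 5, upper: 6}
  - {name: omega, lower: 1, mode: 3, upper: 5}
  - {name: Tc, lower: 2, mode: 2.5, upper: 3}
  - {name: tf, lower: 30, mode: 40, upper: 50}
  - {name: tp, lower: 5, mode: 10, upper: 15}
  - {name: x0, lower: 0.01, mode: 0.05, upper: 0.1}
  - {name: eps_max, lower: 20, mode: 25, upper: 30}
  - {name: s, lower: 30, mode: 50, upper: 70}
  - {name: solar_flux, lower: 1348, mode: 1368, upper: 1388}
  - {name: climate_sens, lower: 2.5, mode: 3.2, upper: 4}
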