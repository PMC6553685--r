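Package: socioclim
Title: Coupled Socio-Climate Dynamics with Social Learning and Norms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulates a coupled human-climate system in which the proportion
    of climate-change mitigators in a population evolves by imitation
    (replicator) dynamics with social norms and delayed temperature
    extrapolation, coupled to a reduced Earth-system model (four carbon pools
    plus a zero-dimensional surface energy balance) forced by anthropogenic
    CO2 emissions. Provides the emission forcing machinery (historical series
    input, a saturating post-2014 baseline, synthetic fixtures), a
    delay-differential simulator with historical spin-up, and the numerical
    experiments built on it: Monte-Carlo ensembles with triangular parameter
    distributions, one-at-a-time (tornado) sensitivity analysis,
    forecast-horizon sweeps, peak-anomaly contour grids over mitigation cost
    and social learning rate, and steepest-descent intervention pathways.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    deSolve,
    stats,
    utils,
    graphics,
    grDevices,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
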