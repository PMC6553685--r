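test_that("spin-up preserves equilibrium without forcing and responds to it", {
  cfg0 <- scenario_config(schedule = zero_schedule())
  sp0 <- spin_up(cfg0)
  expect_true(all(abs(as.matrix(sp0$data[c(state_names())])) < 1e-6))
  sp <- baseline_spin()
  s14 <- traj_at(sp, 2014)
  expect_gt(s14$T, 0)
  expect_gt(s14$C_at, 0)
  expect_equal(sp$data$year[1], 1800)
  expect_equal(sp$data$T[1], 0)   # climate starts at zero deviation
})

test_that("early atmospheric response is close to linear in the forcing", {
  hist <- synth_historical_emissions()
  half <- hist
  half$emissions_gtc <- half$emissions_gtc / 2
  mk <- function(h) scenario_config(schedule = make_schedule(h))
  e1 <- traj_at(spin_up(mk(hist)), 1830, "C_at")$C_at
  e2 <- traj_at(spin_up(mk(half)), 1830, "C_at")$C_at
  expect_equal(e1 / e2, 2, tolerance = 0.1)
})

test_that("coupled run starts at x0, stays in bounds and extends the spin-up", {
  cfg <- baseline_config()
  tr <- run_coupled(cfg, spin = baseline_spin())
  expect_equal(traj_at(tr, 2014, "x")$x, cfg$social$x0, tolerance = 1e-8)
  expect_true(all(tr$data$x >= 0 & tr$data$x <= 1))
  expect_true(all(diff(tr$data$year) > 0))
  # history consistency with the spin-up segment
  shared <- seq(1810, 2010, by = 25)
  expect_equal(traj_at(tr, shared, "T")$T,
               traj_at(baseline_spin(), shared, "T")$T, tolerance = 1e-6)
  # interpolation at stored nodes returns stored values
  i <- c(10, 500, nrow(tr$data))
  expect_equal(traj_at(tr, tr$data$year[i], "T")$T, tr$data$T[i])
})

test_that("boundary and decoupling limits of the coupled run", {
  cfg <- baseline_config()
  sp <- baseline_spin()
  # x0 = 0 is an absorbing boundary reproducing the null model
  cfg0 <- cfg; cfg0$social <- modify_social_params(cfg$social, list(x0 = 0))
  tr0 <- run_coupled(cfg0, spin = sp)
  expect_true(all(tr0$data$x == 0))
  null0 <- fixed_behaviour_run(cfg, 0, spin = sp)
  expect_equal(tr0$data$T, null0$data$T, tolerance = 1e-6)
  # vanishing learning rate freezes x at x0
  cfgk <- cfg; cfgk$social <- modify_social_params(cfg$social,
                                                   list(kappa = 1e-12))
  trk <- run_coupled(cfgk, spin = sp)
  post <- trk$data$year >= 2014
  expect_equal(trk$data$x[post], rep(cfg$social$x0, sum(post)),
               tolerance = 1e-8)
  fixed <- fixed_behaviour_run(cfg, cfg$social$x0, spin = sp)
  expect_equal(trk$data$T, fixed$data$T, tolerance = 1e-5)
})

test_that("fixed-behaviour runs are deterministic and full mitigation relaxes the anomaly", {
  cfg <- baseline_config()
  sp <- baseline_spin()
  a <- fixed_behaviour_run(cfg, 0.05, spin = sp)
  b <- fixed_behaviour_run(cfg, 0.05, spin = sp)
  expect_identical(a$data, b$data)
  full <- fixed_behaviour_run(cfg, 1, spin = sp)
  d <- full$data[full$data$year >= 2014, ]
  # without the anthropogenic source the atmospheric excess declines
  expect_lt(d$C_at[nrow(d)], max(d$C_at))
  expect_lt(d$T[nrow(d)], peak_anomaly(full) )
  expect_lt(peak_anomaly(full), peak_anomaly(a))
})

test_that("frozen-projection coupled run recovers the logistic closed form", {
  cfg <- baseline_config()
  soc <- modify_social_params(cfg$social,
                              list(delta = 0, kappa = 0.2, x0 = 0.05))
  cfg$social <- soc
  Tfc <- 3.2
  tr <- run_coupled(cfg, spin = baseline_spin(),
                    projection_override = function(t) Tfc)
  K <- perceived_cost(Tfc, soc) - soc$beta
  post <- tr$data[tr$data$year >= 2014, ]
  tt <- post$year - 2014
  closed <- 0.05 * exp(soc$kappa * K * tt) /
    (1 - 0.05 + 0.05 * exp(soc$kappa * K * tt))
  expect_equal(post$x, closed, tolerance = 1e-5)
})

test_that("insufficient history and missing forcing are reported", {
  cfg <- baseline_config()
  cfg$social <- modify_social_params(cfg$social, list(tp = 300))
  expect_error(run_coupled(cfg), "insufficient history")
  late <- make_schedule(data.frame(year = c(1900, 2014),
                                   emissions_gtc = c(1, 10)))
  expect_error(scenario_config(schedule = late), "missing forcing")
})

test_that("peak anomaly refines the grid and handles degenerate windows", {
  cfg <- baseline_config()
  mk <- function(years, T) socioclim:::new_trajectory(
    data.frame(year = years, x = 0, C_at = 0, C_veg = 0, C_so = 0,
               C_oc = 0, T = T, emission_rate = 0), cfg)
  yrs <- seq(2000, 2100, by = 1)
  inc <- mk(yrs, 0.01 * (yrs - 2000))
  expect_equal(peak_anomaly(inc, c(2000, 2100)), 1, tolerance = 1e-9)
  const <- mk(yrs, rep(0.7, length(yrs)))
  expect_equal(peak_anomaly(const, c(2010, 2050)), 0.7)
  # parabolic bump with analytic maximum 2.0 at 2050.5 (off the grid)
  bump <- mk(yrs, 2 - 0.001 * (yrs - 2050.5)^2)
  pk <- peak_anomaly(bump, c(2000, 2100), with_year = TRUE)
  expect_equal(pk[["peak"]], 2, tolerance = 1e-6)
  expect_equal(pk[["year"]], 2050.5, tolerance = 1e-2)
  expect_error(peak_anomaly(inc, c(2200, 2300)), "empty peak window")
})

test_that("halving solver tolerances leaves the baseline peak unchanged", {
  cfg <- baseline_config()
  p1 <- peak_anomaly(run_coupled(cfg, spin = baseline_spin()))
  cfg2 <- cfg; cfg2$rtol <- cfg$rtol / 2; cfg2$atol <- cfg$atol / 2
  p2 <- peak_anomaly(run_coupled(cfg2))
  expect_lt(abs(p1 - p2), 0.01)
})

test_that("faster social learning shortens the minority-to-majority transition", {
  cfg <- baseline_config()
  sp <- baseline_spin()
  crossing_time <- function(kappa) {
    c2 <- cfg; c2$social <- modify_social_params(cfg$social,
                                                 list(kappa = kappa))
    d <- run_coupled(c2, spin = sp)$data
    lo <- min(d$year[d$year > 2014 & d$x >= 0.05 & c(0, diff(d$x)) > 0])
    hi <- min(d$year[d$x >= 0.95])
    hi - lo
  }
  times <- vapply(c(0.05, 0.1, 0.3), crossing_time, 0)
  expect_true(all(diff(times) < 0))
})

test_that("end-of-century anomalies follow the stylised scenario ordering", {
  anns <- vapply(c("rcp26", "rcp45", "rcp60", "rcp85"), function(nm) {
    ser <- stylised_rcp_emissions(nm)
    cfg <- scenario_config(
      schedule = make_schedule(ser, eps_max = 0, s = 50, end_year = 2100),
      horizon_end = 2100, peak_window = c(1800, 2100))
    traj_at(fixed_behaviour_run(cfg, 0), 2100, "T")$T
  }, 0)
  expect_true(all(diff(anns) > 0))
})

test_that("trajectory CSV round trip and YAML config loading agree with defaults", {
  f <- withr::local_tempfile(fileext = ".csv")
  sp <- baseline_spin()
  write_trajectory_csv(sp, f)
  back <- utils::read.csv(f)
  expect_equal(names(back),
               c("year", "x", "C_at", "C_veg", "C_so", "C_oc", "T",
                 "emission_rate"))
  expect_equal(back$T, sp$data$T)
  loaded <- read_scenario_config(default_config_path())
  expect_equal(loaded$config$social, baseline_config()$social)
  expect_equal(loaded$config$climate, baseline_config()$climate)
  expect_equal(loaded$config$schedule$historical,
               baseline_config()$schedule$historical)
  expect_equal(loaded$distributions, default_distributions())
})
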