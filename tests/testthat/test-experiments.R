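test_that("triangular sampler matches its closed-form moments and CDF", {
  expect_equal(sample_triangular(param_dist("kappa", 0.3, 0.3, 0.3), 5),
               rep(0.3, 5))
  d <- param_dist("beta", 0.5, 1, 1.5)
  set.seed(11)
  x <- sample_triangular(d, 1e5)
  expect_true(all(x >= 0.5 & x <= 1.5))
  m_theory <- (0.5 + 1 + 1.5) / 3
  v_theory <- (0.5^2 + 1^2 + 1.5^2 - 0.5 * 1 - 0.5 * 1.5 - 1 * 1.5) / 18
  se <- sqrt(v_theory / length(x))
  expect_lt(abs(mean(x) - m_theory), 3 * se)
  p_mode <- (1 - 0.5) / (1.5 - 0.5)
  se_p <- sqrt(p_mode * (1 - p_mode) / length(x))
  expect_lt(abs(mean(x <= 1) - p_mode), 3 * se_p)
  # asymmetric case
  d2 <- param_dist("tf", 0, 10, 40)
  set.seed(12)
  y <- sample_triangular(d2, 1e5)
  expect_lt(abs(mean(y) - 50 / 3), 3 * sqrt(stats::var(y) / length(y)))
  expect_error(param_dist("a", 1, 0.5, 2), "lower <= mode <= upper")
})

test_that("ensembles are reproducible and degenerate ones reduce to single runs", {
  cfg <- baseline_config()
  deg <- list(param_dist("kappa", 0.05, 0.05, 0.05),
              param_dist("beta", 1, 1, 1))
  names(deg) <- c("kappa", "beta")
  e1 <- run_ensemble(cfg, deg, n = 1, master_seed = 3,
                     summarise_times = seq(2014, 2200, 10))
  single <- run_coupled(cfg)
  expect_equal(e1$peak_anomaly, peak_anomaly(single), tolerance = 1e-10)
  expect_equal(e1$T_band$median,
               traj_at(single, seq(2014, 2200, 10), "T")$T,
               tolerance = 1e-10)
  sml <- list(kappa = param_dist("kappa", 0.03, 0.05, 0.15))
  e2 <- run_ensemble(cfg, sml, n = 3, master_seed = 9,
                     summarise_times = c(2100))
  e3 <- run_ensemble(cfg, sml, n = 3, master_seed = 9,
                     summarise_times = c(2100))
  expect_identical(e2$peak_anomaly, e3$peak_anomaly)
  expect_identical(e2$params, e3$params)
  # order-statistic oracle: pointwise median of three runs is the middle one
  probe_T <- vapply(e2$trajectories,
                    function(tr) traj_at(tr, 2100, "T")$T, 0)
  expect_equal(e2$T_band$median, sort(probe_T)[2])
  expect_true(all(e2$T_band$lower <= e2$T_band$median &
                    e2$T_band$median <= e2$T_band$upper))
  expect_error(run_ensemble(cfg, sml, overrides = list(nope = 1), n = 1),
               "unknown parameter")
})

test_that("tornado bars equal two-run differences and keep their sign structure", {
  cfg <- baseline_config()
  dists <- list(tf = param_dist("tf", 30, 40, 50),
                x0 = param_dist("x0", 0.05, 0.05, 0.05))
  tor <- tornado(cfg, dists)
  expect_s3_class(tor, "socioclim_tornado")
  # degenerate parameter contributes exactly zero on both sides
  expect_equal(tor[tor$parameter == "x0", c("dev_lower", "dev_upper")],
               data.frame(dev_lower = 0, dev_upper = 0),
               ignore_attr = TRUE)
  # direct-run oracle for tf
  base <- peak_anomaly(run_coupled(cfg))
  lo <- peak_anomaly(run_coupled(apply_overrides(cfg, list(tf = 30))))
  hi <- peak_anomaly(run_coupled(apply_overrides(cfg, list(tf = 50))))
  row <- tor[tor$parameter == "tf", ]
  expect_equal(row$dev_lower, lo - base, tolerance = 1e-8)
  expect_equal(row$dev_upper, hi - base, tolerance = 1e-8)
  # deviations are reported separately, not forced symmetric
  expect_false(isTRUE(all.equal(row$dev_lower, -row$dev_upper)))
  # ordered by impact
  imp <- pmax(abs(tor$dev_lower), abs(tor$dev_upper))
  expect_true(all(diff(imp) <= 0))
  expect_equal(attr(tor, "baseline_peak"), base, tolerance = 1e-8)
})

test_that("contour grid nodes are single-run peaks, non-increasing in kappa", {
  cfg <- baseline_config()
  g1 <- contour_grid(cfg, beta_grid = 1, kappa_grid = 0.05)
  expect_equal(unname(g1$peak[1, 1]),
               peak_anomaly(run_coupled(cfg, spin = baseline_spin())),
               tolerance = 1e-8)
  kg <- c(0.03, 0.08, 0.2)
  g <- contour_grid(cfg, beta_grid = c(0.75, 1.25), kappa_grid = kg)
  expect_equal(dim(g$peak), c(3, 2))
  for (j in 1:2) expect_true(all(diff(g$peak[, j]) < 0))
  # higher mitigation cost raises the peak at fixed kappa
  expect_true(all(g$peak[, 2] > g$peak[, 1]))
})

test_that("steepest descent on a quadratic bowl finds the analytic minimum", {
  bg <- seq(0, 2, length.out = 41)
  kg <- seq(0, 0.2, length.out = 41)
  z <- outer(kg, bg, function(k, b) (10 * (k - 0.12))^2 + (b - 0.8)^2)
  grid <- list(peak = z, beta_grid = bg, kappa_grid = kg)
  path <- steepest_descent_path(grid, c(beta = 1.8, kappa = 0.02),
                                step = 0.01)
  end <- path[nrow(path), ]
  expect_lt(abs(end$beta - 0.8), diff(bg)[1] * 2)
  expect_lt(abs(end$kappa - 0.12), diff(kg)[1] * 2)
  expect_error(steepest_descent_path(grid, c(beta = 5, kappa = 0.02)),
               "outside the grid hull")
  # brute-force greedy descent over a 10x refined grid lands in the same
  # coarse cell (moves to the best of the 8 neighbours, gain per distance)
  rb <- seq(0, 2, length.out = 401)
  rk <- seq(0, 0.2, length.out = 401)
  zi <- outer(rk / 0.2, rb / 2,
              function(ks, bs) (10 * (ks * 0.2 - 0.12))^2 + (bs * 2 - 0.8)^2)
  ik <- which.min(abs(rk - 0.02)); ib <- which.min(abs(rb - 1.8))
  for (it in 1:20000) {
    nb <- as.matrix(expand.grid(ik + (-1:1), ib + (-1:1)))
    nb <- nb[!(nb[, 1] == ik & nb[, 2] == ib) &
               nb[, 1] >= 1 & nb[, 1] <= 401 & nb[, 2] >= 1 & nb[, 2] <= 401,
             , drop = FALSE]
    dist <- sqrt((nb[, 1] - ik)^2 + (nb[, 2] - ib)^2)
    gain <- (zi[cbind(ik, ib)] - zi[nb]) / dist
    if (all(gain <= 0)) break
    ik <- nb[which.max(gain), 1]; ib <- nb[which.max(gain), 2]
  }
  expect_lt(abs(end$beta - rb[ib]), diff(bg)[1])
  expect_lt(abs(end$kappa - rk[ik]), diff(kg)[1])
})

test_that("on a saturating surface the path spends its early budget on kappa", {
  bg <- seq(0, 1, length.out = 41)
  kg <- seq(0, 1, length.out = 41)
  # steep early gains in kappa that saturate, linear gains in beta
  z <- outer(kg, bg, function(k, b) 2 * exp(-6 * k) + 0.5 * b)
  grid <- list(peak = z, beta_grid = bg, kappa_grid = kg)
  path <- steepest_descent_path(grid, c(beta = 0.95, kappa = 0.05),
                                step = 0.02)
  dk <- abs(diff(path$kappa)); db <- abs(diff(path$beta))
  n <- length(dk)
  early <- 1:ceiling(n / 4)
  late <- (n - floor(n / 4)):n
  expect_gt(mean(dk[early] > db[early]), 0.9)
  expect_gt(mean(db[late] > dk[late]), 0.9)
  # the surface value decreases monotonically along the path
  expect_true(all(diff(path$peak) < 0))
})

test_that("horizon sweep reduces to the ensemble and reports honest quantiles", {
  cfg <- baseline_config()
  dists <- list(kappa = param_dist("kappa", 0.03, 0.05, 0.15))
  sw <- horizon_sweep(cfg, dists, tf_values = 40, n = 3, master_seed = 21)
  ens <- run_ensemble(cfg, dists, overrides = list(tf = 40), n = 3,
                      master_seed = 21, summarise_times = 2100)
  expect_equal(sw$peak_anomaly, ens$peak_anomaly)
  # IQR against the order-statistic interpolation formula (type-7)
  x <- sort(sw$peak_anomaly)
  manual_q <- function(p) {
    h <- (length(x) - 1) * p
    x[floor(h) + 1] + (h - floor(h)) * (x[min(floor(h) + 2, length(x))] -
                                          x[floor(h) + 1])
  }
  expect_equal(unname(stats::quantile(sw$peak_anomaly, 0.75) -
                        stats::quantile(sw$peak_anomaly, 0.25)),
               manual_q(0.75) - manual_q(0.25))
})

test_that("scenario presets return exactly the published override sets", {
  expect_equal(scenario_presets("worst"),
               list(kappa = 0.02, beta = 1.5, delta = 1.5, fmax = 4,
                    x0 = 0.01))
  expect_equal(scenario_presets("best"),
               list(kappa = 0.2, beta = 0.5, delta = 0.5, fmax = 6,
                    tf = 50))
  expect_error(scenario_presets("middling"), "unknown preset")
})
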