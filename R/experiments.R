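#' Triangular parameter distribution
#'
#' A triangular distribution on `[lower, upper]` peaking at `mode` (the
#' baseline value), the uncertainty description used for every sampled
#' parameter. The degenerate case `lower == mode == upper` is allowed and
#' always returns the baseline.
#'
#' @param name parameter name (must match a social, climate or forcing
#'   parameter; see [default_distributions()]).
#' @param lower,mode,upper bounds and peak, `lower <= mode <= upper`.
#' @return object of class `param_dist`.
#' @export
param_dist <- function(name, lower, mode, upper) {
  if (!(is.character(name) && length(name) == 1L))
    stop("name must be a single string", call. = FALSE)
  if (!(lower <= mode && mode <= upper))
    stop("need lower <= mode <= upper for '", name, "'", call. = FALSE)
  structure(list(name = name, lower = lower, mode = mode, upper = upper),
            class = "param_dist")
}

#' Draw from a triangular distribution
#'
#' Inverse-CDF sampling: with `F(mode) = (mode - lower)/(upper - lower)`,
#' a uniform draw below `F(mode)` maps through the rising branch
#' `lower + sqrt(u (upper - lower)(mode - lower))` and above it through the
#' falling branch.
#'
#' @param dist a [param_dist()].
#' @param n number of draws.
#' @return numeric vector in `[lower, upper]`; draws consume the current R
#'   RNG stream, so they are reproducible under `set.seed()`.
#' @export
sample_triangular <- function(dist, n = 1) {
  stopifnot(inherits(dist, "param_dist"))
  a <- dist$lower; m <- dist$mode; b <- dist$upper
  if (a == b) return(rep(a, n))
  u <- stats::runif(n)
  Fm <- (m - a) / (b - a)
  ifelse(u < Fm,
         a + sqrt(u * (b - a) * (m - a)),
         b - sqrt((1 - u) * (b - a) * (b - m)))
}

#' Default parameter distributions
#'
#' The baseline (mode) and triangular bounds for every uncertain parameter:
#' behavioural constants, the post-2014 emission schedule, and the two
#' sampled climate constants. Baselines equal the package defaults of
#' [social_params()], [make_schedule()] and [climate_params()].
#'
#' @return named list of [param_dist()] objects.
#' @export
default_distributions <- function() {
  d <- list(
    param_dist("kappa", 0.02, 0.05, 0.2),
    param_dist("beta", 0.5, 1, 1.5),
    param_dist("delta", 0.5, 1, 1.5),
    param_dist("fmax", 4, 5, 6),
    param_dist("omega", 1, 3, 5),
    param_dist("Tc", 2, 2.5, 3),
    param_dist("tf", 30, 40, 50),
    param_dist("tp", 5, 10, 15),
    param_dist("x0", 0.01, 0.05, 0.1),
    param_dist("eps_max", 20, 25, 30),
    param_dist("s", 30, 50, 70),
    param_dist("solar_flux", 1348, 1368, 1388),
    param_dist("climate_sens", 2.5, 3.2, 4))
  stats::setNames(d, vapply(d, `[[`, "", "name"))
}

# which component each overridable parameter belongs to
param_component <- function(name) {
  if (name %in% c("kappa", "beta", "fmax", "delta", "omega", "Tc", "tf",
                  "tp", "x0")) return("social")
  if (name %in% c("eps_max", "s")) return("forcing")
  if (name %in% names(formals(climate_params))) return("climate")
  stop("unknown parameter name: '", name, "'", call. = FALSE)
}

#' Apply named parameter overrides to a scenario
#'
#' Routes each entry of a named list to the component it belongs to
#' (social, climate or forcing) and returns the modified
#' [scenario_config()], revalidating and recomputing derived constants.
#' This is the mechanism behind ensembles, tornado bounds and
#' [scenario_presets()].
#'
#' @param config a [scenario_config()].
#' @param overrides named list of scalar parameter values (e.g.
#'   `list(kappa = 0.2, solar_flux = 1388, eps_max = 20)`).
#' @return the modified `scenario_config`.
#' @export
apply_overrides <- function(config, overrides) {
  if (!length(overrides)) return(config)
  comp <- vapply(names(overrides), param_component, "")
  soc <- overrides[comp == "social"]
  cli <- overrides[comp == "climate"]
  frc <- overrides[comp == "forcing"]
  if (length(soc)) config$social <- modify_social_params(config$social, soc)
  if (length(cli))
    config$climate <- modify_climate_params(config$climate, cli)
  if (length(frc)) {
    sch <- config$schedule
    config$schedule <- make_schedule(
      sch$historical,
      eps_max = if ("eps_max" %in% names(frc)) frc$eps_max else sch$eps_max,
      s = if ("s" %in% names(frc)) frc$s else sch$s,
      end_year = sch$end_year)
  }
  config
}

# master seed -> per-realisation child seeds (order-independent)
child_seeds <- function(master_seed, n) {
  rng <- local_rng(master_seed)
  rng$int(n, .Machine$integer.max - 1L)
}

run_one_realisation <- function(config, distributions, overrides, seed,
                                base_spin) {
  drawn <- list()
  if (length(distributions)) {
    rng <- local_rng(seed)
    u <- rng$unif(length(distributions))
    for (i in seq_along(distributions)) {
      d <- distributions[[i]]
      if (d$name %in% names(overrides)) next
      a <- d$lower; m <- d$mode; b <- d$upper
      Fm <- if (b > a) (m - a) / (b - a) else 1
      drawn[[d$name]] <- if (b == a) a
      else if (u[i] < Fm) a + sqrt(u[i] * (b - a) * (m - a))
      else b - sqrt((1 - u[i]) * (b - a) * (b - m))
    }
  }
  all_ov <- utils::modifyList(drawn, as.list(overrides))
  cfg <- apply_overrides(config, all_ov)
  comp <- if (length(all_ov)) vapply(names(all_ov), param_component, "")
          else character()
  # the historical spin-up only feels climate/forcing parameters; reuse the
  # shared one when none of those were touched
  spin <- if (any(comp %in% c("climate", "forcing"))) spin_up(cfg)
          else base_spin
  list(traj = run_coupled(cfg, spin = spin), params = all_ov)
}

#' Monte-Carlo ensemble
#'
#' Runs `n` coupled simulations with uncertain parameters drawn from
#' triangular distributions, optionally holding some parameters at fixed
#' override values. Per-realisation seeds are spawned deterministically
#' from the master seed, so results are reproducible and independent of
#' execution order. Parameters are applied from 1800 (the historical
#' spin-up is recomputed whenever a sampled parameter affects it), matching
#' the convention that parameters are fixed in time.
#'
#' @param config a [scenario_config()] holding the baselines.
#' @param distributions named list of [param_dist()]; default
#'   [default_distributions()].
#' @param overrides named list of fixed parameter values that bypass
#'   sampling.
#' @param n ensemble size.
#' @param master_seed integer master seed.
#' @param summarise_times years at which pointwise summaries are formed.
#' @return object of class `socioclim_ensemble`: per-realisation peak
#'   anomalies, drawn parameters, pointwise median and 95% band (2.5/97.5
#'   percentiles) of `T` and `x`, and the realisation trajectories.
#' @export
run_ensemble <- function(config, distributions = default_distributions(),
                         overrides = list(), n = 100, master_seed = 1L,
                         summarise_times = NULL) {
  stopifnot(inherits(config, "scenario_config"), n >= 1)
  for (nm in names(overrides)) param_component(nm)  # validate names
  if (is.null(summarise_times))
    summarise_times <- seq(config$start_year, config$horizon_end, by = 1)
  base_spin <- spin_up(config)
  seeds <- child_seeds(master_seed, n)
  runs <- vector("list", n)
  for (i in seq_len(n))
    runs[[i]] <- run_one_realisation(config, distributions, overrides,
                                     seeds[i], base_spin)
  peak <- vapply(runs, function(r) peak_anomaly(r$traj), 0)
  Tmat <- matrix(vapply(runs, function(r)
    traj_at(r$traj, summarise_times, "T")$T,
    numeric(length(summarise_times))), nrow = length(summarise_times))
  Xmat <- matrix(vapply(runs, function(r)
    traj_at(r$traj, summarise_times, "x")$x,
    numeric(length(summarise_times))), nrow = length(summarise_times))
  band <- function(mat) {
    q <- apply(mat, 1, stats::quantile, probs = c(0.025, 0.5, 0.975),
               names = FALSE)
    q <- matrix(q, nrow = 3)
    data.frame(year = summarise_times, lower = q[1, ], median = q[2, ],
               upper = q[3, ])
  }
  out <- list(peak_anomaly = peak, params = lapply(runs, `[[`, "params"),
              T_band = band(Tmat), x_band = band(Xmat),
              trajectories = lapply(runs, `[[`, "traj"),
              n = n, master_seed = master_seed)
  class(out) <- "socioclim_ensemble"
  out
}

#' @export
print.socioclim_ensemble <- function(x, ...) {
  q <- stats::quantile(x$peak_anomaly, c(0.025, 0.5, 0.975))
  cat(sprintf("Socio-climate ensemble: %d realisations (master seed %d)\n",
              x$n, x$master_seed))
  cat(sprintf("  peak anomaly median %.2f C (95%% band %.2f-%.2f C)\n",
              q[2], q[1], q[3]))
  invisible(x)
}

#' @export
plot.socioclim_ensemble <- function(x, ...) {
  b <- x$T_band
  graphics::plot(b$year, b$median, type = "l",
                 ylim = range(c(b$lower, b$upper)),
                 xlab = "year", ylab = "T anomaly (C)", ...)
  graphics::polygon(c(b$year, rev(b$year)), c(b$lower, rev(b$upper)),
                    col = grDevices::adjustcolor("steelblue", 0.3),
                    border = NA)
  graphics::lines(b$year, b$median)
  invisible(x)
}

#' One-at-a-time (tornado) sensitivity analysis
#'
#' For each distribution, runs the model once with the parameter at its
#' lower bound and once at its upper bound (all other parameters at
#' baseline), and reports the deviation of the peak temperature anomaly
#' from the all-baseline run. Upper- and lower-bound deviations are kept
#' separate because the responses are typically asymmetric (and sometimes
#' of equal sign, as for the solar flux).
#'
#' @param config a [scenario_config()] at baseline values.
#' @param distributions named list of [param_dist()].
#' @return data.frame (class `socioclim_tornado`) with columns `parameter`,
#'   `lower`, `upper` (bound values), `dev_lower`, `dev_upper` (degrees C),
#'   and attribute `baseline_peak`; rows ordered by decreasing
#'   `max(|dev_lower|, |dev_upper|)`. Failed runs propagate as errors
#'   naming the parameter and bound.
#' @export
tornado <- function(config, distributions = default_distributions()) {
  stopifnot(inherits(config, "scenario_config"))
  base_peak <- peak_anomaly(run_coupled(config))
  one <- function(name, value, side) {
    ov <- stats::setNames(list(value), name)
    tryCatch(peak_anomaly(run_coupled(apply_overrides(config, ov))),
             error = function(e)
               stop("tornado run failed for ", name, " at ", side,
                    " bound: ", conditionMessage(e), call. = FALSE))
  }
  rows <- lapply(distributions, function(d) {
    dl <- if (d$lower == d$mode) 0 else one(d$name, d$lower, "lower") - base_peak
    du <- if (d$upper == d$mode) 0 else one(d$name, d$upper, "upper") - base_peak
    data.frame(parameter = d$name, lower = d$lower, upper = d$upper,
               dev_lower = dl, dev_upper = du)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out <- out[order(-pmax(abs(out$dev_lower), abs(out$dev_upper))), ]
  attr(out, "baseline_peak") <- base_peak
  class(out) <- c("socioclim_tornado", "data.frame")
  out
}

#' @export
plot.socioclim_tornado <- function(x, ...) {
  n <- nrow(x)
  ord <- rev(seq_len(n))
  graphics::plot(NULL, xlim = range(c(x$dev_lower, x$dev_upper, 0)),
                 ylim = c(0.5, n + 0.5), yaxt = "n",
                 xlab = "peak anomaly deviation (C)", ylab = "", ...)
  graphics::axis(2, at = seq_len(n), labels = x$parameter[ord], las = 1)
  for (i in seq_len(n)) {
    r <- x[ord[i], ]
    graphics::rect(0, i - 0.3, r$dev_upper, i + 0.3, col = "firebrick")
    graphics::rect(0, i - 0.3, r$dev_lower, i + 0.3, col = "steelblue")
  }
  graphics::abline(v = 0)
  invisible(x)
}

#' Peak-anomaly surface over mitigation cost and learning rate
#'
#' Deterministic grid of peak temperature anomalies at specified values of
#' the net mitigation cost (beta) and the social learning rate (kappa),
#' all other parameters at baseline.
#'
#' @param config a [scenario_config()].
#' @param beta_grid,kappa_grid numeric grids (non-empty).
#' @return object of class `socioclim_contour`: a matrix of peak anomalies
#'   indexed `[kappa, beta]`, plus the grids. Per-node failures are
#'   recorded as `NA` with a warning, not errors.
#' @export
contour_grid <- function(config, beta_grid, kappa_grid) {
  stopifnot(length(beta_grid) >= 1, length(kappa_grid) >= 1)
  spin <- spin_up(config)
  m <- matrix(NA_real_, length(kappa_grid), length(beta_grid),
              dimnames = list(kappa = signif(kappa_grid, 6),
                              beta = signif(beta_grid, 6)))
  for (i in seq_along(kappa_grid)) for (j in seq_along(beta_grid)) {
    cfg <- apply_overrides(config, list(kappa = kappa_grid[i],
                                        beta = beta_grid[j]))
    m[i, j] <- tryCatch(peak_anomaly(run_coupled(cfg, spin = spin)),
                        error = function(e) {
                          warning("grid node kappa=", kappa_grid[i],
                                  ", beta=", beta_grid[j], " failed: ",
                                  conditionMessage(e), call. = FALSE)
                          NA_real_
                        })
  }
  structure(list(peak = m, beta_grid = beta_grid, kappa_grid = kappa_grid),
            class = "socioclim_contour")
}

#' @export
plot.socioclim_contour <- function(x, path = NULL, ...) {
  graphics::contour(x$kappa_grid, x$beta_grid, x$peak,
                    xlab = "kappa (/yr)", ylab = "beta", ...)
  if (!is.null(path))
    graphics::lines(path$kappa, path$beta, col = "red", lwd = 2)
  invisible(x)
}

# bilinearly interpolate a gridded field at (xi, yi)
bilinear <- function(xg, yg, z, xi, yi) {
  i <- findInterval(xi, xg, all.inside = TRUE)
  j <- findInterval(yi, yg, all.inside = TRUE)
  tx <- (xi - xg[i]) / (xg[i + 1] - xg[i])
  ty <- (yi - yg[j]) / (yg[j + 1] - yg[j])
  z[i, j] * (1 - tx) * (1 - ty) + z[i + 1, j] * tx * (1 - ty) +
    z[i, j + 1] * (1 - tx) * ty + z[i + 1, j + 1] * tx * ty
}

#' Steepest-descent pathway on a peak-anomaly surface
#'
#' Follows the negative gradient of the gridded peak-anomaly surface from a
#' starting point, in a rescaled coordinate system in which each axis is
#' z-scored by its grid spread (so "steepest" compares the two axes on a
#' common scale; the surface itself defines no metric between cost and
#' rate). The gradient is formed by central differences on the grid and
#' interpolated bilinearly; steps have fixed length `step` in the scaled
#' space. The path stops at the grid boundary or when the gradient norm
#' falls below `grad_tol`.
#'
#' @param grid a [contour_grid()] result (or any list with `peak`,
#'   `beta_grid`, `kappa_grid`).
#' @param start named numeric `c(beta =, kappa =)` inside the grid hull.
#' @param step step length in scaled units.
#' @param grad_tol termination tolerance on the scaled gradient norm.
#' @param max_steps safety cap on the number of steps.
#' @return data.frame with columns `beta`, `kappa`, `peak` along the path.
#' @export
steepest_descent_path <- function(grid, start, step = 0.02,
                                  grad_tol = 1e-4, max_steps = 2000) {
  kg <- grid$kappa_grid; bg <- grid$beta_grid; z <- grid$peak
  if (any(is.na(z))) stop("grid contains failed nodes", call. = FALSE)
  b <- start[["beta"]]; k <- start[["kappa"]]
  if (b < min(bg) || b > max(bg) || k < min(kg) || k > max(kg))
    stop("start point outside the grid hull", call. = FALSE)
  sk <- diff(range(kg)); sb <- diff(range(bg))
  if (sk == 0 || sb == 0) stop("degenerate grid", call. = FALSE)
  # central-difference gradient fields on the grid (forward/backward at edges)
  gradk <- apply(z, 2, function(col) num_grad(kg, col))
  gradb <- t(apply(z, 1, function(row) num_grad(bg, row)))
  path <- list()
  for (it in seq_len(max_steps)) {
    pk <- bilinear(kg, bg, z, k, b)
    path[[it]] <- c(beta = b, kappa = k, peak = pk)
    gk <- bilinear(kg, bg, gradk, k, b) * sk   # d peak per scaled kappa
    gb <- bilinear(kg, bg, gradb, k, b) * sb
    gnorm <- sqrt(gk^2 + gb^2)
    if (gnorm < grad_tol) break
    k2 <- k - step * (gk / gnorm) * sk
    b2 <- b - step * (gb / gnorm) * sb
    hit <- k2 < min(kg) || k2 > max(kg) || b2 < min(bg) || b2 > max(bg)
    k <- min(max(k2, min(kg)), max(kg))
    b <- min(max(b2, min(bg)), max(bg))
    if (hit) {
      path[[it + 1]] <- c(beta = b, kappa = k,
                          peak = bilinear(kg, bg, z, k, b))
      break
    }
  }
  as.data.frame(do.call(rbind, path))
}

# gradient of values sampled at (possibly uneven) nodes
num_grad <- function(xg, y) {
  n <- length(xg)
  g <- numeric(n)
  if (n == 1) return(g)
  g[1] <- (y[2] - y[1]) / (xg[2] - xg[1])
  g[n] <- (y[n] - y[n - 1]) / (xg[n] - xg[n - 1])
  if (n > 2) {
    i <- 2:(n - 1)
    g[i] <- (y[i + 1] - y[i - 1]) / (xg[i + 1] - xg[i - 1])
  }
  g
}

#' Forecast-horizon sweep
#'
#' Repeats the Monte-Carlo ensemble with the forward extrapolation horizon
#' `tf` held at each value of a sweep grid (all other uncertain parameters
#' sampled), collecting the peak-anomaly samples behind box-and-whisker
#' summaries. `tf = 0` (decisions based on the current anomaly only) is a
#' legal sweep value.
#'
#' @param config a [scenario_config()].
#' @param distributions named list of [param_dist()].
#' @param tf_values numeric vector of horizons (years).
#' @param n realisations per horizon.
#' @param master_seed master seed (shared across horizons so the sweep
#'   isolates the effect of `tf`).
#' @return data.frame (class `socioclim_sweep`) with one row per
#'   realisation: `tf`, `realisation`, `peak_anomaly`.
#' @export
horizon_sweep <- function(config, distributions = default_distributions(),
                          tf_values = c(0, 10, 20, 30, 40, 50), n = 100,
                          master_seed = 1L) {
  rows <- lapply(tf_values, function(tf) {
    ens <- run_ensemble(config, distributions, overrides = list(tf = tf),
                        n = n, master_seed = master_seed)
    data.frame(tf = tf, realisation = seq_len(n),
               peak_anomaly = ens$peak_anomaly)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("socioclim_sweep", "data.frame")
  out
}

#' @export
plot.socioclim_sweep <- function(x, ...) {
  graphics::boxplot(peak_anomaly ~ tf, data = x, range = 0,
                    xlab = "forecast horizon tf (yr)",
                    ylab = "peak anomaly (C)", ...)
  invisible(x)
}

#' Published scenario presets
#'
#' Fixed parameter override sets for the two bracketing scenarios: `worst`
#' sets the social parameters to the bounds that most favour non-mitigative
#' behaviour (kappa 0.02, beta 1.5, delta 1.5, fmax 4, x0 0.01); `best`
#' to the bounds that least favour it (kappa 0.2, beta 0.5, delta 0.5,
#' fmax 6, tf 50).
#'
#' @param name `"worst"` or `"best"`.
#' @return named list of overrides for [run_ensemble()] /
#'   [apply_overrides()].
#' @export
scenario_presets <- function(name) {
  switch(name,
         worst = list(kappa = 0.02, beta = 1.5, delta = 1.5, fmax = 4,
                      x0 = 0.01),
         best = list(kappa = 0.2, beta = 0.5, delta = 0.5, fmax = 6,
                     tf = 50),
         stop("unknown preset: '", name, "' (use \"worst\" or \"best\")",
              call. = FALSE))
}
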