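#' Scenario configuration
#'
#' Bundles everything one simulation needs: behavioural parameters, Earth
#' system parameters, the emission schedule, the simulated period and solver
#' settings. The period splits into a historical spin-up
#' `[start_year, behaviour_start_year]` with the social component frozen,
#' and the coupled phase `[behaviour_start_year, horizon_end]` in which the
#' proportion of mitigators evolves.
#'
#' @param social a [social_params()] object.
#' @param climate a [climate_params()] object.
#' @param schedule an [make_schedule()] emission schedule.
#' @param start_year first simulated year; must be covered by the schedule.
#' @param behaviour_start_year year at which social dynamics are initiated
#'   (mitigator proportion reset to `social$x0`).
#' @param horizon_end last simulated year. The default carries the run two
#'   centuries past the behavioural start, which brackets the post-peak
#'   decline in all configurations shipped here.
#' @param rtol,atol solver tolerances (lsoda).
#' @param step_out spacing of stored output (years).
#' @param peak_window default window for [peak_anomaly()].
#' @param seed optional integer seed recorded with the configuration.
#' @return object of class `scenario_config`.
#' @export
scenario_config <- function(social = social_params(),
                            climate = climate_params(),
                            schedule = make_schedule(
                              synth_historical_emissions()),
                            start_year = 1800,
                            behaviour_start_year = 2014,
                            horizon_end = 2200,
                            rtol = 1e-8, atol = 1e-10, step_out = 0.25,
                            peak_window = c(1800, 2200), seed = NULL) {
  validate_social_params(social)
  validate_climate_params(climate)
  stopifnot(inherits(schedule, "emission_schedule"))
  if (!(start_year < behaviour_start_year &&
        behaviour_start_year < horizon_end))
    stop("need start_year < behaviour_start_year < horizon_end",
         call. = FALSE)
  if (schedule$historical$year[1] > start_year)
    stop("missing forcing: emission schedule starts at ",
         schedule$historical$year[1], " but the simulation starts at ",
         start_year, call. = FALSE)
  cfg <- list(social = social, climate = climate, schedule = schedule,
              start_year = start_year,
              behaviour_start_year = behaviour_start_year,
              horizon_end = horizon_end, rtol = rtol, atol = atol,
              step_out = step_out, peak_window = peak_window, seed = seed)
  class(cfg) <- "scenario_config"
  cfg
}

#' @export
print.scenario_config <- function(x, ...) {
  cat(sprintf("Socio-climate scenario: %d-%d, behaviour from %d\n",
              x$start_year, x$horizon_end, x$behaviour_start_year))
  print(x$social); print(x$climate); print(x$schedule)
  invisible(x)
}

traj_columns <- function() c("x", state_names(), "emission_rate")

new_trajectory <- function(df, config) {
  stopifnot(all(c("year", traj_columns()) %in% names(df)))
  obj <- list(data = df, config = config, cache = new.env(parent = emptyenv()))
  class(obj) <- "socioclim_traj"
  obj
}

# cached per-column spline interpolant of a trajectory
traj_interp <- function(traj, var) {
  if (is.null(traj$cache[[var]]))
    traj$cache[[var]] <- stats::splinefun(traj$data$year, traj$data[[var]],
                                          method = "fmm")
  traj$cache[[var]]
}

#' Evaluate a trajectory at arbitrary times
#'
#' Spline interpolation of a stored trajectory; at stored nodes the stored
#' value is returned exactly. The mitigator proportion is clamped to
#' `[0, 1]`.
#'
#' @param traj a `socioclim_traj` object.
#' @param t times (calendar years) within the trajectory range.
#' @param vars variables to evaluate (default all).
#' @return data.frame with column `year` plus one column per variable.
#' @export
traj_at <- function(traj, t, vars = traj_columns()) {
  rng <- range(traj$data$year)
  if (any(t < rng[1] - 1e-9 | t > rng[2] + 1e-9))
    stop("time outside trajectory range [", rng[1], ", ", rng[2], "]",
         call. = FALSE)
  out <- data.frame(year = t)
  for (v in vars) {
    val <- traj_interp(traj, v)(t)
    if (v == "x") val <- clamp01(val)
    out[[v]] <- val
  }
  out
}

#' @export
as.data.frame.socioclim_traj <- function(x, ...) x$data

#' @export
print.socioclim_traj <- function(x, ...) {
  d <- x$data
  cat(sprintf("Socio-climate trajectory %g-%g (%d points)\n",
              min(d$year), max(d$year), nrow(d)))
  last <- d[nrow(d), ]
  cat(sprintf("  final state: x = %.3f, T = %.2f C, CO2 = %.0f ppm\n",
              last$x, last$T,
              (x$config$climate$C_at0 + last$C_at) /
                x$config$climate$gtc_per_ppm))
  invisible(x)
}

#' @export
summary.socioclim_traj <- function(object, ...) {
  cfg <- object$config
  pk <- peak_anomaly(object, cfg$peak_window, with_year = TRUE)
  tb <- cfg$behaviour_start_year
  probe <- traj_at(object, pmin(c(tb, 2060, cfg$horizon_end),
                                max(object$data$year)))
  out <- list(peak_anomaly = pk[["peak"]], peak_year = pk[["year"]],
              T_behaviour_start = probe$T[1],
              co2_ppm_behaviour_start =
                (cfg$climate$C_at0 + probe$C_at[1]) / cfg$climate$gtc_per_ppm,
              x_2060 = probe$x[2], T_end = probe$T[3],
              x_end = probe$x[3])
  class(out) <- "summary.socioclim_traj"
  out
}

#' @export
print.summary.socioclim_traj <- function(x, ...) {
  cat(sprintf("Peak temperature anomaly: %.2f C in %.0f\n",
              x$peak_anomaly, x$peak_year))
  cat(sprintf("At behaviour start: T = %.2f C, CO2 = %.0f ppm\n",
              x$T_behaviour_start, x$co2_ppm_behaviour_start))
  cat(sprintf("Mitigators in 2060: %.1f%%; at horizon end: %.1f%% (T = %.2f C)\n",
              100 * x$x_2060, 100 * x$x_end, x$T_end))
  invisible(x)
}

#' @export
plot.socioclim_traj <- function(x, ...) {
  d <- x$data
  old <- graphics::par(mfrow = c(3, 1), mar = c(2.5, 4, 1, 1))
  on.exit(graphics::par(old))
  graphics::plot(d$year, d$T, type = "l", xlab = "", ylab = "T anomaly (C)",
                 ...)
  graphics::plot(d$year, d$x, type = "l", ylim = c(0, 1), xlab = "",
                 ylab = "mitigators x")
  graphics::plot(d$year, d$emission_rate * (1 - d$x), type = "l",
                 xlab = "year", ylab = "emissions (GtC/yr)")
  invisible(x)
}

#' Historical spin-up
#'
#' Integrates the climate over `[start_year, behaviour_start_year]` from the
#' zero-deviation (pre-industrial) state, with the social component frozen
#' so that the full baseline emission rate forces the atmosphere. The
#' resulting dense trajectory provides both the initial climate state and
#' the temperature history needed for delayed projections.
#'
#' @param config a [scenario_config()].
#' @return a `socioclim_traj` over the spin-up period (with `x = 0`).
#' @export
spin_up <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  times <- seq(config$start_year, config$behaviour_start_year,
               by = config$step_out)
  clim <- config$climate
  sched <- config$schedule
  rhs <- function(t, y, parms)
    list(climate_rhs(y, emission_rate(sched, t), 0, clim))
  y0 <- stats::setNames(numeric(5), state_names())
  out <- deSolve::ode(y0, times, rhs, NULL, method = "lsoda",
                      rtol = config$rtol, atol = config$atol)
  df <- as.data.frame(out)
  names(df)[1] <- "year"
  df <- cbind(df[1], x = 0, df[-1],
              emission_rate = emission_rate(sched, df$year))
  new_trajectory(df, config)
}

# delayed-temperature lookup factory: spin-up history before the handover
# time, solver memory (dense interpolation) after it
make_lagged_T <- function(spin, t_handover, T_index) {
  histT <- traj_interp(spin, "T")
  function(s) {
    if (s <= t_handover + 1e-9) histT(s) else deSolve::lagvalue(s, T_index)
  }
}

#' Run the coupled socio-climate model
#'
#' Integrates the full delay system from `behaviour_start_year` to
#' `horizon_end`, starting from the spin-up end state with the mitigator
#' proportion reset to `x0`. The delayed temperature `T(t - tp)` is served
#' from the spin-up trajectory while `t - tp` precedes the behavioural
#' start, and from the solution's own dense history afterwards (method of
#' steps via the solver's lag interface). The returned trajectory covers
#' the whole period `[start_year, horizon_end]`, with the spin-up segment
#' prepended.
#'
#' @param config a [scenario_config()].
#' @param spin spin-up trajectory from [spin_up()]; computed on the fly if
#'   omitted.
#' @param x_fixed optional proportion: freeze the social state at this value
#'   (the fixed-behaviour null model; [fixed_behaviour_run()] is the
#'   user-facing wrapper).
#' @param projection_override optional function of time returning the
#'   projected anomaly `Tf`, bypassing the delayed extrapolation (used to
#'   study the social module against closed forms).
#' @return a `socioclim_traj` over `[start_year, horizon_end]`.
#' @export
run_coupled <- function(config, spin = NULL, x_fixed = NULL,
                        projection_override = NULL) {
  stopifnot(inherits(config, "scenario_config"))
  soc <- config$social
  clim <- config$climate
  sched <- config$schedule
  tb <- config$behaviour_start_year
  if (tb - soc$tp < config$start_year)
    stop("insufficient history: tp = ", soc$tp,
         " reaches before the simulation start", call. = FALSE)
  if (is.null(spin)) spin <- spin_up(config)
  if (max(spin$data$year) < tb || min(spin$data$year) > tb - soc$tp)
    stop("spin-up trajectory does not cover [behaviour_start - tp, ",
         "behaviour_start]", call. = FALSE)

  x_start <- if (is.null(x_fixed)) soc$x0 else clamp01(x_fixed)
  end_state <- unlist(traj_at(spin, tb, state_names())[state_names()])
  names(end_state) <- state_names()
  y0 <- c(x = x_start, end_state)
  times <- seq(tb, config$horizon_end, by = config$step_out)
  lagT <- make_lagged_T(spin, tb, T_index = 6L)
  tf_over_tp <- soc$tf / soc$tp

  rhs <- function(t, y, parms) {
    x <- clamp01(y[[1L]])
    Tnow <- y[[6L]]
    Tf <- if (is.null(projection_override)) {
      Tnow + tf_over_tp * (Tnow - lagT(t - soc$tp))
    } else projection_override(t)
    dx <- if (is.null(x_fixed)) {
      soc$kappa * x * (1 - x) *
        (-soc$beta + soc$fmax / (1 + exp(-soc$omega * (Tf - soc$Tc))) +
           soc$delta * (2 * x - 1))
    } else 0
    list(c(dx, climate_rhs(y[2:6], emission_rate(sched, t), x, clim)))
  }
  out <- deSolve::dede(y0, times, rhs, NULL, method = "lsoda",
                       rtol = config$rtol, atol = config$atol,
                       control = list(mxhist = 1e5))
  df <- as.data.frame(out)
  names(df)[1] <- "year"
  df$x <- clamp01(df$x)
  df$emission_rate <- emission_rate(sched, df$year)
  pre <- spin$data[spin$data$year < tb, ]
  if (!is.null(x_fixed)) pre$x <- 0   # spin-up convention: frozen social state
  full <- rbind(pre[names(df)], df)
  new_trajectory(full, config)
}

#' Fixed-behaviour null model
#'
#' Runs the climate with the mitigator proportion forced to stay at
#' `x_const` from the behavioural start year onwards (no imitation
#' dynamics). Used as the no-adaptation null against which the coupled
#' model is compared.
#'
#' @param config a [scenario_config()].
#' @param x_const the frozen proportion of mitigators.
#' @param spin optional precomputed spin-up.
#' @return a `socioclim_traj`.
#' @export
fixed_behaviour_run <- function(config, x_const = 0.05, spin = NULL) {
  run_coupled(config, spin = spin, x_fixed = x_const)
}

#' Peak temperature anomaly
#'
#' Maximum of the temperature anomaly over a window, refined off the stored
#' grid by maximising the spline interpolant around the best node.
#'
#' @param traj a `socioclim_traj`.
#' @param window length-2 numeric `c(from, to)` in years; defaults to the
#'   configuration's `peak_window` clipped to the trajectory range.
#' @param with_year if `TRUE` return `c(peak =, year =)`.
#' @return peak anomaly in degrees C (optionally with its year).
#' @export
peak_anomaly <- function(traj, window = NULL, with_year = FALSE) {
  stopifnot(inherits(traj, "socioclim_traj"))
  rng <- range(traj$data$year)
  if (is.null(window)) window <- traj$config$peak_window
  window <- c(max(window[1], rng[1]), min(window[2], rng[2]))
  if (window[2] <= window[1]) stop("empty peak window", call. = FALSE)
  d <- traj$data
  sel <- d$year >= window[1] & d$year <= window[2]
  if (!any(sel)) stop("empty peak window", call. = FALSE)
  yrs <- d$year[sel]; Ts <- d$T[sel]
  i <- which.max(Ts)
  f <- traj_interp(traj, "T")
  lo <- max(window[1], yrs[max(1, i - 1)])
  hi <- min(window[2], yrs[min(length(yrs), i + 1)])
  opt <- if (hi > lo) stats::optimize(f, c(lo, hi), maximum = TRUE)
         else list(objective = Ts[i], maximum = yrs[i])
  peak <- max(opt$objective, Ts[i])
  yr <- if (opt$objective >= Ts[i]) opt$maximum else yrs[i]
  if (with_year) c(peak = peak, year = yr) else peak
}
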