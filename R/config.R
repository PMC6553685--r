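#' Read a scenario configuration from YAML
#'
#' Builds a [scenario_config()] from a YAML file with optional sections
#' `social`, `climate`, `forcing`, `distributions` and `experiment`. Any
#' omitted entry falls back to the package default, so a config file only
#' needs to state what it changes.
#'
#' Section contents:
#' * `social`: any argument of [social_params()].
#' * `climate`: any argument of [climate_params()].
#' * `forcing`: `emissions_csv` (path read via
#'   [load_historical_emissions()]) or `synthetic: {end_rate, start_year,
#'   end_year, shape, jitter, seed}`, plus `eps_max` and `s`.
#' * `experiment`: `start_year`, `behaviour_start_year`, `horizon_end`,
#'   `rtol`, `atol`, `step_out`, `peak_window`, `seed`.
#' * `distributions`: a list of `{name, lower, mode, upper}` entries.
#'
#' @param path YAML file.
#' @return list with elements `config` (a [scenario_config()]) and
#'   `distributions` (named list of [param_dist()], the defaults merged
#'   with any file entries).
#' @export
read_scenario_config <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path, call. = FALSE)
  y <- yaml::read_yaml(path)
  soc <- do.call(social_params, as.list(y$social))
  cli <- do.call(climate_params, as.list(y$climate))
  frc <- y$forcing
  hist <- if (!is.null(frc$emissions_csv))
    load_historical_emissions(frc$emissions_csv)
  else do.call(synth_historical_emissions, as.list(frc$synthetic))
  sched <- make_schedule(
    hist,
    eps_max = if (is.null(frc$eps_max)) formals(make_schedule)$eps_max
              else frc$eps_max,
    s = if (is.null(frc$s)) formals(make_schedule)$s else frc$s,
    end_year = utils::tail(hist$year, 1))
  exp_args <- as.list(y$experiment)
  if (!is.null(exp_args$peak_window))
    exp_args$peak_window <- as.numeric(exp_args$peak_window)
  cfg <- do.call(scenario_config,
                 c(list(social = soc, climate = cli, schedule = sched),
                   exp_args))
  dists <- default_distributions()
  for (d in y$distributions)
    dists[[d$name]] <- param_dist(d$name, d$lower, d$mode, d$upper)
  list(config = cfg, distributions = dists)
}

#' Path of the shipped default configuration
#'
#' @return file path of the YAML config holding all package baselines and
#'   triangular bounds.
#' @export
default_config_path <- function() {
  system.file("extdata", "default_config.yaml", package = "socioclim",
              mustWork = TRUE)
}

#' Write a trajectory to CSV
#'
#' Tidy export with columns `year, x, C_at, C_veg, C_so, C_oc, T,
#' emission_rate`.
#'
#' @param traj a `socioclim_traj`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(traj, path) {
  stopifnot(inherits(traj, "socioclim_traj"))
  utils::write.csv(traj$data[c("year", traj_columns())], path,
                   row.names = FALSE)
  invisible(path)
}
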