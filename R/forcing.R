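#' Emission schedule
#'
#' Baseline anthropogenic CO2 emission rate `eps(t)` (GtC/yr): linear
#' interpolation of an annual historical series up to its final year
#' (nominally 2014), and a saturating increment thereafter,
#' `eps(t) = eps_end + (t - t_end) * eps_max / ((t - t_end) + s)`,
#' approaching but never exceeding `eps_end + eps_max`. The two branches
#' agree at the transition year, so the schedule is continuous.
#'
#' @param historical data.frame with numeric columns `year` (strictly
#'   increasing) and `emissions_gtc` (non-negative), ending at the
#'   transition year.
#' @param eps_max saturating increment of the post-transition branch
#'   (GtC/yr, >= 0).
#' @param s half-saturation constant (years, > 0): `s` years after the
#'   transition the increment reaches `eps_max / 2`.
#' @param end_year required final historical year (the transition year).
#' @return object of class `emission_schedule`.
#' @seealso [emission_rate()], [load_historical_emissions()],
#'   [synth_historical_emissions()]
#' @export
make_schedule <- function(historical, eps_max = 25, s = 50,
                          end_year = 2014) {
  if (!is.data.frame(historical) ||
      !all(c("year", "emissions_gtc") %in% names(historical)))
    stop("historical must be a data.frame with columns year, emissions_gtc",
         call. = FALSE)
  yr <- historical$year
  em <- historical$emissions_gtc
  if (any(!is.finite(yr)) || any(!is.finite(em)))
    stop("historical series contains non-finite values", call. = FALSE)
  if (any(diff(yr) <= 0))
    stop("historical years must be strictly increasing", call. = FALSE)
  if (any(em < 0))
    stop("historical emission rates must be non-negative", call. = FALSE)
  if (!is.finite(eps_max) || eps_max < 0)
    stop("eps_max must be non-negative", call. = FALSE)
  if (!is.finite(s) || s <= 0) stop("s must be positive", call. = FALSE)
  if (utils::tail(yr, 1) != end_year)
    stop("historical series must end at ", end_year, " (ends at ",
         utils::tail(yr, 1), ")", call. = FALSE)
  sched <- list(historical = data.frame(year = yr, emissions_gtc = em),
                eps_2014 = utils::tail(em, 1), eps_max = eps_max, s = s,
                end_year = end_year,
                interp = stats::approxfun(yr, em, method = "linear",
                                          rule = 1))
  class(sched) <- "emission_schedule"
  sched
}

#' Evaluate an emission schedule
#'
#' @param schedule an [make_schedule()] object.
#' @param t time in calendar years (vectorised); must not precede the first
#'   historical year.
#' @return emission rate in GtC/yr.
#' @export
emission_rate <- function(schedule, t) {
  stopifnot(inherits(schedule, "emission_schedule"))
  t0 <- schedule$historical$year[1]
  if (any(t < t0 - 1e-9))
    stop("emission schedule is undefined before ", t0, call. = FALSE)
  te <- schedule$end_year
  ifelse(t <= te,
         schedule$interp(pmin(t, te)),
         schedule$eps_2014 +
           (t - te) * schedule$eps_max / ((t - te) + schedule$s))
}

#' @export
print.emission_schedule <- function(x, ...) {
  h <- x$historical
  cat(sprintf(
    "Emission schedule: historical %d-%d (%d points), eps(%d) = %.3g GtC/yr\n",
    h$year[1], x$end_year, nrow(h), x$end_year, x$eps_2014))
  cat(sprintf("  post-%d: saturating, eps_max = %g GtC/yr, s = %g yr (ceiling %.3g)\n",
              x$end_year, x$eps_max, x$s, x$eps_2014 + x$eps_max))
  invisible(x)
}

#' Read an annual anthropogenic emission series
#'
#' Accepts either a single-series CSV with header `year,emissions_gtc`, or a
#' component file with header `year,fossil_gtc,landuse_gtc` in which the two
#' sources are summed. A land-use column that ends before the fossil record
#' (blank/NA cells) is extended by linear extrapolation of a least-squares
#' fit to its last `extrap_window` available years before summation.
#'
#' @param path CSV file path.
#' @param extrap_window number of trailing years used for the land-use
#'   extrapolation fit.
#' @return data.frame with columns `year`, `emissions_gtc`, years strictly
#'   increasing.
#' @export
load_historical_emissions <- function(path, extrap_window = 20) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  has_single <- all(c("year", "emissions_gtc") %in% names(df))
  has_split <- all(c("year", "fossil_gtc", "landuse_gtc") %in% names(df))
  if (!has_single && !has_split)
    stop("expected columns year,emissions_gtc or year,fossil_gtc,landuse_gtc",
         call. = FALSE)
  check_col <- function(col, nm, allow_na = FALSE) {
    v <- suppressWarnings(as.numeric(col))
    bad <- which(is.na(v) & !(allow_na & (is.na(col) | col == "")))
    if (length(bad))
      stop("non-numeric ", nm, " in row(s) ",
           paste(bad + 1L, collapse = ", "), " of the CSV", call. = FALSE)
    v
  }
  year <- check_col(df$year, "year")
  dup <- year[duplicated(year)]
  if (length(dup))
    stop("duplicated year(s) in emission series: ",
         paste(unique(dup), collapse = ", "), call. = FALSE)
  o <- order(year)
  if (has_single) {
    em <- check_col(df$emissions_gtc, "emissions_gtc")
    out <- data.frame(year = year[o], emissions_gtc = em[o])
  } else {
    fossil <- check_col(df$fossil_gtc, "fossil_gtc")
    landuse <- check_col(df$landuse_gtc, "landuse_gtc", allow_na = TRUE)
    year <- year[o]; fossil <- fossil[o]; landuse <- landuse[o]
    if (any(is.na(fossil)))
      stop("fossil_gtc column must cover every year", call. = FALSE)
    if (any(is.na(landuse))) {
      avail <- which(!is.na(landuse))
      if (length(avail) < 2)
        stop("too few land-use values to extrapolate", call. = FALSE)
      idx <- utils::tail(avail, extrap_window)
      fit <- stats::lm(lu ~ yr,
                       data = data.frame(yr = year[idx], lu = landuse[idx]))
      miss <- which(is.na(landuse))
      landuse[miss] <- pmax(0, stats::predict(
        fit, newdata = data.frame(yr = year[miss])))
    }
    out <- data.frame(year = year, emissions_gtc = fossil + landuse)
  }
  if (any(out$emissions_gtc < 0))
    stop("negative emission rate in series", call. = FALSE)
  out
}

#' Synthesise a plausible historical emission series
#'
#' Deterministic fixture generator standing in for the historical record: a
#' smooth, monotone non-decreasing annual series growing from near zero to
#' `end_rate` at `end_year`. The deterministic backbone is a power law in
#' scaled time, `end_rate * ((t - start) / (end - start))^shape`; a seeded
#' low-order Fourier perturbation of relative size `jitter` adds smooth
#' decade-scale structure, after which the series is made monotone
#' (running maximum) and re-pinned to the endpoint.
#'
#' @param end_rate emission rate at `end_year` (GtC/yr).
#' @param start_year,end_year series range (annual resolution).
#' @param shape power-law exponent of the growth backbone; 3 gives a
#'   cumulative total close to the historical fossil + land-use record when
#'   `end_rate` is the observed 2014 rate.
#' @param jitter relative amplitude of the smooth seeded perturbation.
#' @param seed integer seed; the same seed always yields the same series.
#' @return data.frame with columns `year`, `emissions_gtc`.
#' @export
synth_historical_emissions <- function(end_rate = 10.7, start_year = 1800,
                                       end_year = 2014, shape = 3,
                                       jitter = 0.02, seed = 1L) {
  if (end_year <= start_year) stop("end_year must exceed start_year",
                                   call. = FALSE)
  if (end_rate <= 0) stop("end_rate must be positive", call. = FALSE)
  year <- seq(start_year, end_year)
  u <- (year - start_year) / (end_year - start_year)
  base <- end_rate * u^shape
  if (jitter > 0) {
    rng <- local_rng(seed)
    k <- 1:4
    amp <- rng$norm(4) * jitter / sqrt(k)
    pert <- as.vector(sin(outer(u, k * pi)) %*% amp)
    base <- base * exp(pert)
  }
  em <- cummax(base)                       # enforce monotone growth
  em <- em * (end_rate / em[length(em)])   # re-pin the endpoint
  data.frame(year = year, emissions_gtc = em)
}

# small self-contained RNG wrapper: isolates seeded draws from the global
# RNG stream
local_rng <- function(seed) {
  env <- new.env()
  assign("state", NULL, envir = env)
  run <- function(f) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                        globalenv()) else NULL
    on.exit({
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, envir = globalenv())
    })
    st <- get("state", envir = env)
    if (is.null(st)) set.seed(seed) else assign(".Random.seed", st,
                                                envir = globalenv())
    out <- f()
    assign("state", get(".Random.seed", globalenv()), envir = env)
    out
  }
  list(norm = function(n) run(function() stats::rnorm(n)),
       unif = function(n) run(function() stats::runif(n)),
       int = function(n, max) run(function() sample.int(max, n)))
}

#' Stylised future emission pathways
#'
#' Simple synthetic emission scenarios shaped like the four Representative
#' Concentration Pathway (RCP) families, for qualitative validation of the
#' climate core (end-of-century anomaly ordering). These are coarse
#' hand-shaped pathways built in code, not the published RCP tables.
#'
#' @param name one of `"rcp26"`, `"rcp45"`, `"rcp60"`, `"rcp85"`.
#' @param historical historical series to prepend (defaults to the
#'   synthetic fixture ending in 2014).
#' @return data.frame with columns `year`, `emissions_gtc`, 1800-2100.
#' @export
stylised_rcp_emissions <- function(name = c("rcp26", "rcp45", "rcp60",
                                            "rcp85"),
                                   historical = synth_historical_emissions()) {
  name <- match.arg(name)
  nodes <- switch(name,
    rcp26 = data.frame(year = c(2020, 2030, 2050, 2080, 2100),
                       emissions_gtc = c(10.8, 9.5, 4.5, 1.0, 0.1)),
    rcp45 = data.frame(year = c(2020, 2040, 2060, 2080, 2100),
                       emissions_gtc = c(11.0, 11.5, 9.0, 5.5, 4.2)),
    rcp60 = data.frame(year = c(2020, 2040, 2060, 2080, 2100),
                       emissions_gtc = c(10.9, 12.0, 14.0, 15.5, 13.8)),
    rcp85 = data.frame(year = c(2020, 2040, 2060, 2080, 2100),
                       emissions_gtc = c(11.5, 15.5, 20.0, 25.0, 28.0)))
  yrs <- seq(2015, 2100)
  fut <- stats::approx(c(2014, nodes$year),
                       c(utils::tail(historical$emissions_gtc, 1),
                         nodes$emissions_gtc), xout = yrs)$y
  rbind(historical, data.frame(year = yrs, emissions_gtc = fut))
}
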