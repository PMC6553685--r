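#' Perceived cost of climate change
#'
#' Sigmoidal utility penalty associated with a (projected) temperature
#' anomaly: `f(T) = fmax / (1 + exp(-omega * (T - Tc)))`. The curve rises
#' from 0 towards the ceiling `fmax`, with midpoint `Tc` and steepness
#' `omega`.
#'
#' @param T temperature anomaly in degrees C (vectorised).
#' @param params a [social_params()] object.
#' @return perceived cost in utility units, strictly inside `(0, fmax)`.
#' @examples
#' p <- social_params(fmax = 5, omega = 3, Tc = 2.5)
#' perceived_cost(2.5, p)  # fmax / 2
#' @export
perceived_cost <- function(T, params) {
  validate_social_params(params)
  if (!is.numeric(T) || any(!is.finite(T)))
    stop("temperature anomaly must be finite numeric", call. = FALSE)
  params$fmax / (1 + exp(-params$omega * (T - params$Tc)))
}

# unscaled cost curve ftilde(T) = ftilde_max / (1 + exp(-omega (T - Tc)));
# requires the raw parameter form
perceived_cost_raw <- function(T, params) {
  if (!has_raw_form(params))
    stop("raw-form parameters (alpha, gamma, c, ftilde_max) required",
         call. = FALSE)
  params$ftilde_max / (1 + exp(-params$omega * (T - params$Tc)))
}

#' Strategy utilities
#'
#' Utility of being a mitigator, `e_M = -alpha + c * ftilde(Tf) + delta * x`,
#' and of being a non-mitigator, `e_N = -gamma - ftilde(Tf) + delta * (1 - x)`.
#' Mitigators pay the adoption cost `alpha` but gain a share `c` of the
#' perceived climate cost as incentive; non-mitigators pay the levy `gamma`
#' and bear the climate cost itself. Each strategy gains the norm bonus
#' `delta` weighted by its own prevalence. Requires raw-form parameters.
#'
#' @param x proportion of mitigators in `[0, 1]`.
#' @param Tf projected temperature anomaly (degrees C).
#' @param params a [social_params()] object carrying the raw form.
#' @return utility (finite scalar; vectorised over `x` and `Tf`).
#' @export
mitigator_utility <- function(x, Tf, params) {
  check_proportion(x)
  ft <- perceived_cost_raw(Tf, params)
  -params$alpha + params$c * ft + params$delta * x
}

#' @rdname mitigator_utility
#' @export
nonmitigator_utility <- function(x, Tf, params) {
  check_proportion(x)
  ft <- perceived_cost_raw(Tf, params)
  -params$gamma - ft + params$delta * (1 - x)
}

check_proportion <- function(x) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x < 0 | x > 1))
    stop("proportion must lie in [0, 1]", call. = FALSE)
  invisible(x)
}

#' Imitation switching rates
#'
#' Total population switching rates between the two strategies:
#' `r_{N->M} = kappa * x * (1 - x) * max(eM - eN, 0)` and symmetrically for
#' `r_{M->N}`. At most one of the pair is nonzero, and both vanish at the
#' boundaries `x = 0, 1`.
#'
#' @param x proportion of mitigators.
#' @param eM,eN strategy utilities.
#' @param kappa social learning rate (per year).
#' @return named numeric vector `c(n_to_m = , m_to_n = )` of rates (per year).
#' @export
switch_rates <- function(x, eM, eN, kappa) {
  check_proportion(x)
  base <- kappa * x * (1 - x)
  c(n_to_m = base * max(eM - eN, 0),
    m_to_n = base * max(eN - eM, 0))
}

#' Projected temperature anomaly
#'
#' Linear extrapolation of the recent temperature trend: the slope over the
#' last `tp` years is carried `tf` years forward,
#' `Tf(t) = T(t) + (tf / tp) * (T(t) - T(t - tp))`. With `tf = 0` the
#' projection is the current anomaly.
#'
#' @param history a function of time returning the temperature anomaly; must
#'   be evaluable on `[t - tp, t]`.
#' @param t time (calendar year) at which the projection is formed.
#' @param params a [social_params()] object (`tp`, `tf` are used).
#' @param t_min optional earliest time covered by `history`; supplying it
#'   enables an explicit insufficient-history error.
#' @return projected anomaly in degrees C.
#' @export
projected_temperature <- function(history, t, params, t_min = NULL) {
  validate_social_params(params)
  if (!is.null(t_min) && t - params$tp < t_min - 1e-9)
    stop("insufficient history: need temperature back to ",
         t - params$tp, " but history starts at ", t_min, call. = FALSE)
  Tnow <- history(t)
  Tpast <- history(t - params$tp)
  if (!is.finite(Tnow) || !is.finite(Tpast))
    stop("insufficient history: temperature not evaluable over [t - tp, t]",
         call. = FALSE)
  Tnow + (params$tf / params$tp) * (Tnow - Tpast)
}

#' Replicator right-hand side for the proportion of mitigators
#'
#' Net rate of change of the mitigator fraction in reduced form,
#' `dx/dt = kappa * x * (1 - x) * (-beta + f(Tf) + delta * (2 x - 1))`,
#' which equals the difference of the two switching rates built from the raw
#' utilities. `x` is clamped to `[0, 1]` before evaluation so that the
#' boundary equilibria are exact.
#'
#' @param x proportion of mitigators.
#' @param Tf projected temperature anomaly (degrees C).
#' @param params a [social_params()] object.
#' @return `dx/dt` (per year).
#' @export
social_rhs <- function(x, Tf, params) {
  xc <- clamp01(x)
  params$kappa * xc * (1 - xc) *
    (-params$beta + perceived_cost(Tf, params) +
       params$delta * (2 * xc - 1))
}

# snap to the invariant boundaries within tol, then hard-clip
clamp01 <- function(x, tol = 1e-12) {
  x[abs(x) < tol] <- 0
  x[abs(x - 1) < tol] <- 1
  pmin(pmax(x, 0), 1)
}

#' Integrate the social dynamics against a prescribed projection
#'
#' Solves `dx/dt = social_rhs(x, Tf(t), params)` with `Tf` supplied as a
#' function of time, decoupled from the climate. Mainly useful for studying
#' the behaviour module in isolation (e.g. against the logistic closed form
#' obtained when `delta = 0` and the payoff gap is constant).
#'
#' @param params a [social_params()] object.
#' @param Tf_fun function of time returning the projected anomaly.
#' @param times output times (years).
#' @param x0 initial proportion (defaults to `params$x0`).
#' @param rtol,atol solver tolerances.
#' @return data.frame with columns `time` and `x`.
#' @export
simulate_social <- function(params, Tf_fun, times, x0 = params$x0,
                            rtol = 1e-8, atol = 1e-10) {
  validate_social_params(params)
  check_proportion(x0)
  rhs <- function(t, y, parms) {
    list(social_rhs(y[[1]], Tf_fun(t), params))
  }
  out <- deSolve::ode(c(x = x0), times, rhs, NULL, method = "lsoda",
                      rtol = rtol, atol = atol)
  data.frame(time = out[, "time"], x = clamp01(out[, "x"]))
}
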