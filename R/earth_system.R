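#' Climate state vector
#'
#' State of the reduced Earth system, as deviations from pre-industrial
#' values: atmospheric (`C_at`), vegetation (`C_veg`), soil (`C_so`) and
#' ocean (`C_oc`) carbon in GtC, and the surface temperature anomaly `T` in
#' degrees C. The pre-industrial state is the all-zeros vector.
#'
#' @param C_at,C_veg,C_so,C_oc carbon pool deviations (GtC).
#' @param T temperature anomaly (degrees C).
#' @return named numeric vector of class `climate_state`.
#' @export
climate_state <- function(C_at = 0, C_veg = 0, C_so = 0, C_oc = 0, T = 0) {
  s <- c(C_at = C_at, C_veg = C_veg, C_so = C_so, C_oc = C_oc, T = T)
  if (any(!is.finite(s))) stop("climate state must be finite", call. = FALSE)
  class(s) <- "climate_state"
  s
}

state_names <- function() c("C_at", "C_veg", "C_so", "C_oc", "T")

# atmospheric CO2 mixing ratio (ppm) for a given state
co2_ppm <- function(state, params) {
  (params$C_at0 + state[["C_at"]]) / params$gtc_per_ppm
}

# Michaelis-Menten CO2 dependence of photosynthesis
fertilisation <- function(ca, params) {
  pmax(ca - params$k_c, 0) / (params$k_M + pmax(ca - params$k_c, 0))
}

#' Carbon-cycle fluxes
#'
#' The four carbon exchange processes of the reduced model, each evaluated
#' at a deviation-form [climate_state()] and returning a flux in GtC/yr:
#'
#' * `photosynthesis_rate()`: gross uptake
#'   `P = P0 g(c_a)/g(c_a0) (1 + a_P T)` where
#'   `g(c) = (c - k_c)/(k_M + c - k_c)` is Michaelis-Menten CO2
#'   fertilisation above the compensation point `k_c`. Uptake is treated as
#'   light/area-limited rather than proportional to standing biomass, so the
#'   vegetation pool relaxes to a finite equilibrium under fertilisation.
#' * `vegetation_respiration()`: `Rveg = Rveg0 (C_veg/C_veg0) q10_veg^(T/10)`.
#' * `soil_respiration()`: `Rso = Rso0 (C_so/C_so0) q10_soil^(T/10)`.
#' * `litter_fall()`: internal vegetation-to-soil transfer
#'   `L = L0 (C_veg/C_veg0)` (does not touch the atmosphere).
#' * `ocean_uptake()`: net air-to-sea flux
#'   `Foc = (k_ao dC_at - k_oa dC_oc)(1 - solub_T T)` -- linear exchange on
#'   the deviations, damped by warming (reduced solubility); may be of
#'   either sign.
#'
#' At the pre-industrial (zero-deviation) state the land fluxes equal their
#' calibrated reference values and the ocean flux is zero, so the unforced
#' system is stationary there.
#'
#' @param state a [climate_state()] (deviations from pre-industrial).
#' @param params a [climate_params()] object.
#' @return flux in GtC/yr.
#' @export
photosynthesis_rate <- function(state, params) {
  ca <- co2_ppm(state, params)
  tempfac <- max(0, 1 + params$a_P * state[["T"]])
  params$gpp_preind *
    fertilisation(ca, params) / fertilisation(params$co2_preind, params) *
    tempfac
}

#' @rdname photosynthesis_rate
#' @export
vegetation_respiration <- function(state, params) {
  params$rveg_preind * ((params$C_veg0 + state[["C_veg"]]) / params$C_veg0) *
    params$q10_veg^(state[["T"]] / 10)
}

#' @rdname photosynthesis_rate
#' @export
soil_respiration <- function(state, params) {
  params$rso_preind * ((params$C_so0 + state[["C_so"]]) / params$C_so0) *
    params$q10_soil^(state[["T"]] / 10)
}

#' @rdname photosynthesis_rate
#' @export
litter_fall <- function(state, params) {
  params$litter_preind * ((params$C_veg0 + state[["C_veg"]]) / params$C_veg0)
}

#' @rdname photosynthesis_rate
#' @export
ocean_uptake <- function(state, params) {
  (params$k_ao * state[["C_at"]] - params$k_oa * state[["C_oc"]]) *
    max(0, 1 - params$solub_T * state[["T"]])
}

#' Net downward radiative flux at the surface
#'
#' `F_d = S (1 - albedo) / 4 + G0 + lambda_co2 log(c_a / c_a0)`: absorbed
#' shortwave plus greenhouse back-radiation whose CO2-dependent part grows
#' logarithmically with the atmospheric mixing ratio. `G0` is fixed at
#' construction so that `F_d` balances `sigma T_preind^4` in the
#' pre-industrial state at the reference solar flux. Increasing either
#' `C_at` or `solar_flux` increases `F_d`.
#'
#' @inheritParams photosynthesis_rate
#' @return flux in W m^-2.
#' @export
downward_flux <- function(state, params) {
  ca <- co2_ppm(state, params)
  params$solar_flux * (1 - params$albedo) / 4 + params$G0 +
    params$lambda_co2 * log(ca / params$co2_preind)
}

#' Carbon-cycle right-hand side
#'
#' Pool derivatives in GtC/yr. The atmospheric balance is
#' `dC_at/dt = eps (1 - x) - P + Rveg + Rso - Foc`: the anthropogenic
#' emission rate `eps` enters scaled by the proportion `1 - x` of
#' non-mitigators, so full mitigation (`x = 1`) shuts off the anthropogenic
#' source exactly. Litter fall transfers carbon from vegetation to soil and
#' ocean uptake moves it into the explicit ocean pool, so total modelled
#' carbon changes only through `eps (1 - x)`.
#'
#' @inheritParams photosynthesis_rate
#' @param emission_rate baseline anthropogenic emission rate (GtC/yr, >= 0).
#' @param x proportion of mitigators in `[0, 1]`.
#' @return named numeric vector of derivatives for `C_at`, `C_veg`, `C_so`,
#'   `C_oc` (GtC/yr).
#' @export
carbon_rhs <- function(state, emission_rate, x, params) {
  if (!is.finite(emission_rate) || emission_rate < 0)
    stop("emission_rate must be a non-negative finite scalar", call. = FALSE)
  check_proportion(x)
  P <- photosynthesis_rate(state, params)
  Rv <- vegetation_respiration(state, params)
  Rs <- soil_respiration(state, params)
  L <- litter_fall(state, params)
  Foc <- ocean_uptake(state, params)
  c(C_at = emission_rate * (1 - x) - P + Rv + Rs - Foc,
    C_veg = P - Rv - L,
    C_so = L - Rs,
    C_oc = Foc)
}

#' Energy-balance right-hand side
#'
#' `dT/dt = (F_d - sigma T_abs^4) / c_eff`, converted to degrees C per
#' year, with `T_abs = T_preind + T`. Zero exactly at radiative balance;
#' the sign of `dT/dt` is the sign of the flux imbalance.
#'
#' @inheritParams photosynthesis_rate
#' @return temperature tendency (degrees C per year).
#' @export
temperature_rhs <- function(state, params) {
  Tabs <- params$T_preind + state[["T"]]
  (downward_flux(state, params) - params$sigma_SB * Tabs^4) *
    params$seconds_per_year / params$heat_capacity
}

# full climate tendency vector (GtC/yr and C/yr) used by the simulator
climate_rhs <- function(state, emission_rate, x, params) {
  c(carbon_rhs(state, emission_rate, x, params),
    T = temperature_rhs(state, params))
}
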