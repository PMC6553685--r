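#' Reduced Earth-system parameters
#'
#' Constants of the reduced Earth-system model: a four-pool carbon cycle
#' (atmosphere, vegetation, soil, ocean) and a zero-dimensional surface
#' energy balance. All state variables are carried as *deviations* from
#' pre-industrial values; the reference (pre-industrial) pool sizes and
#' fluxes held here calibrate the model so that the zero-deviation state is
#' an exact equilibrium of the unforced system.
#'
#' The energy balance is written on the absolute surface temperature
#' `T_abs = T_preind + T`: `c_eff dT_abs/dt = F_d - sigma T_abs^4`, with the
#' Earth's surface area and thermal capacity folded into the single
#' effective areal heat capacity `heat_capacity` (J m^-2 K^-1). The downward
#' flux `F_d` is absorbed shortwave plus a greenhouse back-radiation term
#' that grows logarithmically with atmospheric CO2; the constant part of the
#' back-radiation is derived at construction so that the pre-industrial
#' state is a radiative equilibrium at the *reference* solar flux
#' (`solar_flux_ref`). Perturbing `solar_flux` away from the reference
#' therefore forces the climate, as it should.
#'
#' @param solar_flux incident solar constant actually used in the downward
#'   flux (W m^-2).
#' @param solar_flux_ref reference solar constant at which the
#'   pre-industrial state is in equilibrium (W m^-2). Leave at default
#'   unless re-calibrating.
#' @param albedo planetary albedo (dimensionless).
#' @param climate_sens equilibrium warming for a doubling of CO2 (degrees
#'   C); sets the strength of the log-CO2 greenhouse term (all fast
#'   feedbacks folded in).
#' @param heat_capacity effective areal heat capacity of the surface
#'   (J m^-2 K^-1); a_E and the thermal capacity of the source formulation
#'   are folded into this single constant.
#' @param T_preind pre-industrial absolute surface temperature (K).
#' @param co2_preind pre-industrial atmospheric CO2 (ppm).
#' @param gtc_per_ppm conversion between atmospheric carbon mass and mixing
#'   ratio (GtC per ppm).
#' @param C_veg0,C_so0,C_oc0 pre-industrial vegetation, soil and (effective)
#'   ocean carbon pools (GtC).
#' @param gpp_preind pre-industrial gross photosynthetic uptake (GtC/yr).
#' @param rveg_preind pre-industrial vegetation (autotrophic) respiration
#'   (GtC/yr); litter fall and soil respiration balance the remainder.
#' @param k_c CO2 compensation point of photosynthesis (ppm).
#' @param k_M half-saturation constant of CO2 fertilisation (ppm).
#' @param a_P linear temperature coefficient of photosynthesis (per degree
#'   C of anomaly).
#' @param q10_veg,q10_soil Q10 temperature factors of vegetation and soil
#'   respiration.
#' @param k_ao air-to-ocean exchange coefficient on the atmospheric carbon
#'   deviation (per yr).
#' @param k_oa ocean back-flux coefficient on the ocean carbon deviation
#'   (per yr); `k_ao / k_oa` sets the long-run ocean:atmosphere partition of
#'   excess carbon.
#' @param solub_T fractional reduction of net ocean uptake per degree of
#'   warming (per degree C; solubility effect).
#'
#' @return An object of class `climate_params` with derived constants
#'   `C_at0` (pre-industrial atmospheric carbon, GtC), `litter_preind`,
#'   `rso_preind`, `lambda_co2` (W m^-2 per e-fold of CO2) and `G0`
#'   (constant back-radiation, W m^-2) attached.
#' @export
climate_params <- function(solar_flux = 1368, solar_flux_ref = 1368,
                           albedo = 0.3, climate_sens = 3.2,
                           heat_capacity = 4e9, T_preind = 288,
                           co2_preind = 280, gtc_per_ppm = 2.124,
                           C_veg0 = 550, C_so0 = 1500, C_oc0 = 1000,
                           gpp_preind = 120, rveg_preind = 60,
                           k_c = 29, k_M = 120, a_P = 0.01,
                           q10_veg = 2, q10_soil = 2,
                           k_ao = 0.035, k_oa = 0.012, solub_T = 0.015) {
  p <- list(solar_flux = solar_flux, solar_flux_ref = solar_flux_ref,
            albedo = albedo, climate_sens = climate_sens,
            heat_capacity = heat_capacity, T_preind = T_preind,
            co2_preind = co2_preind, gtc_per_ppm = gtc_per_ppm,
            C_veg0 = C_veg0, C_so0 = C_so0, C_oc0 = C_oc0,
            gpp_preind = gpp_preind, rveg_preind = rveg_preind,
            k_c = k_c, k_M = k_M, a_P = a_P,
            q10_veg = q10_veg, q10_soil = q10_soil,
            k_ao = k_ao, k_oa = k_oa, solub_T = solub_T)
  class(p) <- "climate_params"
  validate_climate_params(p)
  finalize_climate_params(p)
}

# derived constants; recomputed after any override
finalize_climate_params <- function(p) {
  p$sigma_SB <- 5.670374419e-8          # W m^-2 K^-4
  p$seconds_per_year <- 3.15576e7
  p$C_at0 <- p$co2_preind * p$gtc_per_ppm
  p$litter_preind <- p$gpp_preind - p$rveg_preind
  p$rso_preind <- p$litter_preind
  # greenhouse strength: climate_sens K per doubling against the linearised
  # surface Planck response 4 sigma T0^3
  p$lambda_co2 <- p$climate_sens * 4 * p$sigma_SB * p$T_preind^3 / log(2)
  # constant back-radiation closing the pre-industrial budget at the
  # reference solar flux
  p$G0 <- p$sigma_SB * p$T_preind^4 -
    p$solar_flux_ref * (1 - p$albedo) / 4
  p
}

validate_climate_params <- function(p) {
  stopifnot(inherits(p, "climate_params"))
  pos <- c("solar_flux", "solar_flux_ref", "climate_sens", "heat_capacity",
           "T_preind", "co2_preind", "gtc_per_ppm", "C_veg0", "C_so0",
           "C_oc0", "gpp_preind", "rveg_preind", "k_M", "q10_veg",
           "q10_soil", "k_ao", "k_oa")
  for (nm in pos) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop("climate parameter '", nm, "' must be a positive finite scalar",
           call. = FALSE)
  }
  if (p$albedo < 0 || p$albedo >= 1) stop("albedo must be in [0, 1)",
                                          call. = FALSE)
  if (p$rveg_preind >= p$gpp_preind)
    stop("rveg_preind must be smaller than gpp_preind", call. = FALSE)
  if (p$k_c < 0 || p$k_c >= p$co2_preind)
    stop("k_c must lie in [0, co2_preind)", call. = FALSE)
  invisible(p)
}

#' @export
print.climate_params <- function(x, ...) {
  cat("Reduced Earth-system parameters\n")
  cat(sprintf("  solar flux %g W/m2 (ref %g), albedo %g, 2xCO2 sensitivity %g C\n",
              x$solar_flux, x$solar_flux_ref, x$albedo, x$climate_sens))
  cat(sprintf("  pre-industrial: %g ppm CO2, T = %g K, pools veg %g / soil %g / ocean %g GtC\n",
              x$co2_preind, x$T_preind, x$C_veg0, x$C_so0, x$C_oc0))
  cat(sprintf("  carbon fluxes at reference: GPP %g, Rveg %g, litter %g, Rsoil %g GtC/yr\n",
              x$gpp_preind, x$rveg_preind, x$litter_preind, x$rso_preind))
  invisible(x)
}

modify_climate_params <- function(p, overrides) {
  derived <- c("sigma_SB", "seconds_per_year", "C_at0", "litter_preind",
               "rso_preind", "lambda_co2", "G0")
  for (nm in names(overrides)) {
    if (!nm %in% names(p) || nm %in% derived)
      stop("unknown climate parameter: '", nm, "'", call. = FALSE)
    p[[nm]] <- overrides[[nm]]
  }
  validate_climate_params(p)
  finalize_climate_params(p)
}
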