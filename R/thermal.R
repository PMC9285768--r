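#' Temperature and body-mass scaling of vital rates
#'
#' All consumer rates in the food-web models depend on dry body mass M (ug)
#' and ambient temperature T (degrees C). Whole-organism rates scale as
#' M^0.7, so mass-specific rates (the model tracks biomass) carry the
#' exponent 0.7 - 1. Metabolism increases exponentially with temperature
#' (Arrhenius, activation energy 0.56 eV); maximum ingestion is a unimodal
#' (Gaussian) function of temperature whose optimum can decline with body
#' mass; resource carrying capacities decline exponentially with warming,
#' optionally at resource-specific rates. These three optional couplings are
#' the "size-temperature interactions" toggled by the parameter flags.
#'
#' @name thermal
NULL

#' Arrhenius temperature scaling factor
#'
#' Multiplier \code{exp((E/k) * (1/T_ref_K - 1/T_K))}, equal to 1 at the
#' reference temperature and strictly increasing in temperature for positive
#' activation energy. Temperatures are given in degrees Celsius and
#' converted to Kelvin internally.
#'
#' @param T temperature, degrees C (finite, within -20..60).
#' @param E activation energy, eV (non-negative).
#' @param T_ref reference temperature, degrees C.
#' @param k Boltzmann constant, eV per Kelvin.
#' @return dimensionless positive multiplier.
#' @examples
#' arrhenius_factor(30, 0.56, 20) # about 2.08
#' @export
arrhenius_factor <- function(T, E, T_ref = 20, k = 8.617e-5) {
  if (!all(is.finite(T))) stop("temperature must be finite")
  if (!all(is.finite(T_ref))) stop("reference temperature must be finite")
  if (any(T < -20 | T > 60)) stop("temperature outside supported range [-20, 60] C")
  if (any(E < 0)) stop("activation energy must be non-negative")
  exp((E / k) * (1 / (T_ref + 273.15) - 1 / (T + 273.15)))
}

#' Temperature optimum of maximum ingestion for a given body mass
#'
#' With the ingestion-optimum interaction on, the optimum declines linearly
#' with log10 body mass: \code{topt_ref - topt_slope * log10(M)}, giving
#' 24, 20 and 16 C at 0.1, 1 and 10 ug with the defaults. With the
#' interaction off every consumer has the same optimum \code{topt_ref}.
#'
#' @param M dry body mass, ug (> 0).
#' @param params a parameter set from [default_parameters()].
#' @return optimum temperature, degrees C.
#' @export
topt_for_mass <- function(M, params) {
  if (any(!is.finite(M) | M <= 0)) stop("body mass must be positive and finite")
  if (isTRUE(params$topt_interaction)) {
    params$topt_ref - params$topt_slope * log10(M)
  } else {
    rep(params$topt_ref, length(M))
  }
}

#' Mass-specific maximum ingestion rate
#'
#' \code{imax_coeff * M^(mass_exponent - 1) * u(T - T_opt(M))} where u is a
#' Gaussian kernel with scale \code{thermal_width}, so the rate peaks exactly
#' at the mass-dependent optimum and falls off symmetrically.
#'
#' @inheritParams topt_for_mass
#' @param T temperature, degrees C.
#' @return mass-specific rate, per day.
#' @export
max_ingestion_rate <- function(M, T, params) {
  if (any(!is.finite(M) | M <= 0)) stop("body mass must be positive and finite")
  if (any(!is.finite(T))) stop("temperature must be finite")
  topt <- topt_for_mass(M, params)
  u <- exp(-(T - topt)^2 / (2 * params$thermal_width^2))
  params$imax_coeff * M^(params$mass_exponent - 1) * u
}

#' Mass-specific metabolic rate
#'
#' \code{metab_coeff * M^(e(T) - 1) * arrhenius_factor(T)}, with allometric
#' exponent \code{e(T) = mass_exponent + metab_exponent_slope * (T - T_ref)}.
#' The slope is zero unless the metabolic-exponent interaction is on; when
#' positive it makes metabolism of large consumers rise faster with warming
#' than that of small consumers.
#'
#' @inheritParams max_ingestion_rate
#' @return mass-specific rate, per day.
#' @export
metabolic_rate <- function(M, T, params) {
  if (any(!is.finite(M) | M <= 0)) stop("body mass must be positive and finite")
  slope <- if (isTRUE(params$metab_exponent_interaction)) params$metab_exponent_slope else 0
  e_T <- params$mass_exponent + slope * (T - params$T_ref)
  params$metab_coeff * M^(e_T - 1) *
    arrhenius_factor(T, params$activation_energy, params$T_ref, params$boltzmann_k)
}

#' Temperature-dependent resource carrying capacity
#'
#' Maximum (consumer-free equilibrium) biomass density of a resource,
#' \code{rmax_ref * exp(-c_j * (T - T_ref))}. Both resources share
#' \code{rmax_ref}, so the two curves cross exactly at the reference
#' temperature (20 C). With the resource interaction on, the large resource
#' declines more steeply with warming than the small one
#' (\code{rmax_decline_L > rmax_decline_S}); with it off the two resources
#' are identical.
#'
#' @param resource \code{"RS"} (small) or \code{"RL"} (large).
#' @inheritParams max_ingestion_rate
#' @return biomass density (same units as the state vector).
#' @export
resource_carrying_capacity <- function(resource, T, params) {
  resource <- match.arg(resource, c("RS", "RL"))
  if (any(!is.finite(T))) stop("temperature must be finite")
  cj <- if (resource == "RS") params$rmax_decline_S else params$rmax_decline_L
  params$rmax_ref * exp(-cj * (T - params$T_ref))
}
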