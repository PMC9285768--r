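#' Default model parameter set
#'
#' Returns the full parameter set of the food-web models: allometric and
#' thermal coefficients, resource supply, functional-response constants and
#' background mortality, together with the three size-temperature
#' interaction flags. Values are either read verbatim from a user-supplied
#' transcription file (provenance \code{"transcribed"}) or, by default, are
#' the package's calibrated plankton parameterization (provenance
#' \code{"calibrated-default"}). The calibrated defaults are pinned to the
#' model's published anchors: ingestion optima 24/20/16 C at 0.1/1/10 ug
#' when the optimum interaction is on (all 20 C when off), activation energy
#' 0.56 eV, allometric exponent 0.7, resource carrying capacities crossing
#' at 20 C, and a thermal width of the ingestion kernel solved so that the
#' 1-ug consumer's fundamental thermal niche on its own resource closes at
#' 41.2 C.
#'
#' @param topt_interaction size-dependent ingestion optimum on/off.
#' @param rmax_interaction resource-specific carrying-capacity decline on/off.
#' @param metab_exponent_interaction temperature-dependent metabolic
#'   allometric exponent on/off.
#' @param transcription optional path to a YAML file with a verbatim
#'   parameter transcription; keys must match parameter names.
#' @return a list of class \code{"thermo_params"}; the \code{"provenance"}
#'   attribute tags every value.
#' @export
default_parameters <- function(topt_interaction = TRUE,
                               rmax_interaction = TRUE,
                               metab_exponent_interaction = FALSE,
                               transcription = NULL) {
  p <- list(
    mass_exponent = 0.7,          # whole-organism allometric exponent
    activation_energy = 0.56,     # eV, magnitude of metabolic scaling
    boltzmann_k = 8.617e-5,       # eV / K
    T_ref = 20,                   # C
    topt_ref = 20,                # C, ingestion optimum at 1 ug
    topt_slope = 4,               # C per decade of mass -> 24/20/16 C
    thermal_width = 16.06996442,  # C, calibrated: CS hot limit at 41.2 C
    imax_coeff = 1.5,             # / d, max ingestion at 1 ug and T_opt
    metab_coeff = 0.05,           # / d, metabolism at 1 ug and 20 C
    metab_exponent_slope = if (metab_exponent_interaction) 0.01 else 0,  # / C
    rmax_ref = 100,               # biomass density at 20 C, both resources
    rmax_decline_S = 0.01,        # / C
    rmax_decline_L = if (rmax_interaction) 0.04 else 0.01,  # / C
    delta = 0.1,                  # / d, resource supply rate
    H = 50,                       # half-saturation biomass density
    beta = 0.6,                   # conversion efficiency
    mu = 0.01,                    # / d, background mortality
    z = 0.1,                      # juvenile:adult mass ratio
    topt_interaction = topt_interaction,
    rmax_interaction = rmax_interaction,
    metab_exponent_interaction = metab_exponent_interaction,
    response_form = "shared"      # "shared" or "independent" Monod
  )
  prov <- rep("calibrated-default", length(p))
  names(prov) <- names(p)
  exact <- c("mass_exponent", "activation_energy", "boltzmann_k", "T_ref",
             "topt_ref", "topt_slope")
  prov[exact] <- "empirical"

  if (!is.null(transcription)) {
    tr <- yaml::read_yaml(transcription)
    unknown <- setdiff(names(tr), names(p))
    if (length(unknown) > 0)
      stop("unknown parameter keys in transcription: ",
           paste(unknown, collapse = ", "))
    for (nm in names(tr)) {
      p[[nm]] <- tr[[nm]]
      prov[nm] <- "transcribed"
    }
  }
  attr(p, "provenance") <- prov
  class(p) <- "thermo_params"
  validate_params(p)
  p
}

#' Validate a parameter set
#'
#' Checks the structural invariants of a parameter set and stops with a
#' message listing every violation.
#'
#' @param params a \code{"thermo_params"} list.
#' @return the parameter set, invisibly.
#' @export
validate_params <- function(params) {
  bad <- character(0)
  pos <- c("thermal_width", "rmax_ref", "imax_coeff", "metab_coeff",
           "H", "boltzmann_k")
  for (nm in pos)
    if (!is.numeric(params[[nm]]) || params[[nm]] <= 0)
      bad <- c(bad, paste0(nm, " must be > 0"))
  if (!is.numeric(params$delta) || params$delta < 0)
    bad <- c(bad, "delta must be >= 0")
  if (params$activation_energy < 0) bad <- c(bad, "activation_energy must be >= 0")
  if (params$mu < 0) bad <- c(bad, "mu must be >= 0")
  if (params$beta <= 0 || params$beta > 1) bad <- c(bad, "beta must be in (0, 1]")
  if (params$z <= 0 || params$z >= 1) bad <- c(bad, "z must be in (0, 1)")
  if (isTRUE(params$rmax_interaction)) {
    if (!(params$rmax_decline_L > params$rmax_decline_S))
      bad <- c(bad, "rmax_decline_L must exceed rmax_decline_S when rmax_interaction is on")
  } else {
    if (params$rmax_decline_L != params$rmax_decline_S)
      bad <- c(bad, "rmax_decline_L must equal rmax_decline_S when rmax_interaction is off")
  }
  if (!isTRUE(params$metab_exponent_interaction) && params$metab_exponent_slope != 0)
    bad <- c(bad, "metab_exponent_slope must be 0 when metab_exponent_interaction is off")
  if (!params$response_form %in% c("shared", "independent"))
    bad <- c(bad, "response_form must be 'shared' or 'independent'")
  prov <- attr(params, "provenance")
  core <- setdiff(names(params),
                  c("topt_interaction", "rmax_interaction",
                    "metab_exponent_interaction", "response_form"))
  if (is.null(prov) || !all(core %in% names(prov)))
    bad <- c(bad, "every parameter value must carry a provenance tag")
  if (length(bad) > 0)
    stop("invalid parameter set:\n  - ", paste(bad, collapse = "\n  - "))
  invisible(params)
}

#' @export
print.thermo_params <- function(x, ...) {
  cat("Food-web model parameter set\n")
  flags <- c(topt = x$topt_interaction, rmax = x$rmax_interaction,
             metab_exponent = x$metab_exponent_interaction)
  cat("  size-temperature interactions:",
      paste(names(flags)[flags], collapse = ", "), "\n")
  prov <- attr(x, "provenance")
  num <- names(x)[vapply(x, is.numeric, logical(1))]
  for (nm in num)
    cat(sprintf("  %-22s %-12g [%s]\n", nm, x[[nm]],
                if (nm %in% names(prov)) prov[[nm]] else "?"))
  invisible(x)
}
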