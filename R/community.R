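#' Community configurations
#'
#' Three food-web modules share two algal resources (small RS, large RL)
#' renewed by semichemostat dynamics:
#' \describe{
#'   \item{I}{two unstructured consumer species, small CS (1 ug) and large
#'     CL (10 ug);}
#'   \item{II}{one stage-structured species with juveniles J (1 ug) and
#'     adults A (10 ug);}
#'   \item{III}{two stage-structured species spanning three size classes:
#'     small species (JS 0.1 ug, AS 1 ug) and large species (JL 1 ug,
#'     AL 10 ug).}
#' }
#' The diet preference p scales how strongly each consumer feeds on "its"
#' resource (small consumers on RS, large on RL); it ranges over [0.5, 1]
#' in Communities I and II and over [0, 1] in Community III, where it sets
#' the diet overlap of the equally sized AS and JL.
#'
#' @name communities
NULL

.kind_masses <- function(kind) {
  switch(kind,
    I = c(CS = 1, CL = 10),
    II = c(J = 1, A = 10),
    III = c(JS = 0.1, AS = 1, JL = 1, AL = 10)
  )
}

#' Diet weights of a consumer compartment
#'
#' Weights on (RS, RL) as a function of community kind and diet preference.
#' Kinds I and II: the small species/stage gets (p, 1-p) and the large one
#' (1-p, p). Kind III (default scheme): JS feeds only on RS, AL only on RL,
#' and the mid-sized pair splits as AS = ((1+p)/2, (1-p)/2) and
#' JL = ((1-p)/2, (1+p)/2), so their diets are identical at p = 0 and
#' disjoint at p = 1. The \code{"swap"} scheme instead uses AS = (p, 1-p),
#' JL = (1-p, p), removing intraspecific overlap entirely at p = 0.
#'
#' @param kind community kind, \code{"I"}, \code{"II"} or \code{"III"}.
#' @param compartment compartment label (e.g. \code{"CS"}, \code{"J"},
#'   \code{"AS"}).
#' @param p diet preference.
#' @param scheme Community III mapping, \code{"default"} or \code{"swap"}.
#' @return numeric weights \code{c(RS = , RL = )}, summing to 1.
#' @export
diet_weights <- function(kind, compartment, p, scheme = "default") {
  kind <- match.arg(kind, c("I", "II", "III"))
  scheme <- match.arg(scheme, c("default", "swap"))
  lo <- if (kind == "III") 0 else 0.5
  if (!is.finite(p) || p < lo || p > 1)
    stop(sprintf("p = %g outside the legal range [%g, 1] for Community %s",
                 p, lo, kind))
  w <- if (kind %in% c("I", "II")) {
    switch(compartment,
      CS = , J = c(p, 1 - p),
      CL = , A = c(1 - p, p),
      stop("unknown compartment '", compartment, "' for Community ", kind))
  } else {
    switch(compartment,
      JS = c(1, 0),
      AL = c(0, 1),
      AS = if (scheme == "default") c((1 + p) / 2, (1 - p) / 2) else c(p, 1 - p),
      JL = if (scheme == "default") c((1 - p) / 2, (1 + p) / 2) else c(1 - p, p),
      stop("unknown compartment '", compartment, "' for Community III"))
  }
  names(w) <- c("RS", "RL")
  w
}

#' Build a community configuration
#'
#' Assembles a fully specified model configuration: compartments with body
#' masses and diet weights, temperature, diet preference and the parameter
#' set. Overrides are applied last; unknown override keys are an error.
#'
#' @param kind community kind, \code{"I"}, \code{"II"} or \code{"III"}.
#' @param p diet preference (range depends on kind).
#' @param T ambient temperature, degrees C.
#' @param params parameter set; defaults to [default_parameters()] with the
#'   given flags.
#' @param topt_interaction,rmax_interaction,metab_exponent_interaction
#'   interaction flags, used only when \code{params} is NULL.
#' @param overrides named list applied after assembly. Recognized keys:
#'   any numeric parameter name (e.g. \code{mu}, \code{H}), \code{masses}
#'   (named vector over compartments), \code{mu_by_compartment} (named
#'   vector), \code{diet_scheme}, \code{response_form}.
#' @return a list of class \code{"community_config"}.
#' @export
community_config <- function(kind, p, T, params = NULL,
                             topt_interaction = TRUE,
                             rmax_interaction = TRUE,
                             metab_exponent_interaction = FALSE,
                             overrides = list()) {
  kind <- match.arg(as.character(kind), c("I", "II", "III"))
  if (is.null(params))
    params <- default_parameters(topt_interaction, rmax_interaction,
                                 metab_exponent_interaction)
  validate_params(params)
  if (!is.finite(T)) stop("temperature must be finite")

  masses <- .kind_masses(kind)
  scheme <- "default"
  known_extra <- c("masses", "mu_by_compartment", "diet_scheme", "response_form",
                   "absent_resources")
  unknown <- setdiff(names(overrides), c(names(params), known_extra))
  if (length(unknown) > 0)
    stop("unknown override keys: ", paste(unknown, collapse = ", "))
  for (nm in intersect(names(overrides), names(params)))
    params[[nm]] <- overrides[[nm]]
  if (!is.null(overrides$response_form)) params$response_form <- overrides$response_form
  if (!is.null(overrides$diet_scheme)) scheme <- overrides$diet_scheme
  if (!is.null(overrides$masses)) {
    m <- overrides$masses
    bad <- setdiff(names(m), names(masses))
    if (length(bad) > 0) stop("masses override for unknown compartments: ",
                              paste(bad, collapse = ", "))
    masses[names(m)] <- m
  }
  prov <- attr(params, "provenance")
  over_num <- intersect(names(overrides), names(params))
  if (length(over_num) > 0) prov[over_num] <- "override"
  attr(params, "provenance") <- prov
  validate_params(params)

  species <- switch(kind,
    I = c(CS = "CS", CL = "CL"),
    II = c(J = "C", A = "C"),
    III = c(JS = "S", AS = "S", JL = "L", AL = "L"))
  role <- switch(kind,
    I = c(CS = "unstructured", CL = "unstructured"),
    II = c(J = "juvenile", A = "adult"),
    III = c(JS = "juvenile", AS = "adult", JL = "juvenile", AL = "adult"))

  mu <- rep(params$mu, length(masses))
  names(mu) <- names(masses)
  if (!is.null(overrides$mu_by_compartment)) {
    mo <- overrides$mu_by_compartment
    bad <- setdiff(names(mo), names(mu))
    if (length(bad) > 0) stop("mu override for unknown compartments: ",
                              paste(bad, collapse = ", "))
    mu[names(mo)] <- mo
  }

  comps <- lapply(names(masses), function(id) {
    list(id = id, species = unname(species[id]), role = unname(role[id]),
         mass = unname(masses[id]),
         weights = diet_weights(kind, id, p, scheme))
  })
  names(comps) <- names(masses)

  # juvenile/adult pairing within species
  pairs <- list()
  for (sp in unique(species)) {
    ids <- names(species)[species == sp]
    if (length(ids) == 2 && all(sort(unname(role[ids])) == c("adult", "juvenile"))) {
      j <- ids[role[ids] == "juvenile"]; a <- ids[role[ids] == "adult"]
      if (!(masses[j] < masses[a]))
        stop("juvenile mass must be smaller than adult mass for species ", sp)
      pairs[[sp]] <- list(juvenile = j, adult = a,
                          z = unname(masses[j] / masses[a]))
    }
  }

  absent <- overrides$absent_resources
  if (!is.null(absent) && !all(absent %in% c("RS", "RL")))
    stop("absent_resources must name 'RS' and/or 'RL'")
  cfg <- list(kind = kind, p = p, T = T, params = params,
              compartments = comps, mu = mu, pairs = pairs,
              diet_scheme = scheme, absent_resources = absent)
  class(cfg) <- "community_config"
  cfg
}

#' @export
print.community_config <- function(x, ...) {
  cat(sprintf("Community %s at T = %g C, p = %g\n", x$kind, x$T, x$p))
  for (cp in x$compartments)
    cat(sprintf("  %-3s %-12s %-6s M = %5.2g ug  diet (RS, RL) = (%.3f, %.3f)\n",
                cp$id, cp$role, cp$species, cp$mass,
                cp$weights[1], cp$weights[2]))
  invisible(x)
}

#' Type-II multi-resource functional response
#'
#' Given diet weights on the two resources, returns total mass-specific
#' ingestion and its per-resource split. The default (\code{"shared"}) form
#' is an encounter-weighted Monod response with one half-saturation
#' constant: the effective availability is \code{E = wS*RS + wL*RL}, total
#' ingestion is \code{Imax*E/(H+E)} and the split is
#' \code{Imax*wj*Rj/(H+E)}. The \code{"independent"} form saturates each
#' resource separately: \code{Imax*wj*Rj/(H+Rj)}.
#'
#' @param weights diet weights \code{c(RS, RL)}, non-negative.
#' @param RS,RL resource biomass densities (>= 0).
#' @param Imax mass-specific maximum ingestion rate (> 0).
#' @param H half-saturation biomass density (> 0).
#' @param form \code{"shared"} or \code{"independent"}.
#' @return list with \code{total} (per day) and \code{per_resource}
#'   (named pair summing to \code{total}).
#' @export
functional_response <- function(weights, RS, RL, Imax, H, form = "shared") {
  form <- match.arg(form, c("shared", "independent"))
  if (H <= 0) stop("half-saturation constant H must be > 0")
  if (Imax <= 0) stop("Imax must be > 0")
  if (RS < 0 || RL < 0) stop("resource densities must be >= 0")
  if (any(weights < 0)) stop("diet weights must be >= 0")
  R <- c(RS = RS, RL = RL)
  if (form == "shared") {
    E <- sum(weights * R)
    per <- Imax * weights * R / (H + E)
  } else {
    per <- Imax * weights * R / (H + R)
  }
  names(per) <- c("RS", "RL")
  list(total = sum(per), per_resource = per)
}

#' Net biomass production rate
#'
#' Mass-specific net production \code{nu = beta * ingestion - m}:
#' assimilated intake minus metabolic losses. Background mortality is not
#' part of nu; it enters the biomass balance separately. Negative values
#' represent starvation loss.
#'
#' @param beta conversion efficiency in (0, 1].
#' @param ingestion mass-specific ingestion rate, per day (>= 0).
#' @param m mass-specific metabolic rate, per day (>= 0).
#' @return net production rate nu, per day.
#' @export
net_production <- function(beta, ingestion, m) {
  if (any(beta <= 0 | beta > 1)) stop("beta must be in (0, 1]")
  beta * ingestion - m
}

#' Food-dependent maturation rate
#'
#' Per-biomass flux from the juvenile to the adult compartment in the
#' stage-structured biomass model:
#' \deqn{\gamma(\nu_J, \mu_J) = \frac{\nu_J - \mu_J}{1 - z^{1 - \mu_J/\nu_J}}}
#' for positive juvenile net production, continuously extended through the
#' removable singularity at \eqn{\nu_J = \mu_J} (limit
#' \eqn{\mu_J / \ln(1/z)}), and zero for \eqn{\nu_J \le 0} (starving
#' juveniles do not mature).
#'
#' @param nu_J juvenile net biomass production rate, per day.
#' @param mu_J juvenile background mortality, per day (>= 0).
#' @param z juvenile-to-adult body mass ratio in (0, 1).
#' @return maturation rate gamma >= 0, per day.
#' @export
maturation_rate <- function(nu_J, mu_J, z) {
  if (z <= 0 || z >= 1) stop("z must be in (0, 1)")
  if (mu_J < 0) stop("mu_J must be >= 0")
  out <- numeric(length(nu_J))
  pos <- which(nu_J > 0)
  if (length(pos) > 0) {
    nu <- nu_J[pos]
    q <- 1 - mu_J / nu
    # 1 - z^q via expm1 for accuracy near the removable singularity q -> 0
    denom <- -expm1(q * log(z))
    g <- ifelse(q == 0, nu / log(1 / z), (nu - mu_J) / denom)
    out[pos] <- pmax(g, 0)
  }
  out
}

#' Precompute the temperature- and mass-dependent rates of a configuration
#'
#' Within one configuration the temperature is fixed, so per-compartment
#' maximum ingestion, metabolism, diet weights and the resource carrying
#' capacities are constants of the ODE system. Computed once and reused by
#' the right-hand side.
#'
#' @param config a [community_config()].
#' @return list of rate tables used by [community_rhs()].
#' @export
compute_rates <- function(config) {
  pr <- config$params
  ids <- names(config$compartments)
  M <- vapply(config$compartments, function(cp) cp$mass, numeric(1))
  W <- t(vapply(config$compartments, function(cp) cp$weights, numeric(2)))
  colnames(W) <- c("RS", "RL")
  Rmax <- c(RS = resource_carrying_capacity("RS", config$T, pr),
            RL = resource_carrying_capacity("RL", config$T, pr))
  # an absent resource has zero supply: a pure reduction device for
  # collapsing the system to a single-resource module
  if (!is.null(config$absent_resources)) Rmax[config$absent_resources] <- 0
  list(
    ids = ids,
    labels = c("RS", "RL", ids),
    mass = M,
    W = W,
    Imax = max_ingestion_rate(M, config$T, pr),
    m = metabolic_rate(M, config$T, pr),
    mu = config$mu[ids],
    Rmax = Rmax,
    delta = pr$delta, H = pr$H, beta = pr$beta,
    form = pr$response_form,
    pairs = config$pairs
  )
}

#' Right-hand side of the community ODE system
#'
#' Time derivatives of every compartment: semichemostat resource renewal
#' minus grazing; unstructured consumers grow with net production minus
#' background mortality; juvenile/adult pairs are linked by food-dependent
#' maturation and reproduction (positive adult net production appears
#' instantaneously as new juvenile biomass; adults never grow).
#'
#' @param state named non-negative state vector
#'   (\code{RS}, \code{RL}, then consumer compartments).
#' @param config a [community_config()].
#' @param rates optional precomputed [compute_rates()] table.
#' @return named vector of time derivatives.
#' @export
community_rhs <- function(state, config, rates = NULL) {
  if (is.null(rates)) rates <- compute_rates(config)
  if (is.null(names(state))) {
    if (length(state) != length(rates$labels))
      stop("state length does not match the configuration")
    names(state) <- rates$labels
  }
  if (!identical(sort(names(state)), sort(rates$labels)))
    stop("state labels do not match the configuration's compartments")
  state <- state[rates$labels]
  if (any(state < 0)) stop("state entries must be non-negative")
  .rhs_core(state, rates)
}

# internal fast path: `y` ordered as rates$labels
.rhs_core <- function(y, r) {
  RS <- y[1]; RL <- y[2]
  C <- y[-(1:2)]
  n <- length(C)
  if (r$form == "shared") {
    E <- r$W[, 1] * RS + r$W[, 2] * RL
    den <- r$H + E
    I_RS <- r$Imax * r$W[, 1] * RS / den
    I_RL <- r$Imax * r$W[, 2] * RL / den
  } else {
    I_RS <- r$Imax * r$W[, 1] * RS / (r$H + RS)
    I_RL <- r$Imax * r$W[, 2] * RL / (r$H + RL)
  }
  Itot <- I_RS + I_RL
  nu <- r$beta * Itot - r$m

  dRS <- r$delta * (r$Rmax[1] - RS) - sum(I_RS * C)
  dRL <- r$delta * (r$Rmax[2] - RL) - sum(I_RL * C)

  dC <- (nu - r$mu) * C  # unstructured balance; pairs overwritten below
  if (length(r$pairs) > 0) {
    for (pp in r$pairs) {
      j <- match(pp$juvenile, r$ids); a <- match(pp$adult, r$ids)
      gam <- maturation_rate(nu[j], r$mu[j], pp$z)
      nuA <- nu[a]
      dC[j] <- max(nuA, 0) * C[a] + nu[j] * C[j] - gam * C[j] - r$mu[j] * C[j]
      dC[a] <- gam * C[j] + min(nuA, 0) * C[a] - r$mu[a] * C[a]
    }
  }
  out <- c(dRS, dRL, dC)
  names(out) <- r$labels
  out
}

#' Canonical and random initial states
#'
#' Deterministic canonical states used by the equilibrium multistart, or
#' seeded log-uniform random states. Resources start at their carrying
#' capacities.
#'
#' @param config a [community_config()].
#' @param variant one of \code{"inoculum"} (every consumer at a small equal
#'   biomass), \code{"juvenile-heavy"} / \code{"adult-heavy"} (stage biomass
#'   ratio 100:1 at fixed total), \code{"low"}, \code{"high"},
#'   \code{"resource-only"}, \code{"random"}.
#' @param seed integer seed, used for \code{"random"}.
#' @param total total consumer biomass of the stage-skewed variants.
#' @return named state vector.
#' @export
initial_states <- function(config, variant = "inoculum", seed = 1, total = 10) {
  variant <- match.arg(variant, c("inoculum", "juvenile-heavy", "adult-heavy",
                                  "low", "high", "resource-only", "random"))
  r <- compute_rates(config)
  y <- c(r$Rmax[1], r$Rmax[2], rep(0, length(r$ids)))
  names(y) <- r$labels
  roles <- vapply(config$compartments, function(cp) cp$role, character(1))
  if (variant == "inoculum") {
    y[r$ids] <- 1
  } else if (variant == "low") {
    y[r$ids] <- 1e-3
  } else if (variant == "high") {
    y[r$ids] <- 0.5 * r$Rmax[1]
  } else if (variant %in% c("juvenile-heavy", "adult-heavy")) {
    hi <- if (variant == "juvenile-heavy") "juvenile" else "adult"
    for (id in r$ids) {
      if (roles[id] == "unstructured") y[id] <- 1
      else y[id] <- if (roles[id] == hi) total * 100 / 101 else total / 101
    }
  } else if (variant == "random") {
    set.seed(seed)
    eps <- 1e-9 * config$params$rmax_ref
    lo <- log(eps); hi <- log(10 * config$params$rmax_ref)
    y[r$ids] <- exp(stats::runif(length(r$ids), lo, hi))
  }
  y
}

#' Write / read a community configuration as YAML
#'
#' Serializes kind, diet preference, temperature, flags, the parameter set
#' (with provenance) and any overridden masses or mortalities. Unknown keys
#' on read are an error.
#'
#' @param config a [community_config()].
#' @param path file path.
#' @return \code{read_config} returns a [community_config()].
#' @export
write_config <- function(config, path) {
  pr <- config$params
  num <- names(pr)[vapply(pr, is.numeric, logical(1))]
  obj <- list(
    kind = config$kind, p = config$p, T = config$T,
    diet_scheme = config$diet_scheme,
    flags = list(topt_interaction = pr$topt_interaction,
                 rmax_interaction = pr$rmax_interaction,
                 metab_exponent_interaction = pr$metab_exponent_interaction),
    response_form = pr$response_form,
    parameters = pr[num],
    provenance = as.list(attr(pr, "provenance")),
    masses = as.list(vapply(config$compartments, function(cp) cp$mass,
                            numeric(1))),
    mu_by_compartment = as.list(config$mu)
  )
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  obj <- yaml::read_yaml(path)
  known <- c("kind", "p", "T", "diet_scheme", "flags", "response_form",
             "parameters", "provenance", "masses", "mu_by_compartment")
  unknown <- setdiff(names(obj), known)
  if (length(unknown) > 0)
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "))
  params <- default_parameters(obj$flags$topt_interaction,
                               obj$flags$rmax_interaction,
                               obj$flags$metab_exponent_interaction)
  unknown_p <- setdiff(names(obj$parameters), names(params))
  if (length(unknown_p) > 0)
    stop("unknown parameter keys: ", paste(unknown_p, collapse = ", "))
  prov <- attr(params, "provenance")
  for (nm in names(obj$parameters)) params[[nm]] <- obj$parameters[[nm]]
  if (!is.null(obj$provenance)) prov[names(obj$provenance)] <- unlist(obj$provenance)
  params$response_form <- obj$response_form
  attr(params, "provenance") <- prov
  community_config(obj$kind, obj$p, obj$T, params = params,
                   overrides = list(masses = unlist(obj$masses),
                                    mu_by_compartment = unlist(obj$mu_by_compartment),
                                    diet_scheme = obj$diet_scheme))
}
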