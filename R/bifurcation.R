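#' Scenario templates over the temperature-preference plane
#'
#' A scenario fixes everything about a community except temperature and diet
#' preference, so that boundary mappers and sweeps can instantiate
#' configurations across the (T, p) plane.
#'
#' @param kind community kind, \code{"I"}, \code{"II"} or \code{"III"}.
#' @param topt_interaction,rmax_interaction,metab_exponent_interaction
#'   size-temperature interaction flags.
#' @param overrides named override list, as in [community_config()].
#' @param params optional explicit parameter set.
#' @return object of class \code{"scenario"}.
#' @export
scenario <- function(kind, topt_interaction = TRUE, rmax_interaction = TRUE,
                     metab_exponent_interaction = FALSE,
                     overrides = list(), params = NULL) {
  structure(list(kind = kind, topt_interaction = topt_interaction,
                 rmax_interaction = rmax_interaction,
                 metab_exponent_interaction = metab_exponent_interaction,
                 overrides = overrides, params = params),
            class = "scenario")
}

#' @rdname scenario
#' @param sc a scenario.
#' @param p diet preference.
#' @param T temperature, degrees C.
#' @export
scenario_config <- function(sc, p, T) {
  community_config(sc$kind, p, T, params = sc$params,
                   topt_interaction = sc$topt_interaction,
                   rmax_interaction = sc$rmax_interaction,
                   metab_exponent_interaction = sc$metab_exponent_interaction,
                   overrides = sc$overrides)
}

# species-level biomass sums and orderings for a state vector
.species_biomass <- function(state, config) {
  sp <- vapply(config$compartments, function(cp) cp$species, character(1))
  ids <- names(config$compartments)
  tapply(state[ids], sp, sum)
}

.species_size_order <- function(config) {
  sp <- vapply(config$compartments, function(cp) cp$species, character(1))
  mx <- tapply(vapply(config$compartments, function(cp) cp$mass, numeric(1)),
               sp, max)
  names(sort(mx))  # smaller species first
}

#' Classify a community state
#'
#' Persistence component: which consumer species carry biomass above the
#' extinction threshold. Dominance components: at the species level, whether
#' the larger- or smaller-bodied species holds more total biomass; at the
#' stage level, per structured species, whether juveniles or adults hold
#' more. Exact ties are labelled \code{"balanced"}.
#'
#' @param state named state vector (an equilibrium).
#' @param config a [community_config()].
#' @param eps extinction threshold on biomass.
#' @param tie_tol relative biomass gap below which two units are considered
#'   exactly tied (\code{"balanced"}); absorbs solver round-off in
#'   symmetric configurations.
#' @return list with \code{persistent_species}, \code{species_dominance},
#'   \code{stage_dominance} (named by species) and a compact \code{label}.
#' @export
classify_state_vector <- function(state, config, eps = 1e-7,
                                  tie_tol = 1e-6) {
  B <- .species_biomass(state, config)
  persist <- names(B)[B > eps]
  ord <- .species_size_order(config)
  cmp <- function(b_large, b_small) {
    if (abs(b_large - b_small) <= tie_tol * (b_large + b_small)) 0
    else sign(b_large - b_small)
  }

  species_dominance <- NA_character_
  if (length(ord) >= 2 && length(persist) >= 2) {
    small <- ord[1]; large <- ord[length(ord)]
    s <- cmp(B[[large]], B[[small]])
    species_dominance <- if (s > 0) large else if (s < 0) small else "balanced"
  } else if (length(persist) == 1 && length(ord) >= 2) {
    species_dominance <- persist
  }

  stage_dominance <- character(0)
  for (spn in names(config$pairs)) {
    if (!(spn %in% persist)) next
    pp <- config$pairs[[spn]]
    s <- cmp(state[[pp$adult]], state[[pp$juvenile]])
    stage_dominance[spn] <- if (s > 0) "adult" else if (s < 0) "juvenile" else "balanced"
  }

  label <- if (length(persist) == 0) "consumers-extinct" else {
    parts <- paste(sort(persist), collapse = "+")
    if (!is.na(species_dominance) && length(persist) >= 2)
      parts <- paste0(parts, ";dom=", species_dominance)
    if (length(stage_dominance) > 0)
      parts <- paste0(parts, ";", paste0(names(stage_dominance), ":",
                                         stage_dominance, collapse = ";"))
    parts
  }
  list(persistent_species = persist, species_dominance = species_dominance,
       stage_dominance = stage_dominance, label = label)
}

#' @rdname classify_state_vector
#' @param eq_result an \code{"equilibrium_result"}.
#' @export
classify_state <- function(eq_result, config,
                           eps = 1e-9 * config$params$rmax_ref) {
  classify_state_vector(eq_result$state, config, eps)
}

# equilibrium at one (p, T) point of a scenario from a canonical start
.eq_at <- function(sc, p, T, control, start = "inoculum") {
  cfg <- scenario_config(sc, p, T)
  find_equilibrium(cfg, initial_states(cfg, start), control)
}

# biomass of a subject (species label or compartment id) in an equilibrium
.subject_biomass <- function(eq, config, subject) {
  ids <- names(config$compartments)
  sp <- vapply(config$compartments, function(cp) cp$species, character(1))
  if (subject %in% ids) return(unname(eq$state[subject]))
  if (subject %in% sp) return(sum(eq$state[ids[sp == subject]]))
  stop("subject '", subject, "' is not a species or compartment of this community")
}

# generic sign-change bisection along T of a scalar indicator
.bisect_T <- function(indicator, T_lo, T_hi, tol_T) {
  f_lo <- indicator(T_lo)
  while (T_hi - T_lo > tol_T) {
    mid <- (T_lo + T_hi) / 2
    f_mid <- indicator(mid)
    if (is.na(f_mid)) return(NA_real_)
    if (sign(f_mid) == sign(f_lo)) T_lo <- mid else T_hi <- mid
  }
  (T_lo + T_hi) / 2
}

#' Persistence boundary in the temperature-preference plane
#'
#' For each diet preference on the grid, the subject's equilibrium biomass
#' (from a fixed canonical start) is scanned along temperature; every sign
#' change of presence/absence is refined by bisection to \code{tol_T}.
#' Multiple crossings per preference (lower and upper thermal limits) are
#' supported; a subject persistent over the whole grid yields an empty
#' curve.
#'
#' @param sc a [scenario()].
#' @param subject species label or compartment id.
#' @param T_range temperature range, degrees C.
#' @param p_range diet preference range.
#' @param n_grid grid sizes \code{c(n_T, n_p)}.
#' @param tol_T bisection tolerance, degrees C.
#' @param control an [eq_control()] list.
#' @param start canonical start variant.
#' @return data frame of class \code{"boundary_curve"} with columns
#'   \code{p}, \code{T}, \code{direction} (\code{"lower"}: subject present
#'   above this temperature; \code{"upper"}: present below), ordered by p.
#' @export
persistence_boundary <- function(sc, subject, T_range = c(0, 45),
                                 p_range = NULL, n_grid = c(24, 6),
                                 tol_T = 0.05, control = eq_control(),
                                 start = "inoculum") {
  if (is.null(p_range)) p_range <- if (sc$kind == "III") c(0, 1) else c(0.5, 1)
  cfg0 <- scenario_config(sc, p_range[1], mean(T_range))
  .subject_biomass(find_equilibrium(cfg0, initial_states(cfg0, "resource-only"),
                                    control), cfg0, subject)  # validates subject
  Ts <- seq(T_range[1], T_range[2], length.out = n_grid[1])
  ps <- seq(p_range[1], p_range[2], length.out = n_grid[2])
  rows <- list()
  for (p in ps) {
    present <- vapply(Ts, function(T) {
      eq <- .eq_at(sc, p, T, control, start)
      cfg <- scenario_config(sc, p, T)
      .subject_biomass(eq, cfg, subject) > 0
    }, logical(1))
    flips <- which(diff(present) != 0)
    for (i in flips) {
      ind <- function(T) {
        eq <- .eq_at(sc, p, T, control, start)
        cfg <- scenario_config(sc, p, T)
        if (.subject_biomass(eq, cfg, subject) > 0) 1 else -1
      }
      Tb <- .bisect_T(ind, Ts[i], Ts[i + 1], tol_T)
      rows[[length(rows) + 1]] <- data.frame(
        p = p, T = Tb,
        direction = if (present[i]) "upper" else "lower")
    }
  }
  out <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(p = numeric(0), T = numeric(0), direction = character(0))
  out <- out[order(out$p, out$T), , drop = FALSE]
  attr(out, "boundary_type") <- "persistence"
  attr(out, "subject") <- subject
  attr(out, "refinement_tol") <- tol_T
  class(out) <- c("boundary_curve", "data.frame")
  out
}

#' Dominance boundary in the temperature-preference plane
#'
#' Boundary at which biomass dominance flips between the larger and smaller
#' species (level \code{"species"}) or between adults and juveniles within a
#' structured species (level \code{"stage"}). The indicator is the biomass
#' of the larger unit minus that of the smaller at the stable equilibrium
#' reached from a fixed canonical start; grid cells where either unit is
#' extinct are excluded.
#'
#' @inheritParams persistence_boundary
#' @param level \code{"species"} or \code{"stage"}.
#' @param subject for \code{level = "stage"} in Community III, which species.
#' @return a \code{"boundary_curve"} data frame (p, T), ordered by p.
#' @export
dominance_boundary <- function(sc, level = c("species", "stage"),
                               subject = NULL, T_range = c(0, 45),
                               p_range = NULL, n_grid = c(24, 6),
                               tol_T = 0.05, control = eq_control(),
                               start = "inoculum") {
  level <- match.arg(level)
  if (is.null(p_range)) p_range <- if (sc$kind == "III") c(0, 1) else c(0.5, 1)
  cfg0 <- scenario_config(sc, p_range[1], mean(T_range))
  if (level == "stage" && length(cfg0$pairs) == 0)
    stop("stage-level dominance is undefined for an unstructured community")
  if (level == "species" && length(unique(vapply(cfg0$compartments,
      function(cp) cp$species, character(1)))) < 2)
    stop("species-level dominance needs two consumer species")
  if (level == "stage" && is.null(subject)) {
    if (length(cfg0$pairs) > 1)
      stop("subject species must be given for stage-level dominance here")
    subject <- names(cfg0$pairs)[1]
  }

  ind_value <- function(p, T) {
    cfg <- scenario_config(sc, p, T)
    eq <- find_equilibrium(cfg, initial_states(cfg, start), control)
    gap <- if (level == "species") {
      ord <- .species_size_order(cfg)
      B <- .species_biomass(eq$state, cfg)
      small <- B[[ord[1]]]; large <- B[[ord[length(ord)]]]
      if (small <= 0 || large <= 0) return(NA_real_)
      c(large - small, large + small)
    } else {
      pp <- cfg$pairs[[subject]]
      J <- eq$state[[pp$juvenile]]; A <- eq$state[[pp$adult]]
      if (J + A <= 0) return(NA_real_)
      c(A - J, A + J)
    }
    # round-off ties count as exactly balanced
    if (abs(gap[1]) <= 1e-6 * gap[2]) 0 else gap[1]
  }

  Ts <- seq(T_range[1], T_range[2], length.out = n_grid[1])
  ps <- seq(p_range[1], p_range[2], length.out = n_grid[2])
  rows <- list()
  for (p in ps) {
    v <- vapply(Ts, function(T) ind_value(p, T), numeric(1))
    for (i in seq_len(length(Ts) - 1)) {
      if (is.na(v[i]) || is.na(v[i + 1])) next
      if (v[i] == 0 || sign(v[i]) == sign(v[i + 1])) next
      ind <- function(T) ind_value(p, T)
      Tb <- .bisect_T(ind, Ts[i], Ts[i + 1], tol_T)
      if (!is.na(Tb))
        rows[[length(rows) + 1]] <- data.frame(p = p, T = Tb)
    }
  }
  out <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(p = numeric(0), T = numeric(0))
  out <- out[order(out$p, out$T), , drop = FALSE]
  attr(out, "boundary_type") <- "dominance"
  attr(out, "subject") <- if (level == "species") "species" else subject
  attr(out, "level") <- level
  attr(out, "refinement_tol") <- tol_T
  class(out) <- c("boundary_curve", "data.frame")
  out
}

#' Region of alternative stable states
#'
#' Scans the (T, p) grid counting distinct stable equilibria found by
#' [multistart_equilibria()]; cells with two or more are inside the
#' bistability region. The region edge along temperature is refined by
#' bisection per preference value.
#'
#' @inheritParams persistence_boundary
#' @param seed seed for the random multistart components.
#' @param n_random random starts per cell (added to the canonical starts).
#' @return list with \code{grid} (data frame T, p, n_states),
#'   \code{region} (subset with n_states >= 2) and \code{boundary}
#'   (a \code{"boundary_curve"} of refined edge temperatures).
#' @export
bistability_region <- function(sc, T_range = c(0, 45), p_range = NULL,
                               n_grid = c(12, 5), tol_T = 0.25, seed = 1,
                               n_random = 2, control = eq_control()) {
  if (is.null(p_range)) p_range <- if (sc$kind == "III") c(0, 1) else c(0.5, 1)
  Ts <- seq(T_range[1], T_range[2], length.out = n_grid[1])
  ps <- seq(p_range[1], p_range[2], length.out = n_grid[2])
  n_states_at <- function(p, T) {
    cfg <- scenario_config(sc, p, T)
    length(multistart_equilibria(cfg, n_random = n_random, seed = seed,
                                 control = control))
  }
  grid <- expand.grid(T = Ts, p = ps)
  grid$n_states <- mapply(n_states_at, grid$p, grid$T)
  rows <- list()
  for (p in ps) {
    v <- grid$n_states[grid$p == p]
    multi <- v >= 2
    for (i in which(diff(multi) != 0)) {
      ind <- function(T) if (n_states_at(p, T) >= 2) 1 else -1
      Tb <- .bisect_T(ind, Ts[i], Ts[i + 1], tol_T)
      if (!is.na(Tb)) rows[[length(rows) + 1]] <- data.frame(p = p, T = Tb)
    }
  }
  boundary <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(p = numeric(0), T = numeric(0))
  attr(boundary, "boundary_type") <- "bistability"
  attr(boundary, "refinement_tol") <- tol_T
  class(boundary) <- c("boundary_curve", "data.frame")
  list(grid = grid, region = grid[grid$n_states >= 2, , drop = FALSE],
       boundary = boundary)
}

#' Classified raster of the temperature-preference plane
#'
#' Full classification of equilibria over a (T, p) grid: persistent species,
#' species- and stage-level dominance, compact label, and (optionally) the
#' number of distinct stable states from the canonical multistart.
#'
#' @inheritParams bistability_region
#' @param count_states also count stable states per cell via multistart
#'   (slower).
#' @return data frame with one row per grid cell.
#' @export
map_T_p_plane <- function(sc, T_range = c(0, 45), p_range = NULL,
                          n_grid = c(12, 5), seed = 1,
                          count_states = FALSE, control = eq_control(),
                          start = "inoculum") {
  if (is.null(p_range)) p_range <- if (sc$kind == "III") c(0, 1) else c(0.5, 1)
  Ts <- seq(T_range[1], T_range[2], length.out = n_grid[1])
  ps <- seq(p_range[1], p_range[2], length.out = n_grid[2])
  grid <- expand.grid(T = Ts, p = ps)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    cfg <- scenario_config(sc, grid$p[i], grid$T[i])
    eq <- find_equilibrium(cfg, initial_states(cfg, start), control)
    cl <- classify_state(eq, cfg)
    n_states <- if (count_states)
      length(multistart_equilibria(cfg, n_random = 0, seed = seed,
                                   control = control)) else NA_integer_
    data.frame(T = grid$T[i], p = grid$p[i],
               label = cl$label,
               persistent = paste(sort(cl$persistent_species), collapse = "+"),
               species_dominance = cl$species_dominance,
               stage_dominance = paste(names(cl$stage_dominance),
                                       cl$stage_dominance, sep = ":",
                                       collapse = ";"),
               n_states = n_states,
               stable = isTRUE(eq$stable),
               residual = eq$residual)
  })
  do.call(rbind, res)
}
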