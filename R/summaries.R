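#' Abundance-weighted mean individual body mass
#'
#' The model tracks biomass, so individual numbers are implied as
#' biomass/mass per compartment; the mean individual mass is total consumer
#' biomass over implied total numbers,
#' \code{sum(B_i) / sum(B_i / M_i)} across consumer compartments. Bounded
#' by the smallest and largest compartment masses.
#'
#' @param state named state vector.
#' @param config a [community_config()].
#' @return mean individual mass, ug; \code{NA} (with a warning) when all
#'   consumers are extinct.
#' @export
mean_body_mass <- function(state, config) {
  ids <- names(config$compartments)
  B <- state[ids]
  M <- vapply(config$compartments, function(cp) cp$mass, numeric(1))
  if (sum(B) <= 0) {
    warning("mean body mass undefined: all consumer compartments are zero")
    return(NA_real_)
  }
  sum(B) / sum(B / M)
}

#' Equilibrium biomass along a temperature gradient
#'
#' Forward (cold-to-warm) and backward (warm-to-cold) sweeps with
#' warm-started equilibria: each step starts from the previous equilibrium
#' with every consumer compartment reseeded to at least a small inoculum so
#' that invasions are detected. Where the two sweeps disagree beyond the
#' clustering tolerance both branches are reported (hysteresis across an
#' alternative-stable-state region); elsewhere a single \code{"unique"}
#' branch row is emitted.
#'
#' @param sc a [scenario()].
#' @param p diet preference.
#' @param T_grid sorted temperatures, degrees C.
#' @param control an [eq_control()] list.
#' @param reseed invasion inoculum added to extinct consumer compartments at
#'   each step.
#' @return data frame: one row per (T, branch) with resource and consumer
#'   biomasses, classification label, mean individual mass, residual.
#' @export
biomass_vs_temperature <- function(sc, p = 0.85,
                                   T_grid = seq(0, 45, by = 0.5),
                                   control = eq_control(), reseed = 1e-3) {
  if (is.unsorted(T_grid)) stop("T_grid must be sorted increasing")
  sweep_dir <- function(Ts) {
    out <- vector("list", length(Ts))
    y <- NULL
    for (i in seq_along(Ts)) {
      cfg <- scenario_config(sc, p, Ts[i])
      r <- compute_rates(cfg)
      y0 <- if (is.null(y)) initial_states(cfg, "inoculum") else {
        ys <- y
        ys[1:2] <- pmax(ys[1:2], 0.5 * r$Rmax)  # refresh resources
        ys[r$ids] <- pmax(ys[r$ids], reseed)
        ys
      }
      eq <- find_equilibrium(cfg, y0, control)
      out[[i]] <- eq
      y <- eq$state
    }
    out
  }
  fwd <- sweep_dir(T_grid)
  bwd <- rev(sweep_dir(rev(T_grid)))

  row_of <- function(eq, T, branch) {
    cfg <- scenario_config(sc, p, T)
    cl <- classify_state(eq, cfg)
    mm <- if (sum(eq$state[-(1:2)]) > 0) mean_body_mass(eq$state, cfg) else NA_real_
    cbind(data.frame(T = T, p = p, branch = branch),
          as.data.frame(as.list(eq$state)),
          data.frame(classification = cl$label, mean_mass = mm,
                     residual = eq$residual, stable = isTRUE(eq$stable)))
  }
  rows <- list()
  for (i in seq_along(T_grid)) {
    sf <- fwd[[i]]$state; sb <- bwd[[i]]$state
    sc_norm <- max(abs(sf), abs(sb), 1e-8)
    if (max(abs(sf - sb)) / sc_norm < control$cluster_tol) {
      rows[[length(rows) + 1]] <- row_of(fwd[[i]], T_grid[i], "unique")
    } else {
      rows[[length(rows) + 1]] <- row_of(fwd[[i]], T_grid[i], "forward")
      rows[[length(rows) + 1]] <- row_of(bwd[[i]], T_grid[i], "backward")
    }
  }
  do.call(rbind, rows)
}

#' Temperature at which biomass dominance flips
#'
#' Scans equilibria along temperature at fixed diet preference and refines
#' the first sign change of the dominance indicator (larger minus smaller
#' unit biomass) by bisection. Returns \code{NA} when no flip occurs within
#' the range.
#'
#' @inheritParams biomass_vs_temperature
#' @param level \code{"species"} or \code{"stage"}.
#' @param subject species for stage-level dominance in Community III.
#' @param T_range scanned temperature range, degrees C.
#' @param step scan step, degrees C.
#' @param tol_T bisection tolerance, degrees C.
#' @param direction which flips count: \code{"any"}, \code{"to-smaller"}
#'   (dominance moves to the smaller unit -- smaller species, or juveniles
#'   -- as temperature rises) or \code{"to-larger"} (to the larger species,
#'   or adults).
#' @return flip temperature in degrees C, or \code{NA}.
#' @export
dominance_shift_temperature <- function(sc, p = 0.85,
                                        level = c("species", "stage"),
                                        subject = NULL,
                                        T_range = c(0, 45), step = 1.5,
                                        tol_T = 0.01,
                                        direction = c("any", "to-smaller",
                                                      "to-larger"),
                                        control = eq_control()) {
  level <- match.arg(level)
  direction <- match.arg(direction)
  cfg0 <- scenario_config(sc, p, mean(T_range))
  if (level == "stage" && length(cfg0$pairs) == 0)
    stop("stage-level dominance is undefined for an unstructured community")
  if (level == "stage" && is.null(subject)) subject <- names(cfg0$pairs)[1]

  ind_value <- function(T) {
    cfg <- scenario_config(sc, p, T)
    eq <- find_equilibrium(cfg, initial_states(cfg, "inoculum"), control)
    if (level == "species") {
      ord <- .species_size_order(cfg)
      B <- .species_biomass(eq$state, cfg)
      if (any(B[c(ord[1], ord[length(ord)])] <= 0)) return(NA_real_)
      unname(B[ord[length(ord)]] - B[ord[1]])
    } else {
      pp <- cfg$pairs[[subject]]
      J <- eq$state[pp$juvenile]; A <- eq$state[pp$adult]
      if (J + A <= 0) return(NA_real_)
      unname(A - J)
    }
  }
  Ts <- seq(T_range[1], T_range[2], by = step)
  v <- vapply(Ts, ind_value, numeric(1))
  for (i in seq_len(length(Ts) - 1)) {
    if (is.na(v[i]) || is.na(v[i + 1])) next
    if (v[i] == 0 || sign(v[i]) == sign(v[i + 1])) next
    # indicator is biomass(larger unit) - biomass(smaller unit)
    dir_i <- if (v[i] > 0) "to-smaller" else "to-larger"
    if (direction != "any" && dir_i != direction) next
    return(.bisect_T(ind_value, Ts[i], Ts[i + 1], tol_T))
  }
  NA_real_
}
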