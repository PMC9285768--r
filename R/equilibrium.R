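#' Control settings of the equilibrium engine
#'
#' @param rtol_ode,atol_ode integrator tolerances.
#' @param t_chunk initial integration window, days; doubled between windows.
#' @param t_max maximum total integration time, days.
#' @param res_rtol convergence: max |rhs| below \code{res_rtol * max(state)}.
#' @param eps_ext extinction threshold as a fraction of \code{rmax_ref};
#'   compartments below it are truncated to exactly zero.
#' @param newton_max maximum Newton polishing iterations.
#' @param percap_tol maximum absolute per-capita growth rate (per day) a
#'   non-zero consumer compartment may have at an accepted equilibrium;
#'   compartments declining faster are transient remnants of competitive
#'   exclusion and are truncated.
#' @param stability_margin eigenvalue real-part margin for stability.
#' @param cluster_tol relative L-infinity distance under which two
#'   equilibria count as the same state.
#' @return list of control values.
#' @export
eq_control <- function(rtol_ode = 1e-8, atol_ode = 1e-12, t_chunk = 500,
                       t_max = 1e5, res_rtol = 1e-9, eps_ext = 1e-9,
                       newton_max = 40, percap_tol = 1e-6,
                       stability_margin = 1e-8, cluster_tol = 1e-4) {
  list(rtol_ode = rtol_ode, atol_ode = atol_ode, t_chunk = t_chunk,
       t_max = t_max, res_rtol = res_rtol, eps_ext = eps_ext,
       newton_max = newton_max, percap_tol = percap_tol,
       stability_margin = stability_margin, cluster_tol = cluster_tol)
}

.jacobian_num <- function(y, rates, active) {
  n <- length(active)
  J <- matrix(0, n, n)
  for (k in seq_len(n)) {
    i <- active[k]
    h <- max(1e-7 * abs(y[i]), 1e-9)
    yp <- y; yp[i] <- y[i] + h
    ym <- y; ym[i] <- max(y[i] - h, 0)
    hh <- yp[i] - ym[i]
    J[, k] <- (.rhs_core(yp, rates)[active] - .rhs_core(ym, rates)[active]) / hh
  }
  J
}

.newton_polish <- function(y, rates, ctrl) {
  eps <- ctrl$eps_ext * rates$Rmax_ref
  cons <- seq_along(y)[-(1:2)]
  y[cons][y[cons] < eps] <- 0
  ok <- TRUE
  for (outer in seq_len(2 + length(cons))) {
    active <- c(1:2, cons[y[cons] > 0])
    ok <- TRUE
    for (it in seq_len(ctrl$newton_max)) {
      f <- .rhs_core(y, rates)[active]
      if (max(abs(f)) < 0.1 * ctrl$res_rtol * max(y, 1)) break
      J <- .jacobian_num(y, rates, active)
      step <- tryCatch(solve(J, -f), error = function(e) NULL)
      if (is.null(step)) { ok <- FALSE; break }
      # damp so no active compartment overshoots below zero
      tmax <- 1
      neg <- step < 0 & y[active] > 0
      if (any(neg)) tmax <- min(1, 0.9 * min(y[active][neg] / -step[neg]))
      y[active] <- pmax(y[active] + tmax * step, 0)
    }
    trunc <- cons[y[cons] > 0 & y[cons] < eps]
    # per-capita residual: a positive consumer compartment whose biomass
    # still changes per capita is a transient remnant, not an equilibrium;
    # declining remnants (slow competitive exclusion) are truncated
    dy <- .rhs_core(y, rates)
    pos <- cons[y[cons] > 0]
    percap <- dy[pos] / y[pos]
    trunc <- union(trunc, pos[percap < -ctrl$percap_tol])
    if (any(percap > ctrl$percap_tol)) ok <- FALSE  # invasion still underway
    if (length(trunc) == 0) break
    y[trunc] <- 0
  }
  if (ok) {
    dy <- .rhs_core(y, rates)
    pos <- cons[y[cons] > 0]
    if (length(pos) > 0 && any(abs(dy[pos] / y[pos]) > ctrl$percap_tol))
      ok <- FALSE
    if (max(abs(dy)) > ctrl$res_rtol * max(y, 1)) ok <- FALSE
  }
  attr(y, "ok") <- ok
  y
}

#' Find a stable state of a configured community
#'
#' Integrates the community ODE forward in doubling time windows until the
#' residual \code{max |rhs|} contracts, then polishes the state with a
#' damped Newton solve restricted to non-extinct compartments. Compartments
#' below the extinction threshold are truncated to exactly zero and the
#' residual re-verified. If the trajectory does not settle within the time
#' horizon and its running window keeps oscillating, the outcome is
#' reported as a non-equilibrium attractor with the time-averaged state
#' (not an error).
#'
#' @param config a [community_config()].
#' @param initial_state named non-negative state vector; defaults to the
#'   \code{"inoculum"} canonical start.
#' @param control an [eq_control()] list.
#' @return object of class \code{"equilibrium_result"}: \code{state},
#'   \code{residual}, \code{converged}, \code{attractor}, \code{stable},
#'   \code{persistent} (consumer compartments above the extinction
#'   threshold), \code{classification}, \code{t_integrated}.
#' @export
find_equilibrium <- function(config, initial_state = NULL,
                             control = eq_control()) {
  rates <- compute_rates(config)
  rates$Rmax_ref <- config$params$rmax_ref
  if (is.null(initial_state)) initial_state <- initial_states(config)
  y <- initial_state[rates$labels]
  if (any(is.na(y))) stop("initial state labels do not match the configuration")
  if (any(y < 0)) stop("initial state entries must be non-negative")

  func <- function(t, yy, parms) list(unname(.rhs_core(pmax(yy, 0), rates)))
  t_tot <- 0; chunk <- control$t_chunk
  converged <- FALSE
  while (t_tot < control$t_max) {
    sol <- deSolve::lsoda(unname(y), c(0, chunk), func, parms = NULL,
                          rtol = control$rtol_ode, atol = control$atol_ode,
                          maxsteps = 50000)
    if (any(!is.finite(sol[nrow(sol), -1])))
      stop("state diverged to non-finite values during integration")
    ynew <- pmax(sol[nrow(sol), -1], 0)
    names(ynew) <- rates$labels
    t_tot <- t_tot + chunk
    y <- ynew
    res <- max(abs(.rhs_core(y, rates)))
    if (res < 1e-4 * max(y, 1)) {
      yp <- .newton_polish(y, rates, control)
      if (isTRUE(attr(yp, "ok"))) {
        attr(yp, "ok") <- NULL
        y <- yp; res <- max(abs(.rhs_core(y, rates))); converged <- TRUE
        break
      }
    }
    chunk <- min(chunk * 2, control$t_max - t_tot + 1)
  }

  attractor <- "equilibrium"
  if (!converged) {
    # probe for a cycle: compare state ranges over two long windows
    probe <- function(y0) {
      tt <- seq(0, 2000, by = 10)
      s <- deSolve::lsoda(unname(y0), tt, func, parms = NULL,
                          rtol = control$rtol_ode, atol = control$atol_ode,
                          maxsteps = 50000)
      s[, -1, drop = FALSE]
    }
    s1 <- probe(y); s2 <- probe(pmax(s1[nrow(s1), ], 0))
    amp1 <- apply(s1, 2, function(v) diff(range(v)))
    amp2 <- apply(s2, 2, function(v) diff(range(v)))
    if (max(amp2) > 1e-6 * max(y, 1) && max(amp2) > 0.5 * max(amp1)) {
      attractor <- "nonequilibrium"
      y <- colMeans(s2)
      names(y) <- rates$labels
    } else {
      y <- pmax(s2[nrow(s2), ], 0)
      names(y) <- rates$labels
      yp <- .newton_polish(y, rates, control)
      if (isTRUE(attr(yp, "ok"))) {
        attr(yp, "ok") <- NULL
        y <- yp; converged <- TRUE
      }
    }
  }
  res <- max(abs(.rhs_core(y, rates)))
  eps <- control$eps_ext * rates$Rmax_ref
  y[rates$ids][y[rates$ids] < eps] <- 0
  persistent <- rates$ids[y[rates$ids] > 0]
  stable <- if (converged) stability_check(config, y, control) else NA

  out <- list(state = y, residual = res, converged = converged,
              attractor = attractor, stable = stable,
              persistent = persistent,
              classification = classify_state_vector(y, config, eps),
              t_integrated = t_tot)
  class(out) <- "equilibrium_result"
  out
}

#' @export
print.equilibrium_result <- function(x, ...) {
  cat(sprintf("%s (residual %.2e, %s, %s)\n",
              x$attractor, x$residual,
              if (isTRUE(x$stable)) "stable" else if (isFALSE(x$stable)) "unstable" else "stability indeterminate",
              x$classification$label))
  print(signif(x$state, 6))
  invisible(x)
}

#' Closed-form equilibrium of one unstructured consumer on one resource
#'
#' With a single unstructured consumer feeding with preference p on a single
#' semichemostat resource, the model reduces to a Rosenzweig-MacArthur
#' system with non-oscillatory resource supply and its equilibrium is
#' closed-form. For the shared-H (encounter-weighted) response the consumer
#' nullcline gives \code{R* = H q / (p (beta Imax - q))} with
#' \code{q = m + mu}; for the independent-Monod response
#' \code{R* = H q / (p beta Imax - q)}. In both cases the consumer biomass
#' follows from the supply balance, \code{C* = beta delta (Rmax - R*) / q}.
#' If the consumer cannot persist (\code{R* >= Rmax} or negative), the
#' consumer-free equilibrium is returned with \code{viable = FALSE}.
#'
#' @param params a [default_parameters()] set.
#' @param p diet preference weight on the resource.
#' @param T temperature, degrees C.
#' @param M consumer dry body mass, ug.
#' @param resource \code{"RS"} or \code{"RL"}.
#' @return list with \code{R_star}, \code{C_star}, \code{viable}.
#' @export
analytic_equilibrium_1C1R <- function(params, p, T, M = 1, resource = "RS") {
  Imax <- max_ingestion_rate(M, T, params)
  m <- metabolic_rate(M, T, params)
  Rmax <- resource_carrying_capacity(resource, T, params)
  q <- m + params$mu
  denom <- if (params$response_form == "shared") {
    p * (params$beta * Imax - q)
  } else {
    p * params$beta * Imax - q
  }
  if (denom <= 0)
    return(list(R_star = Rmax, C_star = 0, viable = FALSE))
  R_star <- params$H * q / denom
  if (R_star >= Rmax)
    return(list(R_star = Rmax, C_star = 0, viable = FALSE))
  C_star <- params$beta * params$delta * (Rmax - R_star) / q
  list(R_star = R_star, C_star = C_star, viable = TRUE)
}

#' Linear stability of an equilibrium state
#'
#' Numerical Jacobian of the right-hand side (central finite differences)
#' restricted to the persistent compartments (resources plus consumers
#' above the extinction threshold); the state is stable iff every
#' eigenvalue real part lies below \code{-stability_margin}.
#'
#' @param config a [community_config()].
#' @param state named equilibrium state vector.
#' @param control an [eq_control()] list.
#' @return \code{TRUE}, \code{FALSE}, or \code{NA} if the Jacobian
#'   eigenproblem fails (with a warning).
#' @export
stability_check <- function(config, state, control = eq_control()) {
  rates <- compute_rates(config)
  y <- state[rates$labels]
  eps <- control$eps_ext * config$params$rmax_ref
  cons <- seq_along(y)[-(1:2)]
  active <- c(1:2, cons[y[cons] > eps])
  J <- .jacobian_num(y, rates, active)
  ev <- tryCatch(eigen(J, only.values = TRUE)$values,
                 error = function(e) NULL)
  if (is.null(ev) || any(!is.finite(Re(ev)))) {
    warning("ill-conditioned Jacobian; stability indeterminate")
    return(NA)
  }
  all(Re(ev) < -control$stability_margin)
}

#' Distinct stable states from multiple starts
#'
#' Runs [find_equilibrium()] from the canonical starts (inoculum,
#' juvenile-heavy, adult-heavy, low, high) plus seeded log-uniform random
#' starts, clusters the converged stable outcomes by relative L-infinity
#' distance, and returns the de-duplicated states.
#'
#' @param config a [community_config()].
#' @param n_random number of random starts.
#' @param seed integer seed for the random starts.
#' @param control an [eq_control()] list.
#' @return list of distinct stable \code{"equilibrium_result"} objects;
#'   attribute \code{"n_starts"} records how many starts were run.
#' @export
multistart_equilibria <- function(config, n_random = 4, seed = 1,
                                  control = eq_control()) {
  variants <- c("inoculum", "juvenile-heavy", "adult-heavy", "low", "high")
  starts <- lapply(variants, function(v) initial_states(config, v))
  if (n_random > 0)
    starts <- c(starts, lapply(seq_len(n_random), function(i)
      initial_states(config, "random", seed = seed + i)))
  results <- lapply(starts, function(y0)
    find_equilibrium(config, y0, control))
  keep <- Filter(function(r) r$converged && isTRUE(r$stable), results)
  distinct <- list()
  for (r in keep) {
    dup <- FALSE
    for (d in distinct) {
      sc <- max(abs(r$state), abs(d$state), 1e-8)
      if (max(abs(r$state - d$state)) / sc < control$cluster_tol) {
        dup <- TRUE; break
      }
    }
    if (!dup) distinct[[length(distinct) + 1]] <- r
  }
  attr(distinct, "n_starts") <- length(starts)
  attr(distinct, "seed") <- seed
  distinct
}
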