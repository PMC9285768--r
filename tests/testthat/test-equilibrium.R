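# a Community I configuration reduced to one consumer on one resource:
# the large resource has zero supply and the large consumer starts extinct
one_consumer_config <- function(pars, p, T) {
  community_config("I", p, T, params = pars,
                   overrides = list(absent_resources = "RL"))
}

one_consumer_start <- function(cfg) {
  y <- initial_states(cfg, "inoculum")
  y["CL"] <- 0
  y
}

test_that("the numerical equilibrium matches the closed-form single-consumer solution", {
  for (seed in 1:12) {
    d <- draw_1c1r(seed)
    cfg <- one_consumer_config(d$pars, d$p, d$T)
    eq <- find_equilibrium(cfg, one_consumer_start(cfg))
    expect_true(eq$converged)
    expect_equal(unname(eq$state["RS"]), d$an$R_star, tolerance = 1e-6)
    expect_equal(unname(eq$state["CS"]), d$an$C_star, tolerance = 1e-6)
    # substituting the closed form back into the dynamics gives zero
    y <- eq$state
    y["RS"] <- d$an$R_star; y["CS"] <- d$an$C_star
    expect_lt(max(abs(community_rhs(y, cfg))), 1e-10 * max(y))
  }
})

test_that("the closed form hits the half-saturation and invasion-threshold identities", {
  pars <- default_parameters()
  # p*beta*Imax = 2(m+mu)  =>  R* = H (for the independent-Monod variant)
  pars$response_form <- "independent"
  m <- metabolic_rate(1, 20, pars)
  q <- m + pars$mu
  Imax <- max_ingestion_rate(1, 20, pars)  # = imax_coeff at the optimum
  p_half <- 2 * q / (pars$beta * Imax)
  an <- analytic_equilibrium_1C1R(pars, p_half, 20)
  expect_equal(an$R_star, pars$H, tolerance = 1e-12)
  # below the invasion threshold the consumer-free branch is returned
  p_thr <- q / (pars$beta * Imax)
  an2 <- analytic_equilibrium_1C1R(pars, p_thr * 0.999, 20)
  expect_false(an2$viable)
  expect_equal(an2$C_star, 0)
  expect_equal(an2$R_star, resource_carrying_capacity("RS", 20, pars))
})

test_that("resource-only equilibria are stable with supply-rate eigenvalues", {
  cfg <- community_config("I", 0.85, 25)
  eq <- find_equilibrium(cfg, initial_states(cfg, "resource-only"))
  expect_true(eq$converged)
  expect_equal(unname(eq$state[c("CS", "CL")]), c(0, 0))
  expect_true(eq$stable)
  # the resource subsystem is linear with relaxation rate delta
  r <- compute_rates(cfg)
  J <- thermostage:::.jacobian_num(eq$state, r, 1:2)
  expect_equal(sort(Re(eigen(J)$values)), rep(-cfg$params$delta, 2),
               tolerance = 1e-6)
})

test_that("find_equilibrium is idempotent and deterministic", {
  cfg <- community_config("II", 0.85, 28)
  eq <- find_equilibrium(cfg)
  eq2 <- find_equilibrium(cfg, eq$state)
  expect_equal(eq2$state, eq$state, tolerance = 1e-8)
  eq3 <- find_equilibrium(cfg)
  expect_identical(eq$state, eq3$state)
})

test_that("equilibria satisfy the residual tolerance and extinction-threshold consistency", {
  cfg <- community_config("I", 0.6, 30)
  eq <- find_equilibrium(cfg)
  expect_lt(eq$residual, 1e-8 * max(eq$state))
  # re-solving after truncating the extinct compartment gives the same labels
  y <- eq$state
  eq2 <- find_equilibrium(cfg, y)
  expect_identical(eq2$classification$label, eq$classification$label)
})

test_that("a slowly excluded competitor is not reported as coexisting", {
  # complete niche overlap: two consumers on one effective resource cannot
  # coexist at equilibrium
  for (T in c(10, 20, 30)) {
    eq <- find_equilibrium(community_config("I", 0.5, T))
    expect_length(eq$classification$persistent_species, 1)
  }
})

test_that("multistart finds a unique state in Community I and alternative states in Community II", {
  cfg1 <- community_config("I", 0.85, 25)
  ms1 <- multistart_equilibria(cfg1, n_random = 4, seed = 1)
  expect_length(ms1, 1)
  expect_true(ms1[[1]]$stable)
  # stage-structured community, weak stage competition, warm: two attractors
  cfg2 <- community_config("II", 0.95, 29)
  ms2 <- multistart_equilibria(cfg2, n_random = 4, seed = 1)
  expect_length(ms2, 2)
  doms <- sort(vapply(ms2, function(r) r$classification$stage_dominance[["C"]],
                      character(1)))
  expect_identical(doms, c("adult", "juvenile"))
  # determinism under a fixed seed
  ms2b <- multistart_equilibria(cfg2, n_random = 4, seed = 1)
  expect_identical(lapply(ms2b, function(r) r$state),
                   lapply(ms2, function(r) r$state))
})

test_that("consumers are extinct at 45 C under the interaction parameterization", {
  for (p in c(0.6, 0.85, 1)) {
    eq <- find_equilibrium(community_config("I", p, 45))
    expect_identical(eq$classification$label, "consumers-extinct")
  }
})
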