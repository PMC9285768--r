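test_that("state classification covers extinction, dominance and ties", {
  cfg <- community_config("I", 0.85, 25)
  expect_identical(
    classify_state_vector(c(RS = 50, RL = 50, CS = 0, CL = 0), cfg)$label,
    "consumers-extinct")
  cl <- classify_state_vector(c(RS = 5, RL = 5, CS = 10, CL = 30), cfg)
  expect_identical(cl$species_dominance, "CL")
  expect_identical(
    classify_state_vector(c(RS = 5, RL = 5, CS = 10, CL = 10), cfg)$species_dominance,
    "balanced")
  cfg2 <- community_config("II", 0.85, 25)
  cl2 <- classify_state_vector(c(RS = 5, RL = 5, J = 2, A = 30), cfg2)
  expect_identical(unname(cl2$stage_dominance["C"]), "adult")
  # single persistent species in a two-species community
  cl3 <- classify_state_vector(c(RS = 5, RL = 5, CS = 10, CL = 0), cfg)
  expect_identical(cl3$persistent_species, "CS")
  expect_identical(cl3$species_dominance, "CS")
})

test_that("the refined persistence boundary at p = 1 matches the scalar invasion criterion", {
  # decoupled consumer: persistence ends where assimilation on the resource
  # at carrying capacity balances metabolism plus mortality -- a scalar root
  # found independently of the equilibrium engine
  pars <- default_parameters()
  g <- function(T) {
    Rm <- resource_carrying_capacity("RS", T, pars)
    pars$beta * max_ingestion_rate(1, T, pars) * Rm / (pars$H + Rm) -
      metabolic_rate(1, T, pars) - pars$mu
  }
  T_oracle <- uniroot(g, c(30, 45), tol = 1e-10)$root
  pb <- persistence_boundary(sc_I_on, "CS", T_range = c(36, 44),
                             p_range = c(0.9, 1), n_grid = c(9, 2),
                             tol_T = 0.02)
  T_mapped <- max(pb$T[pb$p == 1 & pb$direction == "upper"])
  expect_equal(T_mapped, T_oracle, tolerance = 0.002)
})

test_that("boundary subjects and levels are validated", {
  expect_error(
    persistence_boundary(sc_I_on, "XX", T_range = c(20, 25),
                         n_grid = c(2, 2)),
    "not a species or compartment")
  expect_error(
    dominance_boundary(sc_I_on, level = "stage", T_range = c(20, 25),
                       n_grid = c(2, 2)),
    "unstructured")
})

test_that("a subject persistent on the whole grid yields an empty curve", {
  pb <- persistence_boundary(sc_I_on, "CS", T_range = c(15, 25),
                             p_range = c(0.8, 0.9), n_grid = c(4, 2),
                             tol_T = 0.1)
  expect_identical(nrow(pb), 0L)
})

test_that("a fully symmetric community is balanced everywhere", {
  sc_sym <- scenario("I", topt_interaction = FALSE, rmax_interaction = FALSE,
                     overrides = list(masses = c(CS = 2, CL = 2)))
  cfg <- scenario_config(sc_sym, 0.8, 22)
  eq <- find_equilibrium(cfg)
  expect_identical(eq$classification$species_dominance, "balanced")
  db <- dominance_boundary(sc_sym, "species", T_range = c(18, 26),
                           p_range = c(0.7, 0.9), n_grid = c(3, 2),
                           tol_T = 0.2)
  expect_identical(nrow(db), 0L)
})

test_that("the Community I dominance boundary separates large-dominated cold from small-dominated warm water", {
  db <- dominance_boundary(sc_I_on, "species", T_range = c(20, 34),
                           p_range = c(0.85, 0.85), n_grid = c(8, 2),
                           tol_T = 0.05)
  expect_identical(nrow(db), 2L)  # two identical p rows
  Tb <- db$T[1]
  expect_gt(Tb, 20); expect_lt(Tb, 34)
  cfg_cool <- scenario_config(sc_I_on, 0.85, Tb - 2)
  cfg_warm <- scenario_config(sc_I_on, 0.85, Tb + 2)
  expect_identical(find_equilibrium(cfg_cool)$classification$species_dominance, "CL")
  expect_identical(find_equilibrium(cfg_warm)$classification$species_dominance, "CS")
})

test_that("the plane raster is label-consistent with its boundaries and handles empty communities", {
  # raster cells adjacent across the dominance boundary carry different labels
  m <- map_T_p_plane(sc_I_on, T_range = c(24, 30), p_range = c(0.85, 0.9),
                     n_grid = c(4, 2))
  expect_identical(nrow(m), 8L)
  doms <- m$species_dominance[m$p == 0.85]
  expect_true("CL" %in% doms && "CS" %in% doms)
  # consumers cannot invade anywhere: uniform raster
  sc_dead <- scenario("I", overrides = list(metab_coeff = 10))
  m2 <- map_T_p_plane(sc_dead, T_range = c(10, 30), p_range = c(0.6, 0.9),
                      n_grid = c(3, 2))
  expect_identical(unique(m2$label), "consumers-extinct")
})
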