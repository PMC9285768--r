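test_that("diet weights honor the community-specific anchor points", {
  expect_equal(diet_weights("I", "CS", 1), c(RS = 1, RL = 0))
  expect_equal(diet_weights("I", "CL", 1), c(RS = 0, RL = 1))
  expect_equal(diet_weights("I", "CS", 0.5), c(RS = 0.5, RL = 0.5))
  expect_equal(diet_weights("I", "CL", 0.5), c(RS = 0.5, RL = 0.5))
  expect_equal(diet_weights("II", "J", 0.85), c(RS = 0.85, RL = 0.15))
  # Community III: identical mid-size diets at p = 0, disjoint at p = 1
  expect_equal(diet_weights("III", "AS", 0), c(RS = 0.5, RL = 0.5))
  expect_equal(diet_weights("III", "JL", 0), c(RS = 0.5, RL = 0.5))
  expect_equal(diet_weights("III", "AS", 1), c(RS = 1, RL = 0))
  expect_equal(diet_weights("III", "JL", 1), c(RS = 0, RL = 1))
  expect_equal(diet_weights("III", "JS", 0.3), c(RS = 1, RL = 0))
  # swap scheme: no intraspecific overlap at p = 0
  expect_equal(diet_weights("III", "AS", 0, scheme = "swap"), c(RS = 0, RL = 1))
  expect_error(diet_weights("I", "CS", 0.3), "range")
  expect_error(diet_weights("III", "XX", 0.5), "unknown compartment")
  # weights always sum to one
  for (p in c(0, 0.25, 0.5, 0.75, 1))
    for (id in c("JS", "AS", "JL", "AL"))
      expect_equal(sum(diet_weights("III", id, p)), 1)
})

test_that("the functional response satisfies the Monod identities", {
  expect_equal(functional_response(c(0.7, 0.3), 0, 0, 1.5, 50)$total, 0)
  fr <- functional_response(c(1, 0), 50, 77, 1.5, 50)
  expect_equal(fr$total, 0.75)
  fr2 <- functional_response(c(0.5, 0.5), 50, 50, 1.5, 50)
  expect_equal(fr2$total, 0.75)
  expect_equal(unname(fr2$per_resource), c(0.375, 0.375))
  # same identities for the independent-Monod form
  fr3 <- functional_response(c(0.5, 0.5), 50, 50, 1.5, 50, form = "independent")
  expect_equal(fr3$total, 0.75)
  # split sums to total, total below Imax
  fr4 <- functional_response(c(0.85, 0.15), 120, 30, 1.5, 50)
  expect_equal(sum(fr4$per_resource), fr4$total)
  expect_lt(fr4$total, 1.5)
  expect_error(functional_response(c(0.5, 0.5), 10, 10, 1.5, -1), "H")
})

test_that("net production is assimilation minus metabolism", {
  expect_equal(net_production(0.6, 1.0, 0.2), 0.4)
  expect_equal(net_production(0.5, 0.4, 0.2), 0)
  expect_equal(net_production(0.6, 0, 0.2), -0.2)
  expect_error(net_production(1.2, 1, 0.1), "beta")
})

test_that("maturation rate has the right limits, clamping, and removable singularity", {
  expect_identical(maturation_rate(0, 0.01, 0.1), 0)
  expect_identical(maturation_rate(-0.5, 0.01, 0.1), 0)
  # removable singularity at nu == mu: limit mu / ln(1/z)
  expect_equal(maturation_rate(0.01, 0.01, 0.1), 0.00434294481903,
               tolerance = 1e-10)
  # numeric approach to the singular point from both sides
  for (eps in 10^-(4:7)) {
    expect_equal(maturation_rate(0.01 + eps, 0.01, 0.1), 0.01 / log(10),
                 tolerance = 1e-2)
    expect_equal(maturation_rate(0.01 - eps, 0.01, 0.1), 0.01 / log(10),
                 tolerance = 1e-2)
  }
  # nu >> mu: gamma -> (nu - mu)/(1 - z)
  expect_equal(maturation_rate(10, 0.01, 0.1), (10 - 0.01) / 0.9,
               tolerance = 1e-3)
  expect_true(all(maturation_rate(seq(-1, 1, by = 0.01), 0.01, 0.1) >= 0))
  expect_error(maturation_rate(0.1, 0.01, 1.5), "z")
})

test_that("the semichemostat rest point and supply-only limits hold", {
  cfg <- community_config("I", 0.85, 25)
  r <- compute_rates(cfg)
  y <- initial_states(cfg, "resource-only")
  expect_equal(unname(community_rhs(y, cfg)), rep(0, 4))
  y2 <- y; y2["RS"] <- 0
  d <- community_rhs(y2, cfg)
  expect_equal(unname(d["RS"]), cfg$params$delta * unname(r$Rmax["RS"]))
  expect_error(community_rhs(c(RS = -1, RL = 1, CS = 1, CL = 1), cfg),
               "non-negative")
})

test_that("total biomass is conserved when conversion is perfect and all losses are off", {
  for (kind in c("I", "II", "III")) {
    cfg <- community_config(kind, 0.8, 25,
                            overrides = list(mu = 0, beta = 1, delta = 0,
                                             metab_coeff = 1e-300))
    set.seed(42)
    for (i in 1:5) {
      y <- initial_states(cfg, "random", seed = i)
      d <- community_rhs(y, cfg)
      expect_lt(abs(sum(d)), 1e-10 * max(y))
    }
  }
})

test_that("a mirrored equal-mass pair in Community I is dynamically neutral", {
  cfg <- community_config("I", 0.8, 23,
                          overrides = list(masses = c(CS = 2, CL = 2),
                                           rmax_interaction = FALSE),
                          rmax_interaction = FALSE)
  y <- c(RS = 40, RL = 70, CS = 12, CL = 5)
  d <- community_rhs(y, cfg)
  yswap <- c(RS = 70, RL = 40, CS = 5, CL = 12)
  dswap <- community_rhs(yswap, cfg)
  expect_equal(unname(d[c("RS", "RL", "CS", "CL")]),
               unname(dswap[c("RL", "RS", "CL", "CS")]))
})

test_that("maturation flux out of juveniles equals the flux into adults", {
  cfg <- community_config("II", 0.85, 25)
  r <- compute_rates(cfg)
  set.seed(7)
  for (i in 1:5) {
    y <- initial_states(cfg, "random", seed = i)
    d <- community_rhs(y, cfg)
    # remove all non-maturation terms from each stage balance; what is left
    # must be equal and opposite
    fr <- lapply(c("J", "A"), function(id) {
      w <- cfg$compartments[[id]]$weights
      functional_response(w, y["RS"], y["RL"], r$Imax[id], r$H)$total
    })
    nuJ <- r$beta * fr[[1]] - r$m["J"]
    nuA <- r$beta * fr[[2]] - r$m["A"]
    out_J <- max(nuA, 0) * y["A"] + nuJ * y["J"] - r$mu["J"] * y["J"] - d["J"]
    in_A <- d["A"] - min(nuA, 0) * y["A"] + r$mu["A"] * y["A"]
    expect_equal(unname(out_J), unname(in_A), tolerance = 1e-8)
  }
})

test_that("ingestion depletes exactly the resources that feed the consumer", {
  cfg <- community_config("III", 1, 25)  # JS/AS on RS only, JL/AL on RL only
  y <- initial_states(cfg, "inoculum")
  base <- community_rhs(y, cfg)
  y2 <- y; y2["AL"] <- y["AL"] + 1
  d2 <- community_rhs(y2, cfg)
  expect_lt(d2["RL"], base["RL"])     # AL grazes RL
  expect_equal(unname(d2["RS"]), unname(base["RS"]))  # but not RS
})
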