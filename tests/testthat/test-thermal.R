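test_that("Arrhenius factor has the reference identity and the correct value", {
  expect_identical(arrhenius_factor(20, 0.56, 20), 1)
  expect_identical(arrhenius_factor(30, 0, 20), 1)
  # direct evaluation of exp((E/k)(1/T_ref - 1/T)) in Kelvin
  expect_equal(arrhenius_factor(30, 0.56, 20), 2.07774109501, tolerance = 1e-10)
  # strictly increasing in T for E > 0; log-linear in 1/T_K
  Ts <- seq(0, 45, by = 5)
  f <- arrhenius_factor(Ts, 0.56, 20)
  expect_true(all(diff(f) > 0))
  fit <- lm(log(f) ~ I(1 / (Ts + 273.15)))
  expect_lt(max(abs(residuals(fit))), 1e-12)
  expect_error(arrhenius_factor(NA_real_, 0.56, 20), "finite")
  expect_error(arrhenius_factor(100, 0.56, 20), "range")
})

test_that("ingestion optima reproduce the 24/20/16 C triplet and collapse without the interaction", {
  pars_on <- default_parameters()
  pars_off <- default_parameters(topt_interaction = FALSE)
  expect_equal(topt_for_mass(c(0.1, 1, 10), pars_on), c(24, 20, 16))
  expect_equal(topt_for_mass(c(0.1, 5, 10), pars_off), c(20, 20, 20))
  expect_error(topt_for_mass(-1, pars_on), "positive")
})

test_that("maximum ingestion peaks at the optimum, is symmetric, and scales as M^(0.7-1)", {
  pars <- default_parameters()
  expect_equal(max_ingestion_rate(1, 20, pars), pars$imax_coeff)
  for (d in c(1, 5, 12)) {
    expect_equal(max_ingestion_rate(10, 16 + d, pars),
                 max_ingestion_rate(10, 16 - d, pars))
  }
  # mass-specific power law at matched offset from each optimum
  ratio <- max_ingestion_rate(10, 16 + 3, pars) / max_ingestion_rate(1, 20 + 3, pars)
  expect_equal(ratio, 10^(-0.3), tolerance = 1e-12)
  # maximal exactly at the optimum
  Ts <- seq(0, 45, by = 0.5)
  i10 <- max_ingestion_rate(10, Ts, pars)
  expect_equal(Ts[which.max(i10)], 16)
})

test_that("metabolism scales allometrically and gains a temperature-dependent exponent only when enabled", {
  pars <- default_parameters()
  expect_equal(metabolic_rate(1, 20, pars), pars$metab_coeff)
  for (T in c(5, 20, 35)) {
    expect_equal(metabolic_rate(10, T, pars) / metabolic_rate(1, T, pars),
                 10^(-0.3), tolerance = 1e-12)
  }
  pars_x <- default_parameters(metab_exponent_interaction = TRUE)
  expect_gt(pars_x$metab_exponent_slope, 0)
  lr <- sapply(c(10, 20, 30, 40), function(T)
    metabolic_rate(10, T, pars_x) / metabolic_rate(1, T, pars_x))
  expect_true(all(diff(lr) > 0))  # large consumers penalized when warm
})

test_that("resource carrying capacities decline with warming and cross at 20 C", {
  pars <- default_parameters()
  expect_equal(resource_carrying_capacity("RS", 20, pars), pars$rmax_ref)
  expect_equal(resource_carrying_capacity("RL", 20, pars), pars$rmax_ref)
  expect_lt(resource_carrying_capacity("RL", 30, pars),
            resource_carrying_capacity("RS", 30, pars))
  expect_gt(resource_carrying_capacity("RL", 10, pars),
            resource_carrying_capacity("RS", 10, pars))
  pars_off <- default_parameters(rmax_interaction = FALSE)
  Ts <- seq(0, 45, by = 5)
  expect_equal(resource_carrying_capacity("RS", Ts, pars_off),
               resource_carrying_capacity("RL", Ts, pars_off))
  expect_true(all(diff(resource_carrying_capacity("RS", Ts, pars)) < 0))
})

test_that("all rates are positive and finite over the working mass and temperature ranges", {
  pars <- default_parameters()
  grid <- expand.grid(M = c(0.01, 0.1, 1, 10, 100), T = seq(0, 45, by = 5))
  v <- with(grid, c(max_ingestion_rate(M, T, pars), metabolic_rate(M, T, pars)))
  expect_true(all(is.finite(v) & v > 0))
})
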