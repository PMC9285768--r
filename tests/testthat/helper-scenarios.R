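# shared scenario templates and a cache so expensive sweeps are computed once
sc_I_on <- scenario("I")
sc_I_off <- scenario("I", topt_interaction = FALSE, rmax_interaction = FALSE)
sc_II_on <- scenario("II")
sc_II_off <- scenario("II", topt_interaction = FALSE, rmax_interaction = FALSE)
sc_III_on <- scenario("III")

.sweep_cache <- new.env(parent = emptyenv())

cached_sweep <- function(key, sc, p = 0.85, T_grid = seq(2, 44, by = 2)) {
  if (is.null(.sweep_cache[[key]]))
    .sweep_cache[[key]] <- biomass_vs_temperature(sc, p = p, T_grid = T_grid)
  .sweep_cache[[key]]
}

# random viable parameter draw for the 1C1R oracle comparisons
draw_1c1r <- function(seed) {
  set.seed(seed)
  repeat {
    pars <- default_parameters()
    pars$imax_coeff <- runif(1, 0.8, 3)
    pars$metab_coeff <- runif(1, 0.02, 0.12)
    pars$H <- runif(1, 20, 120)
    pars$delta <- runif(1, 0.05, 0.3)
    pars$beta <- runif(1, 0.4, 0.9)
    pars$mu <- runif(1, 0.002, 0.03)
    pars$response_form <- sample(c("shared", "independent"), 1)
    attr(pars, "provenance")[c("imax_coeff", "metab_coeff", "H", "delta",
                               "beta", "mu")] <- "override"
    p <- runif(1, 0.5, 1)
    T <- runif(1, 10, 30)
    an <- analytic_equilibrium_1C1R(pars, p, T)
    if (an$viable && an$C_star > 1e-3) return(list(pars = pars, p = p, T = T, an = an))
  }
}
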