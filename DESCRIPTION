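Package: thermostage
Title: Stage-Structured Thermal Food-Web Models of Competing Zooplankton Grazers
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Bioenergetic food-web models of one or two zooplankton grazer
    species, unstructured or split into juvenile and adult stages, competing
    for two algal resources with semichemostat renewal. Consumer rates scale
    allometrically with body mass and with temperature (Arrhenius metabolism,
    unimodal ingestion), optionally with size-temperature interactions
    (size-dependent ingestion optima, resource-specific carrying-capacity
    decline, temperature-dependent metabolic allometry). Provides equilibrium
    computation with stability analysis and multistart detection of
    alternative stable states, persistence/dominance/bistability boundary
    mapping in temperature-by-diet-preference space, equilibrium biomass and
    mean-body-mass temperature sweeps, and a synthetic literature-review
    tally of warming effects on inter- and intraspecific size structure.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    deSolve,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
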