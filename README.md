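# thermostage

Stage-structured, temperature- and size-dependent bioenergetic food-web
models of competing zooplankton grazers on two algal resources — built to
ask how warming reshapes community size structure *between* species
(small vs large grazers) and *within* species (juvenile vs adult stages)
at the same time.

## The models

Two algal resources (small `RS`, large `RL`) renew by semichemostat
dynamics, `dR/dt = δ(Rmax(T) − R) − grazing`, with carrying capacities that
decline exponentially with warming and cross at 20 °C. Consumers feed with
a type-II (Monod) functional response weighted by a diet preference `p`
that couples small consumers to the small resource and large consumers to
the large one; net biomass production is `ν = βI − m`. Juvenile and adult
compartments of a structured species are linked by food-dependent
maturation `γ(ν_J, μ) = (ν_J − μ)/(1 − z^(1 − μ/ν_J))` and reproduction
(positive adult production becomes juvenile biomass instantly).

Rates scale with body mass (`M^0.7` whole-organism) and temperature:
Arrhenius metabolism (activation energy 0.56 eV) and unimodal ingestion.
Three optional **size–temperature interactions** make warming
size-selective: ingestion optima that fall with body mass (24/20/16 °C at
0.1/1/10 µg), a steeper carrying-capacity decline for the large resource,
and a metabolic allometric exponent that rises with temperature.

Three communities are prebuilt: **I** two unstructured species (1, 10 µg),
**II** one structured species (J 1 µg, A 10 µg), **III** two structured
species spanning 0.1–10 µg. The package finds their stable states
(integrate-then-polish with multistart detection of alternative stable
states), maps persistence/dominance/bistability boundaries in the
temperature × diet-preference plane, sweeps equilibrium biomass and mean
individual body mass along temperature, and ships a synthetic
literature-review table of warming-induced size-structure shifts with its
tally.

## Worked example

Community II (one stage-structured grazer) at 28 °C with moderate niche
separation between the stages (`p = 0.85`) and all size–temperature
interactions on:

```r
library(thermostage)
cfg <- community_config("II", p = 0.85, T = 28)
find_equilibrium(cfg)
#> equilibrium (residual 2.49e-11, stable, C;C:adult)
#>        RS        RL         J         A
#>  19.09650   5.88124  11.26370 131.79400

ms <- multistart_equilibria(cfg, n_random = 4, seed = 1)
length(ms)
#> [1] 2
sapply(ms, function(r) mean_body_mass(r$state, cfg))
#> [1] 5.852678 1.149789
```

This point sits inside the alternative-stable-state region: depending on
initial stage abundances the population locks into an adult-dominated
state (A ≈ 132, mean individual mass ≈ 5.9 µg) or a juvenile-dominated one
(J ≈ 79, mean mass ≈ 1.1 µg). Biomass units follow the resource carrying
capacity scale (100 at 20 °C); masses are µg dry weight.

The numbered scripts under `analysis/` run the full workflow — thermal
rate tables, temperature sweeps for Communities I/II with and without the
interactions, boundary maps, mean-body-mass trends, and the review tally —
writing flat tables to `results/`. For example:

```sh
Rscript analysis/02_equilibrium_sweeps.R
#> Community I: dominance shifts to the small species at 25.37 C
#> Community II: dominance shifts to adults at 27.32 C
#> Without the size-temperature interaction neither shift occurs: ...
```

Warming flips Community I toward the *smaller species* and Community II
toward the *larger (adult) stage* — and only when a size–temperature
interaction is present.

## Layout

- `R/` — model code: thermal/allometric rates, community configurations and
  ODE right-hand sides, equilibrium engine, boundary mappers, sweeps,
  review fixture.
- `analysis/` — numbered workflow scripts (thin drivers over the package).
- `tests/testthat/` — unit, property and end-to-end suites.
- `vignettes/stage-structured-thermal-foodwebs.Rmd` — model, calibration
  and numerical-methods documentation.
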