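---
title: "Stage-structured thermal food-web models: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stage-structured thermal food-web models: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thermostage)
```

## The scientific question

Warming changes the size structure of animal communities on two levels at
once: between species (relative abundance of small versus large species) and
within species (relative abundance of juvenile versus adult stages).
`thermostage` implements bioenergetic food-web models built to separate
these two levels for pelagic plankton: one or two zooplankton grazer
species, unstructured or split into juvenile and adult biomass compartments,
competing for two algal resources. The central contrast is between a
"classic" parameterization in which body mass and temperature act
independently on vital rates, and parameterizations with a
*size-temperature interaction* in which warming hits large consumers harder
than small ones.

## Model structure

**Resources.** Two algal resources, small `RS` and large `RL`, follow
semichemostat renewal

$$\frac{dR_j}{dt} = \delta\,(R_{j,\max}(T) - R_j) - \sum_i I_{ij}\,C_i ,$$

where the carrying capacity declines exponentially with warming,
$R_{j,\max}(T) = R_{\mathrm{ref}}\,e^{-c_j (T - 20)}$. Both resources share
$R_{\mathrm{ref}}$, so the two curves cross exactly at 20 °C. With the
resource interaction flag on, the large resource declines more steeply
($c_L > c_S$), so cold water is dominated by large algae and warm water by
small algae; with the flag off the resources are dynamically identical.

**Consumers.** Each consumer compartment $i$ (a species, or one stage of a
species) has dry body mass $M_i$ and diet weights $(w_{iS}, w_{iL})$ on the
two resources. Ingestion follows an encounter-weighted type-II (Monod)
response with a single half-saturation constant $H$:

$$E_i = w_{iS} R_S + w_{iL} R_L, \qquad
  I_{ij} = I_{\max,i}\,\frac{w_{ij} R_j}{H + E_i}.$$

An alternative form that saturates each resource separately
($I_{ij} = I_{\max,i} w_{ij} R_j/(H + R_j)$) is available as the
`response_form = "independent"` switch; all qualitative results reported by
the analysis scripts are unchanged under it. Net biomass production is
$\nu_i = \beta I_i - m_i$; unstructured consumers then follow
$dC_i/dt = (\nu_i - \mu) C_i$.

**Stage structure.** Juvenile and adult compartments of one species are
linked by food-dependent maturation and reproduction:

$$\frac{dJ}{dt} = \max(\nu_A, 0) A + \nu_J J - \max(\gamma_J, 0) J - \mu J,
\qquad
\frac{dA}{dt} = \max(\gamma_J, 0) J + \min(\nu_A, 0) A - \mu A,$$

with the standard stage-structured biomass-model maturation rate

$$\gamma(\nu_J, \mu) = \frac{\nu_J - \mu}{1 - z^{\,1 - \mu/\nu_J}},
\qquad z = M_J/M_A,$$

zero for starving juveniles ($\nu_J \le 0$) and continuously extended
through the removable singularity at $\nu_J = \mu$ (limit
$\mu/\ln(1/z)$; implemented with `expm1` so the extension is numerically
exact). Adults never grow: positive adult production appears instantly as
new juvenile biomass. When adults are the better competitors, maturation
limits the population and biomass accumulates in juveniles; when juveniles
are superior, reproduction limits it and biomass accumulates in adults.
This asymmetry is what lets warming shift stage structure.

**Communities.** Community I: two unstructured species (CS 1 µg, CL 10 µg).
Community II: one structured species (J 1 µg, A 10 µg, $z = 0.1$).
Community III: two structured species spanning three size classes
(JS 0.1 µg, AS 1 µg; JL 1 µg, AL 10 µg). The diet preference $p$ couples
each consumer to "its" resource: in I and II the small unit gets weights
$(p, 1-p)$ and the large unit $(1-p, p)$ with $p \in [0.5, 1]$; $p = 0.5$
is complete niche overlap and $p = 1$ fully separate niches. In Community
III, JS feeds only on RS and AL only on RL, while the equally sized AS and
JL split as $((1\pm p)/2, (1\mp p)/2)$ with $p \in [0, 1]$, so their diets
are literally identical at $p = 0$ and disjoint at $p = 1$. A `"swap"`
scheme (AS $(p, 1-p)$, JL $(1-p, p)$), under which *intraspecific* overlap
vanishes at $p = 0$ instead, is provided as a config switch; with only two
resources, "identical mid-size diets at $p = 0$" and "no intraspecific
overlap at $p = 0$" cannot both hold exactly, and the default honors the
first.

## Temperature and body-mass scaling

Whole-organism rates scale as $M^{0.7}$; because the state variables are
biomasses, all rate coefficients are mass-specific and carry $M^{0.7-1}$.

* **Metabolism** rises exponentially (Arrhenius) with activation energy
  0.56 eV, reference 20 °C:
  $m(M,T) = m_0 M^{e(T)-1} e^{(E/k)(1/T_{\mathrm{ref,K}} - 1/T_K)}$.
  With the metabolic-exponent interaction on, the allometric exponent
  itself warms: $e(T) = 0.7 + 0.01\,(T - 20)$, penalizing large consumers
  in warm water. Off (the default), $e \equiv 0.7$.
* **Maximum ingestion** is unimodal in temperature: a Gaussian kernel
  $\exp(-(T - T_{opt}(M))^2 / 2\sigma^2)$ around a mass-dependent optimum.
  With the optimum interaction on,
  $T_{opt}(M) = 20 - 4\log_{10} M$ °C, i.e. 24, 20 and 16 °C at 0.1, 1 and
  10 µg; off, all consumers peak at 20 °C. The Gaussian is the simplest
  symmetric shape satisfying every anchor the model must reproduce; an
  asymmetric kernel would change nothing reported here because all
  behavior is driven by the *relative* position of the optima.

Every interaction (resource decline, ingestion optimum, metabolic exponent)
can be toggled independently; any of them favors small consumers in warm
water, which is the mechanism behind every headline result.

## Parameter values and calibration

A complete empirically sourced parameter table is not bundled;
`default_parameters()` therefore supports two modes, recorded per value in
a provenance tag:

* a user-supplied YAML **transcription**, used verbatim
  (provenance `transcribed`), or
* the package's **calibrated defaults** (provenance `calibrated-default`).

The calibrated defaults are plankton-scale rates chosen once:
$\delta = 0.1\,d^{-1}$, $R_{\mathrm{ref}} = 100$ (biomass density units),
$H = 50$, $\beta = 0.6$, $\mu = 0.01\,d^{-1}$,
$I_{\max,0} = 1.5\,d^{-1}$ and $m_0 = 0.05\,d^{-1}$ at 1 µg and 20 °C,
$c_S = 0.01$, $c_L = 0.04\,°C^{-1}$ (equal when the resource interaction is
off). The thermal width is not free: $\sigma = 16.06996$ °C is solved so
that the 1-µg consumer's fundamental thermal niche on its own resource
closes at exactly 41.2 °C — the upper persistence limit of the small
consumer in Community I. Every anchor (the 24/20/16 °C optima, the 20 °C
resource crossover, the 41.2 °C limit, the dominance and stage shifts, the
high-$p$ bistability region and its disappearance under raised mortality)
is re-verified by the test suite, so a parameter edit that silently breaks
one fails the build.

One deliberate trade-off: with $\mu = 0.01\,d^{-1}$ the *small* species is
the superior competitor at complete niche overlap at every temperature, so
at $p = 0.5$ it monopolizes both cold and warm water. A much lower
mortality ($\lesssim 0.005\,d^{-1}$) hands the cold end to the large
species instead, but destabilizes the rest of the calibration (the
bistability region stops responding to mortality and limit cycles appear at
$p = 1$). Exclusion at $p = 0.5$ — the substantive claim — holds
regardless.

## Numerical methods

* **Equilibria** are found by integrate-then-polish: `deSolve::lsoda` in
  doubling time windows (500 d up to $10^5$ d) until the residual
  $\max|f|$ contracts, then a damped Newton solve (central-difference
  Jacobian) restricted to non-extinct compartments. Compartments below the
  extinction threshold $10^{-9} R_{\mathrm{ref}}$ are truncated to exactly
  zero. A compartment whose *per-capita* growth still exceeds
  $10^{-6}\,d^{-1}$ in magnitude is not at equilibrium: declining remnants
  of slow competitive exclusion are truncated and the solve repeated, so a
  competitor on its way out is never reported as coexisting. Trajectories
  that never settle are reported as non-equilibrium attractors with their
  time-averaged state (none arise on the default grids).
* **Stability** is judged from the eigenvalues of the numerical Jacobian on
  the persistent compartments (stable iff all real parts $< -10^{-8}$).
* **Alternative stable states** are detected by multistart: five canonical
  starts (inoculum, juvenile-heavy, adult-heavy, low, high) plus seeded
  log-uniform random starts, de-duplicated at relative $L_\infty$ distance
  $10^{-4}$.
* **Boundaries** in the $(T, p)$ plane (persistence, dominance,
  bistability) are located by scanning an indicator on a grid and refining
  every sign change by bisection in $T$; this replaces numerical
  continuation because every mapped boundary separates regions
  distinguishable from stable equilibria reached by forward integration.
  Dominance ties below relative $10^{-6}$ count as exactly balanced, so
  symmetric communities yield "balanced everywhere" rather than noise
  boundaries.
* **Sweeps** run forward and backward in temperature with warm-started
  equilibria (extinct compartments reseeded with a $10^{-3}$ inoculum so
  invasions are caught); where the directions disagree both branches are
  reported, which is how the hysteresis window of Community II appears.

The default grids in the analysis scripts (1–2 °C scan steps, preference
steps of 0.05–0.125, bisection to 0.01–0.05 °C) were chosen so the full
workflow runs in minutes in an interpreted language; all grids and
tolerances are arguments, and the refined boundary points do not move when
the scan grids are halved (only unresolved *additional* crossings could
appear, and the suite checks the ones that matter).

## The synthetic review table

The literature-review component ships as a generator, not data: 164
observations whose level × outcome marginals equal the published counts
(interspecific 123 = 91 smaller + 14 larger + 18 none; intraspecific 41 =
20 smaller + 17 larger + 4 none; 136 source articles recorded as metadata).
The experimental/observational split within each cell was never published
at that granularity; the fixture fixes a synthetic split in which the
smaller-shift excess is strongest among observational studies (68:6
observational vs 23:8 experimental within the interspecific level), and the
seed only shuffles observation ids. Analyses of the fixture are therefore
exact at the level × outcome margin and illustrative below it.

## What the tests do and do not show

The synthetic scenarios reproduce the *mechanistic* claims: equilibrium
structure, boundary topology, direction of dominance shifts, bistability
and its response to mortality, and the closed-form single-consumer
equilibrium to relative $10^{-6}$. They do not emulate features of real
plankton systems that the models deliberately omit: individual-level size
change (the temperature-size rule), explicit nutrient or light competition
between the algae, more than two resources or consumer species, seasonal
forcing, and temperature-dependent diet preference. Passing tests therefore
validate the implementation and its internal calibration, not a forecast
for any particular lake or sea.

## Known limitations

* Cycles: the equilibrium engine detects and labels non-equilibrium
  attractors but does not characterize them further; none occur at the
  default parameterization, and the bifurcation mapper assumes
  equilibrium-based indicators.
* The bistability boundary is defined by multistart basin detection, not by
  fold-point continuation; with the default start set the detected region
  is a (slightly conservative) subset of the true bistable set.
* At complete niche overlap the calibrated defaults make the small species
  the monopolist at every temperature (see the calibration trade-off
  above); which species holds the cold end at $p = 0.5$ is sensitive to
  the mortality-to-metabolism ratio and should not be over-interpreted.
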