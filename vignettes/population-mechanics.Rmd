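---
title: "Population mechanics: inertial models of T cell homeostasis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Population mechanics: inertial models of T cell homeostasis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(popmech)
```

## The modelling framework

`popmech` treats a population of T cells as a damped elastic system. The
motivation is physiological: homeostatic interleukins (IL-7, and IL-15
for memory cells) are concentrated in lymphoid organs, and a T cell
deprived of them does not die instantly but after a delay — an inertia.
The size $x(t)$ of a population controlled by one interleukin $h(t)$
therefore obeys a second-order equation,

$$x'' = -k\,x - c\,x' + \lambda h, \qquad h' = \phi - \mu x,$$

restricted to $x \ge 0$, $h \ge 0$. Here $k$ is an elastic constant
(force per cell), $c$ a damping coefficient, $\lambda$ the homeostatic
force exerted per unit of interleukin, $\phi$ the constant interleukin
production rate and $\mu$ the consumption rate per cell. All quantities
are in the models' own dimensionless units; no unit-conversion layer is
provided.

Two properties distinguish this from logistic-type models:

* the **carrying capacity is emergent**: at equilibrium $x^* = \phi/\mu
  \equiv K$ and $h^* = k\phi/(\lambda\mu)$, so the resting population
  size is a ratio of resource fluxes, not a parameter;
* the **resource is explicit**, so competition between clones acts
  through the interleukin pool rather than through phenomenological
  interaction coefficients.

The equilibrium is linearly stable exactly when $ck > \lambda\mu$: the
linearization has characteristic polynomial
$s^3 + c s^2 + k s + \lambda\mu$, and Routh–Hurwitz for a cubic with
positive coefficients reduces to that single inequality. The package
checks this analytically (`single_characteristic_roots()`) and
numerically (`stability()`, central-difference Jacobian + `eigen()`),
and classifies the marginal case $ck = \lambda\mu$ as *not* stable,
since the criterion is strict; tests deliberately avoid a ±1% band
around the boundary, where finite-precision eigenvalues cannot decide
the question.

When $M$ clones share the interleukin, each receives the share
$m_i/\sum_j m_j$ of the homeostatic force. Summing the per-clone
equations recovers the single-population model for the total — which is
why the total always returns to $K$ while the *composition* of the pool
is free: with identical clone parameters the equilibria form a line
(any split summing to $K$), and the realized point depends on the
initial conditions. For two populations with different parameters the
sign of $\lambda_1 k_2 - \lambda_2 k_1$ decides everything: zero gives
the line of coexistence, a nonzero sign excludes the disadvantaged
population (`two_pop_equilibria()`). Identical clones satisfy the
balance condition trivially, which is the package's resolution of the
apparent conflict between resource competition and high clone
diversity; the classical Lotka–Volterra model (`baseline_lv` functions)
is included as the contrast class, where identical niches sit on a
degenerate knife-edge that any asymmetry collapses into exclusion.

## Constrained integration

The equations are only defined for non-negative cell numbers and
interleukin amounts, but the paper-level models state no enforcement
mechanism; the package integrates the smooth field piecewise
(`deSolve::lsodar`) and treats the domain boundary by **projection with
event detection**:

* every active size and interleukin is monitored by a root function;
  when one crosses zero the solver stops exactly at the crossing;
* the variable is clamped at 0 (a size also has its velocity zeroed);
  if the unconstrained field still points out of the domain the
  variable is *frozen* and the integration continues with it held at 0;
* a frozen variable is released when its unconstrained derivative turns
  non-negative. For an interleukin this is the production/consumption
  balance $\phi - \sum_j \mu_j x_j$. For a clone of a partitioned pool
  the boundary acceleration is the constant antigenic force $A_i$
  (the interleukin share vanishes with the clone), so a clone with
  $A_i = 0$ that reaches zero is permanently frozen — extinct clones do
  not regrow — while only the single-population model and the memory
  compartment of the two-interleukin model, whose boundary forces vary
  in time, carry release monitors.

Every clamp and release is logged in the trajectory's
`constraint_events`. Steady state is declared when the max-norm of the
full derivative stays below `ss_tol` (default $10^{-8}$ times the
capacity scale) over a window `ss_window` (default 10 time units);
solver tolerances default to `rel_tol = 1e-9` and
`abs_tol = 1e-9 * K`, chosen so that the 0.1% agreement between
integration and the closed forms is free of solver noise. The
steady-state criterion is the package's own operationalization — the
source models never define "returns to equilibrium" numerically.

A timescale worth knowing: in the naive pool the *total* relaxes at the
mechanical rates (roots of the cubic above), but the *split* between
clones is restored only by the antigenic forces, at a rate of order
$A/(cK)$. With weak stimulation this mode is very slow; scenarios that
must converge to the affinity-proportional split either use affinities
of sufficient total magnitude or long horizons.

## Memory turnover calculus

Between well-separated activation events the memory pool relaxes back
to $K$. The package implements the discrete bookkeeping this induces:
a naive activation that deposits $m_{1,0}$ new memory cells leaves the
new clone at $m_{1,0}K/(K+m_{1,0})$ and shrinks every incumbent by the
factor $K/(K+m_{1,0})$; a reactivation that adds $\Delta m$ to an
existing clone leaves it at $(\Delta m + m_{1,0})K/(K+\Delta m)$ and
shrinks the rest likewise. Composition over $n$ events gives the
product form $m_{i,n} = m_{i,0}\prod_j K/(K+\Delta m_j)$ for a
non-activated clone — an algebraic identity with the per-event updates,
tested to machine precision.

These closed forms are stated as fits to the relaxation dynamics, so
the package keeps a second, independent route: `run_event_sequence()`
in `"ode"` mode perturbs the equilibrated pool (the new clone enters
with zero velocity; the interleukin stays at its pre-event equilibrium
level) and relaxes it by integration. In the equal-parameter pool the
per-clone dynamics preserves size ratios during relaxation, so the two
routes agree to solver precision whenever $ck > \lambda\mu$ — the
suite's 1% tolerance is deliberately loose insurance, and the
randomized comparison varies $(k, c, \lambda)$ at fixed $K$ to confirm
that only the capacity matters. One caveat is the competitor-free
case: a clone entering an *empty* pool relaxes to $K$ in the ODE,
whereas the formula returns $K/2$; the formulas encode competition and
are only meaningful with incumbents present, so the equivalence tests
start from pools of at least two clones.

Clones that fall strictly below 1 cell are removed (the threshold is
exactly 1.0, applied after each event's relaxation). The extinction
predicate is exposed in both exact form (product $< 1$) and the
logarithmic approximation $\log m_{i,0} < \sum_j \Delta m_j / K$
(natural log, as obtained from the product via
$\log(1 + \Delta m/K) \approx \Delta m/K$). Both are always returned
with a disagreement flag so the approximation is never silent: the two
differ when some $\Delta m$ is comparable to $K$, and — for any event
size — in a narrow band around the extinction threshold itself.
Overlapping events are out of scope and rejected; the calculus assumes
the pool reaches equilibrium between activations.

## Naive selection

Naive clones additionally require sub-threshold antigenic stimulation,
modelled as a constant force $A_i$ per clone, taken proportional to TCR
affinity. The resting pool is affinity-proportional,
$n_i^* = (A_i/A)\,K$ with $A = \sum_j A_j$, and the capacity $K$ is
unchanged by stimulation. Clone $i$ survives (holds at least one cell)
iff $A_i \ge A/K$ — a *dynamic* threshold that every new entrant
raises.

`equilibrate_pool()` iterates size computation and removal. The package
removes **one clone at a time, lowest affinity first**, rather than all
below-threshold clones simultaneously. The choice matters in
near-threshold profiles: with one-at-a-time removal the fixed point has
an exact characterization — every survivor's share is at least one
cell, and re-adding any removed clone alone to the final pool would put
it back below one cell (provable because removals proceed in
increasing affinity order) — whereas simultaneous removal can
over-remove clones that a smaller pool would have supported, breaking
that equivalence. Exact affinity ties are broken by position.

`negative_selection_experiment()` demonstrates the diversity
consequence: drawing candidate affinities from a heavy-tailed
distribution (log-normal by default — a fixture choice, not an
empirical claim) and deleting draws above a cap before sequential entry
yields *more* surviving clones than the uncapped run, because uncapped
high-affinity clones monopolize the capacity and raise the selection
threshold. The effect requires a regime where the pool is actually
crowded (the suite uses $K = 100$ with 150 candidates and
$\sigma_{\log} = 2.5$); with a large capacity and few candidates the
cap is irrelevant. Diversity is reported as richness (survivor count),
with Shannon entropy as a clearly secondary metric.

## Two interleukins, two compartments

With memory cells consuming IL-7 (shared with naive cells) and IL-15
(theirs alone), the compartment sizes at equilibrium are set by the
resource fluxes only: $m^* = \phi_2/\mu_2 = K_m$ and
$n^* = \phi_1/\mu_1 - \phi_2/\mu_2 = K_n$, with $K_n \le 0$ flagged
infeasible. The interleukin levels follow from force balance at
$(m^*, n^*)$. Raising IL-7 production enlarges only the naive pool;
raising IL-15 production converts naive space into memory space at a
fixed total — the organism can steer the naive/memory ratio through
production rates alone. No closed-form stability criterion is asserted
for this model; `stability()` reports `condition_holds = NA` and the
verdict rests on the numerically computed spectrum, instance by
instance.

```{r fig5}
m <- load_scenario("fig5")$model
two_compartment_equilibrium(m)
```

## Scenario presets and reproducibility

`load_scenario()` ships presets `fig1a`–`fig5` carrying the published
caption parameter sets. Two readings were fixed once: the drop-recovery
protocol applies the population drop at the reduced-production
equilibrium (the literal reading of the caption that changes $\phi$ to
$8\cdot 10^4$ for both panels), and the final constant of the
two-compartment set is read as the IL-15 consumption rate $\mu_2 = 3$,
since $\mu_1 = 10$ is listed separately. Scenario configs round-trip
through YAML/JSON; `run_scenario()` writes tidy trajectory CSVs, an
equilibrium/stability JSON and a manifest (parameters, seed, package
version, convergence flags), deterministically for a given spec and
seed.

## What the tests do and do not show

The synthetic generators emulate event sizes and affinity profiles as
log-normal draws with explicit seeds; they stand in for infection
histories and thymic output, and make no claim about real repertoire
statistics. The suite validates *internal* consistency — closed forms
against constrained integration (problem sizes: pools of up to 20
clones, ~50 randomized turnover events, 200-draw stability sweeps;
each well under a minute) — under the models' assumptions: constant
antigenic forces, identical clone mechanics within a pool,
well-separated events, no effector-phase dynamics (event sizes are
inputs, not derived from pathogen load), no spatial structure,
stochasticity or age structure. Agreement here says nothing about fit
to measured T cell counts, which would require calibration against
experimental data and is out of scope.
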