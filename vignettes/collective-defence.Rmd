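---
title: "Collective antibiotic defence in fragmented habitats: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Collective antibiotic defence in fragmented habitats: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fragrescue)
```

## The model

`fragrescue` models a clonal microbial population that defends itself
collectively by degrading an environmental toxin. The worked example
throughout is beta-lactamase-producing bacteria exposed to a beta-lactam
antibiotic, but nothing in the mathematics is specific to that system.

A population of $N(t)$ cells in a well-mixed volume $V$ grows exponentially
at rate $\mu$ while the antibiotic concentration $a(t)$ is at or below the
single-cell MIC threshold $a_{th}$, and dies exponentially at rate $\gamma$
above it:

$$\dot N = N\left[\mu\,\theta(a_{th}-a) - \gamma\,\theta(a-a_{th})\right],$$

with $\theta$ the Heaviside step function. Each live cell carries a fixed
enzymatic degradation capacity $E$ (enzyme copies per cell times the
per-enzyme maximal rate; the two factors never appear separately, so the
package keeps only their product, `enzyme_rate`), and the antibiotic decays
by Michaelis--Menten kinetics:

$$\dot a = -\frac{E\,N}{V}\,\frac{a}{a+K_M}.$$

Starting above threshold, the population is in a *race for survival*: it is
killed exponentially while it degrades the antibiotic, and it survives if
the antibiotic reaches $a_{th}$ before degradation capacity runs out.
Integrating the death phase gives the closed-form condition: survival
requires the initial density $\rho = N_{init}/V$ to exceed

$$\rho^*(a_{init}) = \frac{\gamma}{E}\left[a_{init}-a_{th}
  + K_M \ln\frac{a_{init}}{a_{th}}\right],$$

an *ecological phase boundary* in the $(a_{init},\rho)$ plane
(`critical_density()`). Its shape is the inoculum effect: linear in
$a_{init}$ when $a_{init}\gg K_M$, logarithmic when $a_{init}\ll K_M$.
Model simplifications worth keeping in mind: killing is a clean exponential
above a sharp threshold (no Hill-type pharmacodynamics), and antibiotic is
lost only to enzymatic degradation (no sequestration by binding).

## Reference parameters

The default `model_params()` preset describes beta-lactamase collective
defence in a microfluidic-droplet setting:

| parameter | default | units | meaning |
|---|---|---|---|
| `mu` | 0.01 | min$^{-1}$ | growth rate below threshold |
| `gamma` | 0.045 | min$^{-1}$ | death rate above threshold |
| `enzyme_rate` ($E$) | 3.5e-8 | ug cell$^{-1}$ min$^{-1}$ | per-cell degradation capacity |
| `K_M` | 6.7 | ug ml$^{-1}$ | Michaelis constant |
| `a_th` | 1 | ug ml$^{-1}$ | single-cell MIC |

Internal units are fixed to ml, minutes, ug and cells; picolitres and cubic
micrometres are converted at the interface (`convert_volume()`) because
habitat volumes (droplets ~100 pl, skin pores and alveoli ~10^6 um^3) are
naturally quoted there and silent unit errors are the main practical hazard
in this parameter space.

## Habitat fragmentation

Fragmentation keeps total volume $V$ and mean density $\rho$ fixed and
splits the habitat into $m$ sub-volumes $v = V/m$ that exchange nothing.
Cells land in sub-volumes stochastically; occupancies are
$X_i \sim \mathrm{Poisson}(\rho v)$, as observed for droplet encapsulation
(`sample_partition()`). A sub-volume survives iff
$X_i \ge N^* = \max(1, \lceil \rho^* v\rceil)$, so

$$p_s = P(X \ge N^*), \qquad P_s = 1-(1-p_s)^m,$$

where $P_s$ is the probability that *any* sub-volume survives — the relevant
outcome when even a few surviving cells can regrow. The Poisson tail is
computed with `stats::ppois()` (regularised incomplete gamma), stable for
mean occupancies of $10^4$ and more; the naive pmf summation survives only
as an independent oracle in the test suite. Because the per-count coefficient
of variation is $1/\sqrt{\rho v}$, finer fragmentation makes local densities
more variable, and a population whose mean density is below $\rho^*$ can be
rescued by its over-occupied pockets ("habitat-fragmentation rescue"). In the
extreme where one cell exceeds the critical density ($1/v > \rho^*$,
$N^*=1$), $P_s$ collapses to $1-e^{-\rho V}$ independent of $m$.

In the opposite, non-lethal regime ($\rho > \rho^*$), fragmentation is
detrimental: conditional on being occupied, a sub-volume may still fall
below $N^*$, so the conditional survival probability
$P(X \ge N^*)/P(X \ge 1)$ *decreases* with $m$
(`conditional_survival_curve()`) until the $N^*=1$ regime is reached, where
it trivially returns to 1.

## Numerical design

**Exact event-driven integration.** Within either regime $N(t)$ is a pure
exponential, so the accumulated degradation work
$w(t) = (E/V)\int_0^t N \mathrm{d}s$ has a closed form, and $a(t)$ follows
from the implicit relation $a + K_M\ln a = a_0 + K_M\ln a_0 - w(t)$. The
package therefore never runs a generic ODE solver: `simulate_deterministic()`
evaluates the trajectory exactly on the output grid, and the regime switch is
located in closed form and inserted into the grid. The implicit relation is
inverted by Newton iteration in $u=\ln a$, where the objective
$e^u + K_M u$ is convex and increasing, so convergence from $u_0=\ln a_0$ is
monotone and guaranteed; the iteration is run to relative tolerance 1e-12.
Work values beyond representable concentrations return $a=0$ rather than
overflowing. The test suite cross-checks trajectories, crossing times and
classifications against stiff `deSolve` integration, which plays no role in
the implementation itself.

**Analytic outcome, no extinction cutoff.** Deterministic killing drives
$N$ to zero only asymptotically, so imposing a cutoff such as $N<1$ would
introduce an arbitrary parameter. Instead the outcome is decided by the
phase-boundary criterion itself: killed iff total degradation capacity
$EN_{init}/(\gamma V)$ falls short of the threshold gap. A boundary tie
($\rho v$ exactly $\lceil\rho^* v\rceil$) counts as survival under the
ceiling convention; the dynamical crossing time diverges on this
measure-zero set, and the package documents rather than hides the
discrepancy — property tests exclude exact-boundary inputs.

**Hybrid stochastic engine.** `gillespie_run()` treats births and deaths as
an integer jump process (death propensity $\gamma N$ above threshold, birth
$\mu N$ below) with the antibiotic evolving continuously between events.
Because propensities are constant between events at fixed $N$ and the
antibiotic admits the implicit closed form, the scheme is exact: draw an
exponential waiting time, compare it with the closed-form crossing time at
the current $N$, and either jump or switch regime — no tau-leaping, no
discretisation error. Survival is declared the instant $a$ reaches $a_{th}$
with $N\ge 1$ (after that only births occur, so extinction is impossible);
an `N_CAP` rule is available for extensions where growth itself should be
followed. Runs that reach `t_max` undecided are labelled `UNDETERMINED`,
never silently classified.

**Reproducibility.** Replicate $r$ of any Monte-Carlo estimate runs on seed
`replicate_seed(master, r)` (a fixed LCG-style counter map into
$[0, 2^{31}-1)$), so a single master seed pins every replicate regardless of
execution order, and identical configurations reproduce byte-identical
experiment outputs.

## What the generator emulates — and what it does not

The stochastic ingredients are exactly the two the theory analyses: Poisson
allocation of cells to sub-volumes, and demographic birth–death noise. That
is what microfluidic droplet experiments realise, and it is the setting in
which the analytic formulas are exact, so passing tests demonstrate internal
consistency of theory and simulation under those conditions. Real fragmented
habitats (soil pores, gut crypts, host tissue) can depart from this in ways
the package deliberately does not model: non-Poisson occupancy from spatial
structure (the partition sampler is pluggable, but only the Poisson law
ships), exchange of cells or antibiotic between sub-volumes, time-varying
dosing, and phenotypic or genotypic heterogeneity between cells. Agreement
of Monte-Carlo runs with the closed forms here says nothing about those
effects; the theory's own robustness argument is that any occupancy law
whose CV grows with fragmentation produces qualitatively similar rescue.

## The foraging contrast

`simulate_foraging()` implements the mirror-image interaction: enzymes
*release* a nutrient from a substrate instead of destroying a toxin,

$$\dot n = \frac{EN}{V}\frac{s}{s+K_M}, \quad \dot s = -\dot n, \quad
  \dot N = \mu N\,\theta(n-n_{th}),$$

with growth beginning once the released nutrient exceeds $n_{th}$. The
functional form is a reconstruction: it is the simplest model consistent
with the qualitative behaviour it is meant to show (a lag while nutrient
accumulates, then exponential growth), built by reversing the sign of the
defence degradation law. Nutrient is not consumed by growth; consumption is
an extension point, not implemented. Both zero-order release
($s_{init}\gg K_M$, lag $= n_{th}V/(EN)$) and saturating release are
reachable through `s_init` and `K_M`; defaults mirror the defence preset
($\mu$, $E$, $K_M$ unchanged, $n_{th}=1$, $s_{init}=15$ ug/ml). The same
implicit-solution machinery integrates it exactly, and mass balance
$n+s=s_{init}$ holds by construction.

Fragmentation here changes timing, not fate: the onset of total-population
growth is the *minimum* lag over occupied sub-volumes, an extreme-value
quantity that shrinks as $m$ grows, while the outcome — lag followed by
growth — is invariant and nothing is ever killed.

## Problem sizes and tolerances in the checks

The package's own validation uses deliberately moderate sizes, chosen so the
statistical tests are decisive: fragmentation sweeps use 150–200 whole-
metapopulation replicates per grid point against 99% binomial envelopes
(computed on the complement scale where $p$ is near 1, since naive binomial
quantile search stalls there); the extinction-time law uses 2000 runs
against a Kolmogorov–Smirnov test at $\alpha=0.01$; the mean-field check
uses 50 runs of $10^4$ cells within 5% of the deterministic decay; paired
foraging-lag comparisons use 500 replicates. The demographic-rescue
comparison sits at mean occupancy two cells below the critical count, where
both noise sources matter. Wilson score intervals are used for all
Monte-Carlo proportions because they behave correctly at probabilities
pinned near 0 or 1, which fragmentation sweeps hit constantly.

## Known limitations

- The threshold-switched growth law is a caricature of real
  pharmacodynamics; it buys the closed-form phase boundary.
- The effective MIC of a bulk population at 5e7 cells/ml evaluates to
  ~19.9 ug/ml under the reference parameters, and the package treats
  ~20 ug/ml as the bulk survival threshold at that density.
- Deterministic metapopulation runs classify sub-volumes by the exact
  criterion rather than integrating each one; trajectory-level output
  (`keep_series = TRUE`) integrates only occupied sub-volumes and
  interpolates onto a common grid.
- In the extreme-fragmentation limit the model predicts survival of even a
  single isolated cell with certainty; biologically this is the regime
  where the model's assumptions (notably fixed per-cell enzyme capacity
  and no cell-to-cell variability) are least trustworthy.

## A worked example

```{r example, eval = FALSE}
p <- model_params()

# phase boundary at the four reference doses
critical_density(p, c(15, 35, 55, 75))

# a 5000-cell infection at 5e7 cells/ml, dose 35 ug/ml: killed in bulk,
# but fragmented into 100 sub-habitats it survives with probability ~0.06
classify_outcome(p, initial_condition(5000, 35, 1e8, unit = "um3"))
survival_curve(p, rho = 5e7, a_init_list = 35, total_volume = 1e-4,
               m_grid = 100L, n_replicates = 2000, seed = 1)
```
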