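---
title: "Methods: nonlinear public goods dynamics in pggdyn"
author: "pggdyn authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: nonlinear public goods dynamics in pggdyn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pggdyn)
```

## The model

Two cell types compete in a well-mixed population with a shared carrying
capacity. Producers ("cooperators", $C$) secrete a diffusible public good
— think of a growth factor such as IGF-II in a tumor-cell co-culture — at
a per-capita cost $\kappa$; free-riders ("defectors", $D$) consume the
good without producing it. The good is shared within an interaction
neighborhood of $n$ cells, a proxy for its diffusion range.

A focal cell's benefit depends on how many of the $n$ providers around it
are producers. Averaging neighborhood composition at cooperator fraction
$y$ gives the expected producer fractions

$$N_C = \frac{1 + (n-1)y}{n}, \qquad N_D = \frac{(n-1)y}{n},$$

where the focal producer counts itself: the *self-benefit gap*
$N_C - N_D = 1/n$ is the only intrinsic advantage producers ever get, and
it vanishes as neighborhoods grow. Benefits enter the intrinsic growth
rates through a sigmoid in $N$,

$$r_C(y) = \alpha_C\,\frac{1+e^{\sigma}}{1+e^{\sigma-\beta N_C}} - \kappa,
  \qquad
  r_D(y) = \alpha_D\,\frac{1+e^{\sigma}}{1+e^{\sigma-\beta N_D}},$$

with $\beta \ge 0$ the strength of the frequency-dependent effect and
$\sigma \ge 0$ a frequency-independent background. The marginal benefit
is maximal at $N = \sigma/\beta$: below it extra producers synergize,
above it returns diminish. At $\beta = 0$ the rates collapse to
$\alpha_C - \kappa$ and $\alpha_D$ and the game disappears.

Ecology enters through a global logistic factor $E_K = 1 - (x_C+x_D)/K$
on births only:

$$\dot x_C = r_C(y)\,E_K\,x_C - \delta_C x_C, \qquad
  \dot x_D = r_D(y)\,E_K\,x_D - \delta_D x_D.$$

The same rates define an exact continuous-time Markov jump process
(birth events at per-capita rate $\max(0, r_i E_K)$, deaths at
$\delta_i$), which the package simulates with the direct Gillespie
method; the ODE system is its large-$K$ mean-field limit.

### Conventions at the boundaries

$y$ is defined as 1 when defectors are absent and 0 when cooperators are
absent; at total extinction all rates are zero. Negative intrinsic rates
are meaningful in the ODE (flow direction) and are clamped to zero only
where they become jump propensities. Non-integer $n \ge 1$ is accepted
everywhere: the compartment model produces real-valued effective
neighborhood sizes, and the closed forms above are evaluated as written.

## Equilibria, stability, classification

Interior (polymorphic) equilibria solve $\delta_D r_C(y) = \delta_C
r_D(y)$ — the cross-multiplied form of "growth-rate ratio equals
death-rate ratio", which stays valid when a rate crosses zero. The
function is smooth and cheap, so the solver evaluates it on a uniform
grid of 4096 points, brackets sign changes, and refines each bracket by
bisection to $10^{-10}$, deduplicating roots closer than $10^{-6}$. A
tangential contact (the saddle-node point itself) produces no sign
change; it is caught as an interior local minimum of $|f|$ below
$10^{-8}$ and reported as degenerate. For the sigmoidal family at most
two interior roots exist, typically one repelling and one attracting.

Stability comes from the eigenvalues of the $2\times2$ Jacobian of the
ODE system, computed by central finite differences (relative step
$10^{-6}$); eigenvalues within $10^{-8}$ of zero are reported as
marginal rather than classified. At an interior equilibrium the
total-population direction is always attracting, so a 2D saddle is
labeled "unstable" — it is the frequency dynamics that flee it. At an
equilibrium frequency that is not demographically viable
($r_C(y^*) \le \delta_C$, so $Y^* \le 0$) stability refers to the
reduced frequency equation alone and $Y^*$ is reported as `NA`.

Long-run regimes are classified by mutual invasibility of the two
monomorphic states — cooperators invade all-D iff
$r_C(0)/\delta_C > r_D(0)/\delta_D$, defectors invade all-C iff
$r_D(1)/\delta_D > r_C(1)/\delta_C$ — giving producer dominance,
free-rider dominance, bistability, or coexistence (extinction when
neither monomorphic state is viable). Interior-equilibrium stability is
used as a consistency check; a disagreement raises a warning instead of
being silently resolved. The prototypical case is the strong-benefit
($\beta > \sigma$) regime with both interior equilibria present and
all-D uninvadable: the invasibility pair reads "free-rider dominance",
yet a stable polymorphic attractor exists behind the repelling
threshold — the warning flags that second attractor, which a
four-class invasibility taxonomy cannot name.

A practical note on timescales: near a monomorphic attractor the density
factor equilibrates to $E_K = \delta/r$, which can be small (e.g. 0.05
when $\delta/\alpha = 0.05$); the frequency dynamics then run on that
slowed clock. Verdicts read off finite-horizon trajectories need
horizons long relative to $1/(E_K\,|r_C - r_D|)$, not just $1/\alpha$ —
the invasion classifier integrates for $500/\alpha$ by default and
extends the horizon once if the state has not settled.

## Bifurcation sweeps and hysteresis

`bifurcation_sweep()` recomputes the interior roots and monomorphic
invasibilities along a grid of a control parameter ($n$ or $\beta$) and
reports two event morphologies: a *saddle-node* where the interior root
count drops by two with boundary stabilities unchanged (an attracting
and a repelling polymorphic branch coalesce), and a *transcritical*
pattern where the root count changes by one while a boundary state's
invasibility flips (the interior branch passes through a monomorphic
state and exchanges stability with it). Critical values are reported as
midpoints of the bracketing grid interval — the sweep's resolution, not
a continuation method, sets their precision.

`hysteresis_sweep()` integrates to the attained attractor at each
control value, seeding each step with the previous step's final state
plus one individual-equivalent of any type that has dropped below that
floor (a rare-migrant perturbation mirroring how the stochastic
protocols seed lost types; with perturbation 0 monomorphic states are
absorbing). Within a bistable window the forward sweep continues the
attractor it came in on and the backward sweep the other, so the
branches disagree there. Because the transcritical instability can be
extremely weak just past the critical point, the *observed*
finite-horizon hysteresis window can overhang the strict bistable
window; this is a property of the dynamics, not an artifact.

## The stochastic individual-based model

The Gillespie loop (compiled, using R's RNG so every run is reproducible
from `set.seed`) recomputes all four propensities after every event.
Above $K$ the clamped birth propensities make the population decay at
the death rates, matching the ODE's flow direction. Ensembles derive
child seeds as `seed + run - 1` and record per-run final states, label
frequencies with binomial standard errors, and the ensemble mean
trajectory with per-time standard errors.

`rate_mode = "sampled_neighborhood"` replaces the mean-field $N_C$,
$N_D$ by a fresh hypergeometric draw of the $n-1$ neighbors from the
current population at every event (truncated to the remaining population
when fewer are available, with the producer fraction taken over the
realized provider group). For populations in the hundreds and above this
changes outcome frequencies by less than sampling error — asserted as an
equivalence-within-3-SE test — which is why the cheaper mean-field mode
is the default.

Outcome labels at the classification horizon (`t_max`, default
$200/\alpha$) are purely count-based: `all_C`/`all_D` when one type is
extinct, `extinct` when both are, otherwise `coexistence` (threshold 1
individual). With weak frequency dependence ($\beta < \sigma$) the
defector decay near the all-C attractor runs at rate
$\delta(1 - r_D(1)/r_C(1))$, which can be of order $10^{-3}$–$10^{-2}$
per day; the fraction of runs still carrying both types is then a
strong function of the horizon, and count-based labels at a fixed
horizon should be read as "not yet absorbed", not as a steady-state
coexistence probability.

## The compartment model

To let population size feed back on neighborhood size, the population is
split into $N$ compartments. Each cycle (i) assigns every individual
independently to a uniformly random compartment (multinomial mixing,
exactly conserving both type totals) and (ii) evolves every compartment
under the ODE dynamics for a selection time $T_s$ (default $10/\alpha$)
with its *local* cooperator fraction and a neighborhood size equal to
its current occupancy, floored at 1 — a lone producer keeps its full
self-benefit, a lone free-rider gets nothing. Occupancies are
multinomial with mean $Y/N$, so $1/N$ acts as an emergent inverse
neighborhood size. The density factor is global by default (one
system-wide $K$; `capacity_mode = "per_compartment"` divides $K$ evenly
instead). After each selection step the continuous within-compartment
masses return to integers by expectation-preserving stochastic rounding
(floor plus Bernoulli on the fractional part), so the next multinomial
mix acts on discrete individuals. The steady-state cooperator fraction
is averaged over the last 20% of cycles (default 200 cycles).

The critical compartment number is estimated two ways. Numerically,
`ncrit_numeric()` bisects over $N$ with a majority rule over replicate
protocol runs. The mean-field prediction `ncrit_meanfield()` replaces
occupancies by their expectation and requires *both* boundary conditions
for the all-C long-run state: a rare cooperator must invade all-D at
effective $n = Y^*_D/N$ (the self-benefit $1/n$ grows as compartments
shrink), and a rare defector must fail against all-C at
$n = Y^*_C/N$. The second condition is essential for strong frequency
dependence: with large $\beta$ a free-rider extracts nearly the full
benefit from an almost-all-producer neighborhood, so all-C is only
uninvadable once compartments hold barely more than one cell — which is
why $N_{crit}$ first falls and then rises back toward $Y^*$ as $\beta$
grows, and why the invasion condition alone would wrongly predict a
monotone decrease.

## Fitting the benefit parameters

Competition assays report the change $\Delta y$ in producer fraction
over a fixed duration (typically 4 days) from a grid of seeding
fractions. The model surface is the reduced frequency equation

$$\dot y = y(1-y)\,[E_K\,(r_C(y) - r_D(y)) - (\delta_C - \delta_D)],$$

the exact quotient-rule reduction of the two-species system. By default
the fit runs in the *exponential regime* ($E_K \equiv 1$): short assays
seeded far from confluence never feel the density ceiling, and this
removes the need to know $Y_0$ and $K$. The `full_logistic` mode keeps
the coupling to total density (requiring $Y_0$) and is retained for
sensitivity analysis; the two agree in the low-density limit and the
package tests pin the full mode against the two-species integration.

The likelihood treats observed $\Delta y$ as the model surface plus iid
Gaussian noise with unknown common scale. Profiling the variance reduces
maximum likelihood to least squares in $(\beta, \sigma)$, with the noise
scale reported as $\sqrt{\mathrm{RSS}/m}$. The surface is smooth but can
be locally flat, so optimization is multi-start: an $8\times8$ grid over
the search box ($\beta \in [0,20]$, $\sigma \in [0,10]$ by default), the
best five grid points refined by bounded L-BFGS-B, best refined optimum
returned, with per-start logs kept. Estimates landing on a search bound
are flagged rather than silently returned. Identifiability requires at
least three distinct seeding fractions.

Because the neighborhood size of a diffusible factor is rarely measured,
`fit_across_n()` repeats the fit over a plausible range (default 4 — the
nearest neighbors of a cell in a 2D monolayer — to 40 cells, mean 22)
and reports per-condition medians and IQRs; individual-$n$ failures are
recorded and excluded. `equilibria_from_fit()` carries median estimates
forward to the implied equilibrium structure. With the fixed rates
$\alpha = 1$/day, $\kappa = 0.25\alpha$, equal deaths, and the
benchmark medians $\beta = 3.67$, $\sigma = 1.87$ at $n = 22$, the
implied interior equilibria are a repelling point near $y^* = 0.236$ and
an attracting one near $y^* = 0.784$:

```{r equilibria}
equilibria_from_fit(3.67, 1.87, n_ref = 22)
```

## The synthetic-data generator

`simulate_frequency_change()` emulates the *statistical design* of such
assays: a grid of seeding fractions (default $0.1, \dots, 0.9$), a small
number of replicates (default 3), a 4-day duration, per-condition true
$(\beta, \sigma)$, a neighborhood truth that is either fixed or drawn
per record from the 4–40 range, and additive Gaussian noise on
$\Delta y$ (default SD 0.02, a plausible scale for flow-cytometry or
imaging-based fraction estimates). Defaults were chosen once as a
realistic layout; all are overridable in `freq_change_design()`.

What the generator does *not* emulate: raw cell counts and their
measurement model, plate/batch effects, noise that grows near the
boundaries of $[0,1]$, drift in the background medium between
replicates, or any spatial structure in the assay. Passing the recovery
tests therefore shows that the estimator is consistent and practically
identifiable *under the model's own noise assumptions* — it does not
validate the Gaussian noise choice against real assays.

## Numerical choices

* Trajectory integration: `deSolve::lsoda`, rtol $10^{-8}$ / atol
  $10^{-10}$; sub-atol negative undershoots are clipped to zero.
* Reduced frequency equation and compartment selection step: fixed-step
  classical RK4 (10 steps per day by default; per-capita rates in the
  regimes studied are a few per day, putting $\lambda h$ well inside the
  stability region with local error $\ll 10^{-6}$). Both kernels are
  pinned against `deSolve` solutions in the test suite.
* Root finding: 4096-point bracketing grid, bisection to $10^{-10}$,
  dedup at $10^{-6}$, tangency threshold $10^{-8}$.
* Stability: finite-difference Jacobian (step $10^{-6}$), marginal band
  $10^{-8}$.
* Optimizer: L-BFGS-B, `factr = 1e7` (about $10^{-9}$ relative on the
  objective), bounds as above.
* Invasion verdict thresholds: invader frequency $> 0.99$ fixes,
  $< 0.01$ repelled, otherwise coexistence once $|\dot y|$ is below
  $10^{-6}$.

## Problem sizes used by the test suite

The suite favors many medium-sized checks over few huge ones: stochastic
ensembles of 60–200 runs at $K = 1000$; 2000 pure-birth runs for the
exactness test; $10^4$ random parameter draws for the root-count bound;
100 seeded repeats for the recovery study (9 seeding fractions × 3
replicates each); compartment sweeps of 8 grid points × 10 replicates ×
100 cycles, and $N_{crit}$ bisections with 3 replicates × 60 cycles.
These sizes give the binomial and chi-square checks the power they need
while keeping the full suite in the minutes range.

## Known limitations

* The mean-field averaging of neighborhood composition happens *before*
  the nonlinearity; per-event sampled neighborhoods are available in the
  IBM, but finite-population hypergeometric corrections to the ODE
  itself are not implemented.
* Only the sigmoidal benefit family is implemented. The growth-rate
  evaluation sits behind a single dispatch point so saturating
  (Michaelis–Menten/Hill) benefits could be added, but their richer
  equilibrium structure (up to five interior roots) is out of scope.
* The carrying capacity is a fixed parameter; feedback of the public
  good on $K$ itself is not modeled.
* No explicit space: compartments are exchangeable patches with uniform
  reassignment, not a lattice or diffusion model, and the public good
  has no anisotropic transport.
* Bifurcation events are bracketed at sweep resolution; there is no
  continuation or normal-form analysis.
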