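---
title: "Mixing and diffusion in a two-group contagion process: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mixing and diffusion in a two-group contagion process: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mixsis)
```

## The model and its assumptions

`mixsis` studies a susceptible–infected–susceptible (SIS) contagion
process on a population split into two groups with different propensities
to contagion. The only structural parameter is the mixing level $m \in
[0,1]$: the probability that an interaction partner belongs to the other
group. The mean dynamic is

$$\dot\rho_i \;=\; \delta_i\left[\lambda_i (1-\rho_i)\,
\big(m\rho_j + (1-m)\rho_i\big) \;-\; \rho_i\right],
\qquad \lambda_i = \frac{p\,\upsilon_i}{\delta_i},$$

with $\rho_i$ the infected fraction of group $i$, $p$ the interaction
probability per period, $\upsilon_i$ the per-contact infection
probability and $\delta_i$ the recovery probability. Assumptions worth
making explicit:

* **Equal group sizes, uniform within-group behaviour.** Both groups have
  the same (large) size; all individuals in a group share
  $(\upsilon_i, \delta_i)$. The stochastic simulator relaxes the second
  assumption through optional susceptibility multipliers (below).
* **Rates versus probabilities.** All parameters may be read as
  continuous-time rates or per-period probabilities. Internally
  everything is treated as rates; probability inputs are used unchanged
  because equilibria and the qualitative dynamics depend only on
  $(\lambda_1, \lambda_2, m)$ — the $\delta_i$ prefactor rescales each
  group's clock without moving stationary states.
* **No spontaneous infection** in the SIS variant: $(0,0)$ is always
  stationary. The state-conditional generalization below drops this.
* **Canonical orientation.** Group 2 is the *sensitive* group
  ($\lambda_1 \le \lambda_2$). `adoption_rates()` canonicalizes and
  records a `swapped` flag; user-facing outputs are reported in the
  order the user supplied. The $\lambda_1 = \lambda_2$ diagonal is
  admitted and handled by the same code paths (all curves are then
  constant in $m$).

## Parameters that matter

| Parameter | Meaning | Units | Default |
|---|---|---|---|
| `lambda1`, `lambda2` | effective adoption rate per group | dimensionless | — |
| `m` | expected fraction of between-group interactions | fraction | — |
| `m_grid` | tabulation grid for curves | fraction | 201 equispaced points on $[0,1]$ |
| `tol` (equilibria) | max stationarity residual $\max_i\lvert\dot\rho_i\rvert$ | rate | `1e-10` |
| `nu_S, nu_I, delta_I, delta_S` | state-conditional rates | fraction (or percent with `units = "percent"`) | — |
| `N`, `periods`, `replicates` | simulator size | counts | `(1e4, 1e4)`, 2000, 20 |

$\lambda > 1$ sustains infection in an isolated group; that motivates the
default bisection brackets used in `scripts/acceptance.R`. The 201-point
default grid resolves curve features of width $\gtrsim 0.005$ in $m$,
which is sufficient for every regime boundary we classify; analyses that
need the extinction point use the analytic threshold
$\bar m = 1 - (1-\lambda_1\lambda_2)/(\lambda_1+\lambda_2-2\lambda_1\lambda_2)$
rather than grid refinement, since the closed form is exact (its
denominator is bounded below by
$2\big(\sqrt{\lambda_1\lambda_2}-\lambda_1\lambda_2\big)$, which is
strictly positive throughout the admissible region
$\lambda_2 > 1 \ge \lambda_1\lambda_2$).

## Solving for equilibria

Holding $\rho_j$ fixed, a group's stationarity condition is quadratic in
$\rho_i$; its largest root in $[0,1]$ defines the group's *reaction*
(`sis_reaction()`), selected in closed form with the numerically stable
branch. The composition of the two reactions is a monotone increasing
self-map of $[0,1]$ whose largest fixed point is the endemic state
whenever one exists, so:

1. decide existence analytically ($\lambda_2 > 1$ and either
   $\lambda_1\lambda_2 > 1$ or $m < \bar m$); otherwise return $(0,0)$;
2. iterate the composed map downward from $1$, with Aitken $\Delta^2$
   extrapolation — plain iteration converges only linearly, and its rate
   approaches 1 near the threshold $\bar m$, where acceleration matters;
3. polish with Newton steps on the full 2-D stationarity system
   (analytic Jacobian), and certify the result: residual below `tol`
   (default $10^{-10}$; typically $10^{-14}$ is reached) and Jacobian
   eigenvalue real parts $\le 10^{-8}$ for the stability flag.

The fixed-point route was chosen over a quartic root-finder because the
interior equilibrium has no usable closed form for $0 < m < 1$, and over
plain damped iteration for speed: the nested parameter searches in the
acceptance analyses solve $\sim 10^3$–$10^4$ equilibria. Curves over a
grid of $m$ warm-start each solve from the neighbouring solution. A
positivity threshold of $10^{-9}$ distinguishes the extinct from the
endemic state in reported flags; near $\bar m$ the analytic threshold is
authoritative.

Time integration (`sis_integrate()`) uses `deSolve::lsoda` with tight
tolerances (`rtol 1e-12`, `atol 1e-14`), integrating in doubling chunks
until the stationarity residual drops below the requested tolerance.
States are clipped to $[0,1]^2$ and a clip beyond $10^{-9}$ warns — the
box is forward-invariant for the exact flow, so larger excursions would
indicate integrator trouble.

## Regime classification

With canonical $\lambda_1 \le \lambda_2$ the plane splits by precedence:
**A** if $\lambda_2 \le 1$ (no diffusion), **B** if
$\lambda_1\lambda_2 \le 1$ (extinction above $\bar m$), **E** if
$\lambda_1^{3/4}(\lambda_2+1) \ge \lambda_2^{3/4}(\lambda_1+1)$ (all
three equilibrium curves monotone; this condition can only hold for
$\lambda_2 > 3$, since $\lambda^{3/4}/(\lambda+1)$ peaks at $\lambda=3$),
then **C** versus **D** by whether the resistant group's equilibrium
curve is non-monotonic in $m$. For C/D we use a numeric monotonicity
scan of the solved curve as the authoritative classifier, with the
closed-form boundary candidate
$\lambda_1 = \sqrt{\lambda_2}/(\lambda_2-\sqrt{\lambda_2}+1)$ retained as
a cross-check; the two agree away from the boundary's immediate
neighbourhood. Inequalities within $10^{-9}$ of equality set
`boundary_flags`, while the label itself is assigned deterministically by
the precedence A→B→E→C/D.

Monotonicity detection works on finite differences with an absolute
magnitude filter of $10^{-7}$ (differences below it are solver noise on
the default grid), compresses the resulting sign sequence, and refines
interior extrema by a parabolic pass through the three surrounding grid
points. Pareto analysis is a direct pairwise dominance scan of the grid
(orientation-aware: "better" defaults to *less* infection), merging
contiguous dominated points into intervals while a common dominating
witness exists. `optimal_mixing()` breaks ties toward the smallest $m$
and only applies parabolic refinement to strict interior optima.

## The state-conditional generalization

The generalized model gives each group four rates conditional on the
partner's state, $0<\upsilon_{|S}<\upsilon_{|I}<1$ and
$0<\delta_{|I}<\delta_{|S}<1$:

$$\dot\rho_i = (1-\rho_i)\big[\upsilon_{i|I} I_i + \upsilon_{i|S}(1-I_i)\big]
- \rho_i\big[\delta_{i|I} I_i + \delta_{i|S}(1-I_i)\big],
\qquad I_i = (1-m)\rho_i + m\rho_j.$$

Because $\upsilon_{|S}>0$, the derivative is positive at $\rho_i=0$ and
negative at $\rho_i=1$: the reaction value is always strictly interior
(no extinction), and it is strictly increasing in $\rho_j$. The reaction
is concave in $\rho_j$ when
$(\upsilon_{|I}-\upsilon_{|S})>(\delta_{|S}-\delta_{|I})$ and convex when
reversed; in the concave–concave (and, by a change of variables,
convex–convex) case the interior stationary state is unique and globally
stable, and the solver asserts this operationally by running the monotone
iteration from both corners $(1,1)$ and $(0,0)$ and checking agreement to
$10^{-8}$. For mixed curvature uniqueness is not guaranteed: the solver
warns, reports the fixed point reached from $(1,1)$, and flags
`multiple = TRUE` when the corner starts disagree, rather than asserting
uniqueness it cannot certify. The printed equations carry no separate
interaction probability $p$; we take them at face value ($p$ absorbed
into the rates), which matches the per-period reading of the simulator's
general variant where every agent interacts each period.

Percent inputs (`units = "percent"`) are divided by 100 at construction;
everything downstream is in fractions.

## The stochastic simulator

The agent-based process is the finite-$N$ counterpart of the mean
dynamic: synchronous updates against start-of-period states; each agent
interacts with probability $p$, draws its partner from the other group
with probability $m$ and uniformly from its own group excluding itself
otherwise; infection with probability $\upsilon_i$ (times the agent's
multiplier, capped at 1) when the partner is infected; recovery with
probability $\delta_i$. Sampling is one-sided — the partner's state is
read, not updated through that contact — which is what makes the
expected one-period update coincide exactly with the unit-step Euler map
of the mean dynamic (`meanfield_step()`). An asynchronous/Gillespie mode
is deliberately out of scope: the mean-field equations are derived from
per-period probabilities.

What the generator emulates and what it does not: within-group
heterogeneity is a lognormal susceptibility multiplier with mean 1
applied to $\upsilon_i$ only — the simplest one-parameter spread, a
generic stand-in rather than a replication of any particular empirical
heterogeneity structure. Real contact networks (degree heterogeneity,
clustering, dynamic ties) are not represented at all; passing tests
therefore show convergence of the *well-mixed two-block* process to its
mean dynamic, not robustness of the conclusions to network structure.

Ensemble summaries report per-period means and standard errors across
replicates, and quasi-stationary final-window averages over the last 20%
of periods, conditioning on non-extinct replicates (absorbed replicates
are flagged, never reseeded). `compare_to_meanfield()` reports two
deviations: the final-window distance from the equilibrium, and the
largest distance between the ensemble mean trajectory and the
deterministic trajectory from the same initial fractions. The trajectory
metric is the one whose decrease with $N$ is statistically resolvable at
moderate replicate counts (it shrinks like $1/\sqrt{N}$); the
equilibrium bias itself is $O(1/N)$ and, at strongly supercritical rates
such as $\lambda=(2,5)$, already comparable to Monte-Carlo noise at
$N=10^3$.

Problem sizes used in the shipped tests: the headline consistency run
uses $N = 10^4$ per group, 2000 periods and 20 replicates (initial
infected fraction 0.1), and the size sweep reuses that configuration at
$N \in \{100, 1000, 10000\}$; these sizes put the final-window standard
error near $10^{-4}$, which is what the three-standard-error comparison
against the closed-form bipartite equilibrium $(0.6, 0.75)$ requires.
Reproducibility is exact: a fixed seed yields bitwise-identical
trajectories, because all randomness flows through R's default RNG in a
fixed order of agent decisions.

## Numerical choices and degenerate inputs

* Oracle-agreement tests draw rates bounded away from the bifurcation
  manifolds ($\lvert\lambda_i-1\rvert$ and
  $\lvert\lambda_1\lambda_2-1\rvert$ above 0.05): matching an ODE limit
  to $10^{-6}$ near a fold requires horizons growing like the inverse
  spectral gap, which is a property of the dynamics, not of the solver.
* The extreme cases $m=0$, $m=1$ and $\lambda_1=\lambda_2$ are handled by
  continuity of the same formulas (the reaction quadratic degenerates to
  a linear equation at $m=1$ and to the isolated-group root at
  $m\rho_j=0$); no special-cased analytics are needed.
* In the threshold-constant analysis of `scripts/acceptance.R`, "the
  average curve is non-decreasing on $(0,1]$" is tested through the sign
  of the curve's slope at $m=1$ (finite difference of solved equilibria,
  step $10^{-3}$). The average curve is either monotone or
  single-peaked, so the end slope is an exact discriminator, and it
  stays orders of magnitude above solver noise even where the interior
  dip of near-diagonal parameter pairs is far below any workable
  curve-level tolerance (the dip vanishes like $(\lambda_2-\lambda_1)^2$
  as the rates approach each other).
* Boundary ties in classification are resolved by fixed precedence for
  determinism; the flags expose the tie to the caller.

## Known limitations

* No closed form for the interior equilibrium at $0<m<1$: everything
  between the endpoints is numerical (certified by residual and
  stability checks).
* Degree-heterogeneous or network-explicit contagion, varying population
  size, and multi-group ($>2$) extensions are out of scope.
* The Pareto scan is grid-based: intervals are resolved to the grid step
  (default 0.005), and a dominated set thinner than the grid step could
  be missed.
* For mixed-curvature generalized models the package reports what it
  finds from both corner starts but makes no uniqueness or global
  stability claim.
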