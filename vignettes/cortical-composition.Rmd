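---
title: "Optimal composition of cortical gray matter: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Optimal composition of cortical gray matter: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cortexcomp)
```

## The problem

The gray matter of the cerebral cortex is shared by five components: axons
(fraction $x$), dendrites ($y$), dendritic spines ($s$), glia/astrocytes
($g$) and capillaries ($c$), with $x+y+s+g+c=1$. Measured across mammals
from mouse to human, these fractions are strikingly stable — roughly $1/3$
each for axons and dendrites, $(1/3)^2$ for spines and glia, $(1/3)^4$ for
capillaries — and nearly independent of brain size (allometric exponents
close to zero). `cortexcomp` asks whether this invariant hierarchy can be
the outcome of evolutionary optimization, by building a coupled model of
the five fractions, optimizing candidate fitness functions under the
normalization constraint, and measuring the distance between optimal and
measured compositions.

## The coupled composition model

Three independent variables — $x$, $y$ and the mean spine volume $\bar u$
(in $\mu\mathrm{m}^3$) — determine everything else:

* **Spines** form where an axon and a dendrite meet (geometric
  probability $xy$) *and* the potential spine exceeds a volume threshold
  $\theta$: $s = P(\bar u;\theta)\,x\,y$, where
  $P = \int_\theta^\infty H(u)\,du$ is the exceedance probability of the
  spine-size distribution $H$. The threshold models the minimum metabolic
  allocation a stable spine needs; small spines are stochastic, large ones
  reliable.
* **Glia/astrocytes** tile the tissue in non-overlapping domains and reach
  their spine targets by processes laid out like a minimal spanning tree,
  whose total length over $N_s$ targets in volume $V$ scales as
  $b\,N_s^{2/3}V^{1/3}$ with $b=(3/4\pi)^{1/3}$. With cylindrical
  processes of mean diameter $d_{as}$ this gives
  $g = a\,(s/\bar u)^{2/3}$, $a = (\pi/4)\,b\,d_{as}^2$. The ratio
  $s/\bar u$ is the spine number density $\rho_s$ ($\mu\mathrm{m}^{-3}$),
  so $a$ carries $\mu\mathrm{m}^2$ and $g$ is unitless.
* **Capillaries** cluster where both astrocytes and spines are dense:
  $c = g\,s$, equivalently $c = a\,s^{5/3}/\bar u^{2/3}$, implying
  $c \sim g^{5/2}$ and $c/g = s \ll 1$.

The only fixed physical constant is $d_{as} = 0.85\ \mu$m (from measured
astrocyte process volume $350\ \mu\mathrm{m}^3$ and surface area
$1650\ \mu\mathrm{m}^2$ via $d = 4V/S$), giving $a = 0.352\ \mu$m$^2$.
Both are configurable through `coupling_constants()`.

## Spine-size distributions

Six families for $H(u)$ are implemented, each parametrized by its mean
$\bar u$ so families are interchangeable in the optimization: exponential,
gamma of order $n=1$ and $n=2$, Rayleigh (short tails), log-logistic
(shape $\beta>1$) and log-normal (shape $\sigma>0$) (heavy tails). Each
has a closed-form $P(\bar u;\theta)$ — e.g. $e^{-\theta/\bar u}$ for the
exponential, a Hill function with renormalized threshold
$\tilde\theta = \theta(\pi/\beta)/\sin(\pi/\beta)$ for the log-logistic —
and a closed-form derivative $\partial P/\partial\bar u$ used by the
stationarity conditions. Tests verify every closed form against direct
quadrature of the density ($10^{-8}$) and against Monte-Carlo sampling
(3 standard errors at $n = 10^5$); the gamma polynomials are additionally
checked against the regularized upper incomplete gamma function.

## Fitness functions and their optimization

The meta fitness, minimized subject to $x+y+s+g+c=1$, is

$$F \;=\; f\,\frac{r x + y}{\bar u^{\gamma_1}}
      \;-\; (1-f)\,\frac{s}{\bar u^{\gamma_2}} .$$

* $f = 1$: **wire minimization**. $\gamma_1$ selects the wire property
  being minimized: volume ($0$), surface area ($1/3$), length ($2/3$),
  conduction delays ($5/6$). $r>0$ weighs axons against dendrites.
* $f = 0$: **spine-economy maximization** — maximize the spine fraction
  per unit spine-size cost $s/\bar u^{\gamma_2}$, $\gamma_2 > 0$.
* $0 < f < 1$: the mixed meta-principle.

`solve_principle()` finds constrained stationary points by multi-start
damped Newton iteration on the multiplier-eliminated first-order
conditions in $(x, y, \log\bar u)$, converging to residual norms below
$10^{-10}$. Roots are classified by the eigenvalue signs of the Lagrangian
Hessian projected onto the constraint tangent plane: spine-economy optima
are constrained *maxima* of $s/\bar u^{\gamma_2}$, wire-volume and mixed
optima are constrained *minima* of $F$. Among multiple roots the solver
keeps the one with the best objective whose class matches the principle.

Two structural regimes need care:

* **Divergence.** For pure wire minimization with $\gamma_1>0$ the cost
  is strictly positive and tends to zero as $\bar u\to\infty$, so no
  finite optimum exists; the solver returns the analytic limit branch
  ($P=1$, $g=c=0$, $s=xy$, with $x = \sqrt{2/r}-1$,
  $y = rx-(1-r)$ — feasible only for $r > 1/2$). For mixed principles
  with $\gamma_1>0$ a finite stationary local minimum usually exists and
  is the solution of record, even though its fitness may exceed the
  divergent limit's value of zero; only where that finite branch
  disappears (small $\gamma_2$) does the solver fall back to the limit.
* **Warm starts.** Parameter sweeps warm-start each grid point from its
  neighbour, but the warm root is accepted only if its extremum class
  matches the principle — warm iterates can otherwise slide onto
  spurious saddles with vanishing spine content as the landscape shifts.

An independent check, `oracle_optimize()`, never sees the stationarity
equations: it eliminates the constraint by root-finding (in $y$, or in
$x$ for the symmetric $f=0$ case) and optimizes the fitness directly by
grid scan plus simplex polish. Solver and oracle agree to $10^{-3}$ in
every fraction across a matrix of principles and families; the comparison
is meaningful only where the finite branch is the global optimum inside
the oracle's search box, which is why the test matrix uses mixed cases
with a negative optimal fitness.

## The empirical side

`cortical_composition_table()` ships the six-species composition table
(percent fractions, stated uncertainties, gray-matter volumes 0.12 to
571.8 cm³). From it:

* `species_means()` gives the per-component means over available species
  — (39.0, 34.0, 9.6, 11.7, 1.4)% at the tabulated precision.
* `normalized_reference()` rescales those 1-d.p. means to sum to 100%,
  rounding the result again to 1 d.p.: (40.8, 35.5, 10.0, 12.2, 1.5)%.
  Working at the tabulated precision is deliberate and matters: the
  Mahalanobis distance divides the capillary deviation by its sd of
  0.1%, so the third decimal of that reference value shifts MD by ~0.3.
  The reference sds (2.4, 5.5, 2.1, 1.2, 0.1)% are stored verbatim; the
  source does not state how its ± values were derived, and recomputing
  them from the raw rows does not reproduce them.
* `allometric_fit()` regresses $\log_{10}$(fraction %) on
  $\log_{10}$(volume cm³) with pairwise deletion of missing species. The
  recomputed spine slope is $-0.014$ against a published $-0.013$ (the
  $R^2$ of 0.008 matches exactly), a sub-rounding discrepancy we accept.

Model-data agreement uses the Euclidean distance on unitless fractions
and the variance-normalized Mahalanobis distance; with unit sds the two
coincide. MD's tiny capillary sd makes it far more discriminating than
ED between otherwise similar optima.

## Parameter sweeps and defaults

`sweep_principle()` grids over any of $\gamma_2$, $r$, $f$, $\gamma_1$,
$\theta$ and the shape parameter, recording every solution with its
distances; failed grid points are kept and flagged, never dropped.
Default grids mirror the resolution of the published tables: $r$ step
0.01 on [0.5, 1.2], $\gamma_2$ step 0.05, log-normal $\sigma$ step 0.05
on [0.1, 1.0], log-logistic $\beta$ step 0.5 on [1.5, 7.0], thresholds
$\theta \in \{0.100, 0.321\}\ \mu$m³. Reported minima are over the grid,
matching the published procedure; rounding for table reproduction is
3 decimals, half-away-from-zero. `reproduce_table()` re-runs the sweeps
behind the published best-fit tables; its mixed-principle defaults use
coarser $r$/shape grids (step 0.05 / 0.1) because the full
$r \times \gamma_2 \times \sigma$ product at table resolution is
expensive; pass `grids = list(...)` to refine. The test suite exercises
restricted neighbourhoods of the known optima to keep the default run
under a minute.

## A known inconsistency in the log-normal rows

The published log-normal best-fit rows cannot be reproduced exactly by
*any* implementation of the stated model, and we document rather than
force them. Concretely: (i) the wire-volume-minimization log-normal
minimal-ED row ($x=0.411$, $y=0.354$, $\bar u=0.561$, $P=0.731$) is
internally consistent with the coupling laws, but no $\sigma$ makes it a
stationary point — matching its $P$ and the required
$\partial P/\partial\bar u$ simultaneously is impossible within the
log-normal exceedance law; (ii) the two spine-economy log-normal rows
attributed to $\sigma=0.25$ ($\bar u=0.499, P=0.688$ and
$\bar u=0.535, P=0.828$) imply a local slope of $P(\bar u)$ steeper than
the family permits at that $\sigma$, so no single exceedance curve passes
through both. Sweeping $\sigma$ freely, the package reproduces the
log-normal spine-economy minimal MD well (1.796 vs published 1.788, at
$\sigma=0.45$ rather than the footnoted 0.25) but finds a
wire-minimization minimal ED of 0.030 ($r=0.95$, $\sigma=0.45$) against
a published 0.010. The corresponding acceptance check is asserted at the
published value and intentionally fails, so the discrepancy stays
visible.

## Synthetic data

`synth_composition_table()` emulates the statistical structure the
allometric analysis assumes — and only that: per-component fractions
follow $\log_{10}(\text{fraction}) = \text{intercept} + \text{slope}\cdot
\log_{10}(V) + \varepsilon$ with Gaussian noise on the log scale, so
fractions are positive by construction and the log-log OLS model is
exactly well-specified under the generator. Defaults mimic the real
table's scale (6 species, volumes log-uniform over 0.1–600 cm³).
Parameter-recovery tests (imposed slope 0.25, noise sd 0.02, 20 species)
recover slopes within ±0.05. The generator is *not* biophysically
mechanistic: passing tests show the estimators work on data satisfying
their assumptions, not that real cortical data satisfy them.
`synth_spine_samples()` plays the same role for the distribution module,
with all randomness flowing through mandatory seeds.

## Numerical choices and limitations

* Newton tolerance $10^{-10}$ on the residual norm, 120 iterations,
  step-halving line search; starts outside $(10^{-6}, 1-10^{-6})$ in any
  fraction are discarded; $\bar u > 10^4\ \mu$m³ flags divergence.
* Ties among class-matching roots go to the best objective; all roots
  are reported with `solver_control(verbose = TRUE)`.
* The projected-Hessian classification is numerical; a condition-number
  guard returns `"indeterminate"` rather than guessing near-singular
  cases.
* The analysis is local (one cortical column); it says nothing about
  white-matter or long-range organization, and nothing temporal or
  spatial — the fitness functions have no notion of position or
  development.
* Whether the $\gamma_1>0$ limit fractions are exactly constant in $r$
  is not forced: the limit equations give mild $r$-dependence (MD
  18.5–18.7 over $r \in [0.9, 1.0]$), and computed values are reported
  as such.
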