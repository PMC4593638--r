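# cortexcomp

Optimization models of cortical gray-matter composition.

Across mammals, the five major components of cortical gray matter occupy
remarkably stable volume shares: axons and dendrites about 1/3 each,
dendritic spines and glia/astrocytes about (1/3)², capillaries about
(1/3)⁴ — independent of brain size from mouse (0.12 cm³ of gray matter)
to human (571.8 cm³). `cortexcomp` is for computational neuroanatomists
who want to test whether this hierarchy follows from evolutionary
optimization. It implements a coupled model of the five fractions and
optimizes candidate design principles under the normalization constraint,
comparing each optimum to the data.

## The model

Three variables — axon fraction `x`, dendrite fraction `y`, mean spine
volume `ū` (μm³) — determine the rest through coupling laws:

- spines, by geometric probability and a formation threshold θ:
  `s = P(ū; θ)·x·y`, with `P = ∫_θ^∞ H(u) du` the exceedance probability
  of a spine-size distribution `H` (six families: exponential, gamma
  n = 1, 2, Rayleigh, log-logistic, log-normal, all mean-parametrized);
- glia/astrocytes, from minimal-spanning-tree transport scaling:
  `g = a·(s/ū)^(2/3)`, `a = (π/4)·(3/4π)^(1/3)·d_as² = 0.352 μm²` with
  astrocyte process diameter `d_as = 0.85 μm` (the model's one fixed
  constant);
- capillaries, clustering with both: `c = g·s`.

The meta fitness function, minimized subject to `x+y+s+g+c = 1`, is

    F = f·(r·x + y)/ū^γ1 − (1−f)·s/ū^γ2

`f = 1` is neural wire minimization (γ1 = 0 volume, 1/3 surface, 2/3
length, 5/6 conduction delays; `r` is the axon/dendrite asymmetry);
`f = 0` is spine-economy maximization — as many information-storing
spines as possible, penalized by spine size; intermediate `f` mixes the
two. Optimal compositions are scored against the cross-species reference
(40.8, 35.5, 10.0, 12.2, 1.5)% by Euclidean distance (ED) and
variance-normalized Mahalanobis distance (MD).

## Worked example

Solve the pure spine-economy principle (`f = 0`) for the exponential
spine-size distribution at threshold θ = 0.321 μm³ and cost exponent
γ2 = 0.45, then compare to the data:

```r
library(cortexcomp)

spec <- principle_spec(f = 0, gamma2 = 0.45, theta = 0.321,
                       family = "exponential")
sol <- solve_principle(spec)
sol
#> <principle_solution> branch = stationary, class = max
#>       axons   dendrites      spines        glia capillaries
#>      0.3974      0.3974      0.0984      0.0972      0.0096
#> u_bar = 0.6777 um^3, P = 0.6227, F = -0.117178, |resid| = 3.8e-12

euclidean_distance(sol)    # 0.051
mahalanobis_distance(sol)  # 5.885
```

The optimum puts ~40% of the cortex in axons and in dendrites, ~10% in
spines and in glia and ~1% in capillaries — the empirical hierarchy —
with a mean spine volume of 0.68 μm³ (measured human/macaque values are
0.2–0.4 μm³) and a 62% probability that a potential spine exceeds the
formation threshold. `class = max` confirms the solution is a
constrained maximum of the spine-economy function `s/ū^γ2`, and the
stationarity residual is at solver precision.

The empirical side is equally direct:

```r
allometric_fit("glia")
#> slope = 0.031, R^2 = 0.180, p = 0.48   (brain-size invariance)
round(100 * normalized_reference()$mean, 1)
#>  axons dendrites spines glia capillaries
#>   40.8      35.5   10.0 12.2         1.5
```

Other entry points: `sweep_principle()` / `sweep_argmin()` for parameter
grids, `reproduce_table()` for the published best-fit tables,
`profile_curve()` for distance and composition profiles,
`oracle_optimize()` for a stationarity-free cross-check, and
`synth_composition_table()` / `synth_spine_samples()` for synthetic data
with known ground truth.

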