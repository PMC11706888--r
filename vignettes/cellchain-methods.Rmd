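---
title: "Methods: spring-chain cell mechanics on curved interfaces and its continuum limit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spring-chain cell mechanics on curved interfaces}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cellchain)
```

## The model

`cellchain` models a confluent layer of `N` cells attached to a static,
smooth planar curve (the substrate), seen in cross-section. Each cell body is
a chain of `m` identical springs; nodes between springs slide along the curve
in the overdamped regime, so a node's velocity is its net tangential force
divided by a drag coefficient. Two variants differ in how a spring senses the
substrate:

* **curved springs** measure their length as the *arc* separation of their end
  nodes and pull along the local tangent. In arc-length coordinates the node
  dynamics is `η ds_i/dt = f(ℓ_{i+1}) − f(ℓ_i)` with `ℓ_i = s_i − s_{i−1}` —
  formally identical to a chain on a straight line, hence independent of the
  substrate's shape;
* **straight springs** measure the Euclidean *chord* between nodes and pull
  along the secant; a normal substrate reaction cancels the normal force
  component, leaving the tangential projection to move the node. This model
  feels curvature: chords cut across bends.

Assumptions: the curve is regular and twice differentiable (no corners — at a
cusp, straight-spring nodes can lock); cells neither divide nor die; the
interface does not move; nodes never pass each other (enforced, not assumed:
a crossing aborts the run).

On an open curve the two terminal nodes are pinned to the curve's end points;
on a closed curve node indices are periodic and coordinates live in `[0, L)`.

## Force laws and parameters

Three restoring-force laws are built in, all with `f(a) = 0` and
`f'(a) = k > 0`:

| kind | `f(ℓ)` | continuum diffusivity `D(q)` |
|---|---|---|
| `hookean` | `k(ℓ − a)` | `(k*/η*) q⁻²` (fast diffusion) |
| `inverse_density` | `ka²(1/a − 1/ℓ)` | `D₀ = k*(a*)²/η*` (linear) |
| `inverse_density_sq` | `(ka³/2)(1/a² − 1/ℓ²)` | `D₀* q`, `D₀* = k*(a*)³/η*` (porous medium) |

The two nonlinear laws are the biologically sensible regularisations of
Hooke's law: they diverge under extreme compression (cells cannot be squeezed
to nothing) and saturate under extension.

Parameters are canonical at **cell level** — `k*` (force/length), `a*`
(length), `η*` (force·time/length) are properties of a whole cell — and
spring-level values follow `a = a*/m`, `k = k*m` (springs in series),
`η = η*/m` (constant drag per cell). These scalings are exactly what makes
the dynamics converge as `m → ∞`: the slowest relaxation rate is
`(k/η)(2π/M)²` for `M = Nm` springs, so `k/η` must grow as `M²` for an
`m`-independent timescale. A convenient consequence used throughout the tests:
with these scalings, the scaled force `f(mq)/(ηm)` is *identical* for every
`m`, not just in the limit.

Units are arbitrary; rescale lengths by a cell diameter and times by `η*/k*`
to fit an application.

## The continuum limit

Writing the per-spring density `ρ_i = 1/ℓ_i` and matching a smooth field
`ρ(s,t)` to `ρ_i` at the spring's arc **midpoint**, an expansion in the small
spring length turns the exact difference equation for `ρ_i` into

    ∂q/∂t = ∂/∂s ( D(q) ∂q/∂s ),    q = ρ/m,

with an `O(1/m²)` error; matching anywhere else on the spring costs one order
(`O(1/m)`). Both statements are verified empirically by
`convergence_order()`, which fits the slope of `log(max error)` against
`log(1/m)` for the standard offset protocol: measured slopes are ≈ 1.9
(midpoints) and ≈ 1.2 (quarter-points) for `m ∈ {2,4,8,16}`.

Boundary conditions inherit from the discrete model: pinned ends give no-flux
(`∂q/∂s = 0`), closed loops give periodicity. Geometry appears nowhere in the
limit — tissue-scale tangential relaxation cannot sense curvature.

## Stress

Tangential stress is normalised as `σ_ττ/E = −f(ℓ)/(ka)` with compression
positive, so a 50% stretched Hookean spring carries `−0.5`. (Its continuum
forms, e.g. `1 − 1/(qa*)` for Hooke, are the exact `m`-independent
transcriptions of the spring form; we fix the overall sign by the convention
above — tensile negative — which some asymptotic statements of the stress
flip.) The tangential tension also acts as a surface tension
`γ = f̃(ρ)/w` per out-of-plane width `w`, and on curved regions induces the
Young–Laplace normal stress `σ_nn = γκ`. With cross-section `A = w·h` and
`E = ka/A`, the reported normalisation is exactly
`σ_nn/(Eh) = κ f(ℓ)/(ka) = −κ · σ_ττ/E`; no absolute `w` or `h` is ever
needed. The sign convention for curvature (`κ > 0` convex, with the normal
the tangent rotated by −π/2, i.e. outward on counter-clockwise loops) makes
stretched cells on a convex substrate press into it (`σ_nn > 0`).

## Numerical choices

* **Arc-length reparametrisation.** `s(u)` is the composite Simpson 1/3 rule
  on a cached grid of 10,001 parameter samples with a midpoint-refined panel
  per interval (the panel count is our choice; it puts the quadrature error
  near machine precision for the built-in curves and is validated against
  adaptive quadrature to `1e-8`). Inversion `u(s)` interpolates the cached
  table and polishes with safeguarded Newton steps to `~1e-12`; round-trip
  error is held below `1e-8·L`.
* **Discrete integrator.** Explicit forward Euler, default `Δt = 0.001`. A
  guard refuses `Δt > 0.5 η / max_i f'(ℓ_i(0))` — the linearised stability
  limit (for Hooke, `0.5 η/k`); failing loudly beats producing node
  crossings. States are stored at requested save times by stepping past and
  interpolating linearly in time, since the Euler grid need not hit them.
  The curved-spring loop runs in C++; the straight-spring loop stays in R
  (it needs curve evaluations) and is only used at small `M`.
* **PDE solver.** Method of lines on `J` uniform intervals (default 1000,
  configurable): conservative flux form
  `dq_j/dt = [D_{j+1/2}(q_{j+1}−q_j) − D_{j−1/2}(q_j−q_{j−1})]/δs²` with face
  diffusivities at arithmetic-mean densities and mirror ghosts at no-flux
  boundaries. This choice (the expanded form would also be "central
  differences") conserves the trapezoid mass identically — observed drift is
  at rounding level, `~1e-15` relative. Time integration is an adaptive
  Dormand–Prince 5(4) pair written for this package (no ODE-solver package is
  assumed), `rtol = atol = 1e-8`, with positivity-rejected steps.
* **Stress-free rest lengths.** Curved springs: `a = L/M` exactly. Straight
  springs: the equal-chord polygon inscribed in the closed curve that closes
  after one loop, found by shooting — march `M` chords of trial length `a`
  (each advance a safeguarded Newton solve of `‖r(s′) − r(s)‖ = a`), then
  root-find `a` so the total arc equals `L` (closure gap `< 1e-10·L`). Open
  curves use the same march between the pinned end points, linearly extending
  the curve beyond its ends for trial overshoots.
* **Convergence-order protocol.** Discrete runs use `Δt = 2e-5` (so Euler
  error sits below the smallest spatial error in the sweep) and the continuum
  reference uses `J = 4000` (so PDE error does not pollute the slope), with
  the comparison at `t = 0.05`, mid-relaxation. These were fixed before
  measuring the slopes.
* **Spectra.** Closed forms for the circulant (periodic) and tridiagonal
  (fixed) coupling matrices are cross-checked against `eigen()` to `1e-10`
  up to `M = 50`. For fixed boundaries all `M − 1` non-steady modes decay;
  we sum over all of them (one classical statement of the solution appears
  to drop the fastest mode from the upper summation limit; nothing numerical
  depends on it).

### Equal-chord polygons are not unique

On curves with discrete rotational symmetry the closing equal-chord polygon
comes in phases. On the four-lobed cross `R(θ) = cos⁴θ + sin⁴θ` with
`M = 64`, the polygon with a *node* on a symmetry axis closes with chord
`0.099644`, the one with a chord *midpoint* there with `0.099476`; both are
legitimate stress-free states (every spring force-free), and a relaxing
simulation selects one by its initial phase. At `M = 8` only the node-on-axis
family closes (`a = 0.736813`) — at off-symmetry phases the closure map jumps
and `rest_length_stress_free()` reports that no polygon exists. The function
therefore exposes the march's start point `s0`.

## What the offset initial condition does and does not emulate

The standard perturbation (`initial_condition_offset()`) displaces one cell
boundary by half a resting cell length, leaving one cell 50% stretched next
to one 50% compressed — a localised, order-one mechanical disturbance whose
relaxation exercises every part of the machinery, with exact bookkeeping of
which cell carries which stress. It is *not* a model of biological noise:
there is no stochasticity anywhere in the package (the CLI accepts a seed
only for protocol reproducibility), no heterogeneity between cells, no
proliferation, and no moving interface. A passing test therefore establishes
the mechanics and its limits, not any statistical property of real epithelia.

## Known limitations

* Curves must be regular and smooth; corners and cusps are rejected rather
  than modelled, although real scaffolds have them.
* The straight-spring model runs in interpreted R; for `M` in the thousands
  use the curved model (they agree as `O(1/m²)` anyway).
* Forward Euler is conditionally stable; the guard is based on the initial
  state, so a run that stiffens dramatically mid-trajectory could in
  principle step too coarsely (none of the shipped protocols does).
* Aggregating force laws (`f' < 0`, e.g. Lennard–Jones-type) are outside
  scope except for the linear-stability flag that identifies them.
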