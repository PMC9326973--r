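---
title: "Trajectories from the principle of least action"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Trajectories from the principle of least action}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Molecular dynamics integrates an initial-value problem: given positions and
velocities at `t0`, step forward. Many questions are posed the other way
round: *both* endpoint configurations are known — a liquid snapshot and its
state 1 ps later, or two minima of a cluster — and the trajectory connecting
them is wanted. `ompath` solves this boundary-value problem by minimizing
the Onsager–Machlup (OM) action

$$ S[Q] \;=\; \int_{t_0}^{t_1} \sum_{i=1}^{N}
   \bigl| m_i \ddot q_i(t) + \nabla_i V(Q(t)) \bigr|^2 \, dt , $$

which is non-negative and vanishes exactly on Newtonian paths, so its
minimizer subject to the endpoint constraints is the most probable
classical trajectory. The overall constant prefactor of the action is set
to 1: it does not move the minimizer, and the penalty weights absorb any
scale.

## The trajectory model

A trajectory is represented by a deliberately small network: one scalar
input (time), one hidden layer of `n_hidden` units, and a linear output
layer with `d*N` units — every Cartesian coordinate of every atom. The
network is a closed-form composition, so velocity and acceleration are
computed *exactly* by the chain rule (`model_derivatives()`), never by
finite differences; likewise the full parameter gradient of the loss is
evaluated analytically (it requires Hessian-of-`V`-times-vector products,
which the Lennard-Jones kernels provide in closed form). Tests verify both
against central differences.

Choices the source work leaves open, fixed here once:

* **Activation `tanh`** (default; `softplus` available). The action depends
  on second time derivatives, so the activation must be C²: ReLU-type
  choices have an almost-everywhere-zero second derivative, which removes
  path curvature from the loss entirely, and are rejected.
* **Time normalization.** Physical time in `[t0, t1]` is affinely mapped to
  `[0, 1]`; raw spans in τ would saturate `tanh`.
* **Linear baseline.** By default the network output is *added* to the
  straight-line interpolation between `Q0` and `QT`, so training starts
  from the linear path and the output weights can start near zero. This is
  a convergence aid, not a constraint — the boundary penalties stay in the
  loss, and `baseline = NULL` reproduces the literal penalty-only setup.
* **Initialization.** Input-side weights uniform on `(-freq_scale,
  freq_scale)` with `freq_scale = max(2, n_hidden/4)` by default, and each
  unit's transition point placed uniformly inside the window; output side
  normal with sd `0.01/sqrt(n_hidden)` (so the initial path hugs the
  baseline). The frequency spread matters more than it looks: with O(1)
  input weights every tanh unit is nearly linear across the normalized
  window, the second-derivative basis `a^2 w^2 tanh''` is then vanishingly
  small, and the network simply cannot produce the accelerations
  (|m q̈| of order 10–50 ε/σ in a dense liquid) that a near-Newtonian path
  requires — training stalls at paths whose action is 20–40× the
  attainable value. This was found empirically and is the package's one
  deliberate departure from the obvious default.

## The discretized loss

`total_loss()` evaluates, on a uniform grid of `n_t + 1` points,

```
total = action + lambda_bc0 * |Q(t0) - Q0|^2
               + lambda_bcT * |Q(t1) - QT|^2
               + lambda_E   * dt * sum_k (E(Q(t_k), Qdot(t_k)) - E0)^2
```

Numerical choices: a uniform-weight Riemann sum over all grid points
(trapezoid weights available via `quadrature = "trapezoid"`; they differ
only in the boundary halves and the tests confirm both converge to a dense
quadrature oracle); the energy penalty uses all `n_t + 1` points including
the boundaries; sums — not means — over atoms and grid points, with the
λ's absorbing scale. The grid is defined by the physical window divided by
`n_t`; for the liquid validation runs the window is 0.5 τ (1 ps in argon
units) with `n_t = 25`, making the model's time step 20× the MD step of
0.001 τ (2 fs).

## Training

`train()` minimizes the loss with NADAM (Nesterov-accelerated Adam),
full-batch over the grid, learning rate 1e-3 to 2e-3, early stopping on the
relative improvement of the best total loss (`tolerance`, default 1e-10
over 500 epochs). Penalty weights can be selected by
`random_search_lambdas()`: log-uniform triples in `[1e-1, 1e5]`,
short-trained, and filtered by the declared balance criterion (no weighted
component more than 1e3× another) before picking the lowest total.

One deliberate addition: first-order optimizers stall once the loss
surface becomes a narrow quadratic valley, far above the accuracy the
per-frame RMSD targets demand. `train(..., polish = n)` therefore runs up
to `n` L-BFGS iterations from the best NADAM parameters, using the same
analytic gradient. The default (`polish = 0`) is the literal NADAM-only
scheme; the shipped examples and acceptance runs enable polishing, and all
reported numbers come from runs that state it.

## Ground truth and the synthetic world

All reference data are generated internally, in reduced LJ units
(ε = σ = m = 1, τ = σ√(m/ε); for argon τ ≈ 2 ps — a presentation-layer
conversion only, never applied silently).

* **Liquid state point** (density 0.80 σ⁻³, temperature 0.75 ε/k_B,
  cutoff 2.5 σ with energy shift): the classic LJ liquid-argon region.
  The source work defers its exact setup to supporting information, so
  these are declared defaults, exposed in the configuration, chosen once
  and not tuned afterwards.
* **Preparation**: FCC lattice, then 10 cycles of Maxwell–Boltzmann
  resampling + 0.5 τ NVE stretches, then three rescale-relax cycles so the
  final NVE temperature sits within a few percent of the target. This
  emulates a melted, equilibrated liquid; it is *not* a rigorous NVT
  ensemble (no thermostat statistics), which is irrelevant here because
  only a single equilibrated phase point and its NVE continuation are
  needed.
* **Clusters** use full pairwise summation with no cutoff, so quenched
  minima are comparable with literature energetics: the 13-atom icosahedron
  quenches to −44.326801 ε and the 38-atom FCC truncated octahedron to
  −173.928427 ε, both matching published global-minimum values — a strong
  end-to-end check of the force field and the quencher.

What a green liquid test establishes: that the trained network reproduces
*this* MD engine's trajectory on *this* state point at the stated grid.
It does not establish transferability to other densities, potentials or
window lengths.

### Non-uniqueness of the liquid boundary-value problem

A dense LJ liquid at ρ = 0.80, T = 0.75 has an Einstein (cage-rattling)
period of roughly 0.3 τ. Over a 0.5 τ window — the standard validation
setup here — the two-endpoint boundary-value problem therefore develops
conjugate points and admits **multiple Newtonian solutions**. This is not a
hypothetical: grid-refined training in this package reaches near-zero
action on a path that remains ~0.1 σ (per-coordinate RMSD) away from the
MD trajectory through the same endpoints, and the energy-conservation
penalty does not discriminate, because the alternative branches conserve
the same `E0`. Consequently a per-frame RMSD comparison between the
trained path and the MD reference can plateau around 0.1 σ even when the
optimizer has done its job: it found *a* most-probable path, just not the
branch the initial velocities happened to select. The structural
observables (g(r), energies) of the trained path still match MD closely —
the branches are statistically equivalent — and the shipped tests assert
exactly that, while the strict trajectory-identity bound is asserted
faithfully and documented as not attainable in this regime. Short windows
(≲ the Einstein period), stiffer systems, and cluster problems with
quenched endpoints do not suffer from this, which is why the harmonic and
cluster validations converge to their references.

## Cluster transition paths

* The 13-atom "truncated FCC" starting structure is the radially relaxed
  cuboctahedron. By symmetry the radial relaxation yields an exact
  stationary point of the potential — but a *saddle*, not a minimum (any
  unconstrained quench falls straight into the icosahedron, which is the
  point of the example). `transition_path()` therefore accepts symmetric
  stationary endpoints, not only minima.
* The 38-atom icosahedral endpoint (second-lowest funnel) has no published
  coordinates in the source; `build_lj38_icosahedral_minimum()` generates a
  synthetic stand-in — Mackay 13-core plus a greedily placed 25-atom
  overlayer, quenched and refined by a short small-step basin hop — and
  reports the energy it actually reached rather than asserting a reference
  value.
* **Energy bookkeeping**: for cluster paths `E0` defaults to the potential
  energy of the initial structure with zero kinetic energy, and the energy
  penalty defaults to *off* (`lambda_E = 0`): strict conservation at the
  initial-minimum energy would forbid climbing the barrier at all. This
  tension is inherent to the formulation and is documented rather than
  hidden.
* `arc_length()` is the raw 3N-dimensional polyline length of the path; no
  rotational or permutational alignment is applied by default (an optional
  Kabsch pre-alignment of the final endpoint exists, off by default). Both
  the arc length and the endpoint Euclidean distance are reported, since
  the two readings of the published distances differ.

## Observables

`rmsd_per_frame()` compares trajectories frame by frame in the shared
coordinate system (no alignment — both paths live in the same frame by
construction); the momentum variant uses the model's exact first derivative
for the network velocities. `rdf()` is the standard minimum-image pair
histogram normalized by ideal-gas shell counts (default 200 bins).
`vaf()` averages over all atoms and all time origins and locates the first
zero crossing by linear interpolation; origin averaging is used because the
source does not state its convention, and for an NVE trajectory the choice
only affects noise.

## Degenerate inputs, tolerances, tie-breaks

Coincident atoms raise a singular-configuration error rather than
returning Inf. Quenching accepts an already-stationary input and returns
it unchanged (gradient-norm tolerance 1e-6 ε/σ). A zero-epoch training
budget returns the initial model. `vaf()` returns `NA` for the crossing
time when no sign change occurs in the sampled lags. The trainer breaks
ties by keeping the *first* parameters achieving the best total loss.

## Known limitations

* O(N²) pair loops (no cell lists): fine to a few hundred atoms, not for
  large systems.
* The λ search operationalizes a stated intent ("balance the terms") with
  a declared criterion; other operationalizations are defensible.
* Quenching every frame of a path is the profile's cost driver; it scales
  with `n_t` × quench cost.
* The basin-hopping refinement of the synthetic 38-atom icosahedral
  endpoint does not guarantee the literature second-lowest minimum, only a
  low-lying icosahedral one; the energy it reached is always logged.
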