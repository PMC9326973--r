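# ompath

Atomistic trajectories from the principle of least action.

Molecular dynamics (MD) integrates an *initial-value* problem: positions and
velocities in, future out. Many questions come the other way round — both
endpoint configurations are known (a liquid snapshot and its state 1 ps
later; two minima of a cluster) and the connecting trajectory is wanted.
`ompath` solves this *boundary-value* problem for Lennard-Jones (LJ) systems
by representing the whole trajectory with a small neural network of time,
`Q(t)`, and training it to minimize the discretized Onsager–Machlup (OM)
action

$$ S[Q] = \int_{t_0}^{t_1} \sum_{i=1}^{N}
   \left| m_i \ddot q_i(t) + \nabla_i V(Q(t)) \right|^2 dt
   \;\;(\ge 0,\; = 0 \text{ exactly on Newtonian paths}), $$

subject to penalty terms for the two boundary configurations and for total
energy conservation at a reference energy `E0`:

```
loss = action + lambda_bc0 |Q(t0) - Q0|^2 + lambda_bcT |Q(t1) - QT|^2
              + lambda_E dt sum_k (E(Q(t_k), Qdot(t_k)) - E0)^2
```

Everything runs in reduced LJ units (ε = σ = m = 1, τ = σ√(m/ε) ≈ 2 ps for
argon). The package is aimed at molecular-simulation researchers studying
action-based path methods, transition pathways of LJ clusters, and
physics-informed trajectory models.

What is inside:

* `potentials` — 12-6 LJ energies/forces (free clusters and periodic
  liquids, minimum image, optional truncation/shift) plus closed-form
  Hessian-vector products and a harmonic oracle, with Rcpp kernels.
* `reference_md` — velocity-Verlet NVE engine, FCC lattice + equilibration,
  endpoint-pair generation (`make_endpoint_pair()`): the ground truth.
* `trajectory_model` — the 1 → n_hidden → d·N network with *exact* first
  and second time derivatives (`model_derivatives()`), JSON checkpoints.
* `action_loss` — discretized OM action, boundary and energy penalties,
  analytic parameter gradients (verified against finite differences).
* `training` — NADAM with early stopping, optional quasi-Newton polish,
  and random-search selection of the λ weights.
* `cluster_paths` — LJ₁₃/LJ₃₈ structure builders, quenching, basin hopping,
  transition-path profiles (raw + quenched energies, barrier, arc length),
  optimal structure superposition.
* `analysis` — per-frame position/momentum RMSD, g(r), velocity
  autocorrelation with first zero crossing, energy series.
* `cli_io` — extended-XYZ read/write, JSON run configs, `run_pipeline()`,
  and a small CLI (`inst/cli/ompath`).

## Worked example: a boundary-value problem with a known answer

One particle in an isotropic harmonic well (`k = m = 1`), positions fixed at
`t = 0` and `t = 2` τ; the exact trajectory is
`x(t) = x0 cos t + B sin t`. The network is trained on a 25-increment grid:

```r
library(ompath)
spec <- system_spec(1, potential = "harmonic", stiffness = 1)
x0 <- matrix(c(1, 0, 0), 1, 3)          # position at t = 0
xT <- matrix(c(0.2, 0.8, -0.5), 1, 3)   # position at t = 2 tau
B  <- (xT - x0 * cos(2)) / sin(2)       # analytic solution coefficients
ep <- endpoint_pair(x0, xT, e0 = 0.5 * sum(B^2) + 0.5 * sum(x0^2), window = 2)
grid  <- time_grid(0, 2, 25)
model <- init_model(spec, 20, seed = 1, t1 = 2, baseline = list(q0 = x0, qT = xT))
fit <- train(model, grid, spec, ep, loss_weights(1e3, 1e3, 10),
             train_config(epochs = 3000, learning_rate = 2e-3), polish = 3000)
tail(fit$history, 1)
#> epoch       action          bc0          bcT       energy        total
#>  6000 3.198251e-05 4.809841e-14 1.246583e-13 1.056837e-07 3.303952e-05

exact <- t(sapply(grid$points, function(t) x0 * cos(t) + B * sin(t)))
pred  <- matrix(model_positions(fit$model, grid$points), 26, 3)
max(abs(pred - exact))
#> [1] 9.69e-05
```

The action falls to ~3e-5 (zero up to discretization), the boundary
penalties to ~1e-13, and the trained path matches the closed-form solution
to better than 1e-4 σ at every grid point.

Cluster example — the 13-atom truncated-FCC (cuboctahedral) structure
relaxing into its icosahedral global minimum:

```r
spec <- system_spec(13)
qi <- build_lj13_cuboctahedron()                  # unstable stationary point
qf <- quench(qi + 0.02 * matrix(rnorm(39), 13, 3), spec)  # falls to -44.3268
pr <- transition_path(qi, qf$config, spec, time_grid(0, 0.5, 25),
                      weights = loss_weights(1e3, 1e3, 0),
                      config = train_config(epochs = 4000, learning_rate = 2e-3),
                      polish = 4000)
pr$arc_length        # ~0.9 sigma: the transition barely moves the atoms
pr$quenched_energy   # per-atom inherent-structure profile along the path
```

## Caveats

The liquid boundary-value problem over windows longer than the Einstein
period admits *multiple* Newtonian paths; trained trajectories can converge
to a branch different from the MD reference (the structural observables
still agree — see the methods vignette in `vignettes/` for the full
discussion, and the test suite for what is and is not asserted).
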