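# shared fixtures; anything expensive is memoized so the suite builds it once

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, .fixture_env)) assign(key, force(expr), .fixture_env)
  get(key, .fixture_env)
}

# a small random cluster configuration with no close contacts
random_cluster <- function(n, dim = 3, seed = 1, spread = 1.3, min_sep = 0.85) {
  set.seed(seed)
  repeat {
    q <- matrix(runif(n * dim, -spread * n^(1 / 3), spread * n^(1 / 3)), n, dim)
    if (min(dist(q)) > min_sep) return(q)
  }
}

free_spec <- function(n, dim = 3) system_spec(n, dim = dim, lj = lj_params())

# dimer at the pair-potential minimum distance
dimer <- function() {
  list(spec = free_spec(2),
       config = rbind(c(0, 0, 0), c(2^(1 / 6), 0, 0)))
}

# small equilibrated liquid shared across md/analysis tests
small_liquid <- function() {
  memo("small_liquid", {
    ini <- init_fcc_lattice(32, 0.8)
    eq <- equilibrate(ini$config, ini$spec, temperature = 0.75, seed = 11,
                      n_cycles = 5)
    list(spec = ini$spec, lattice = ini$config, config = eq$config,
         velocities = eq$velocities)
  })
}

# 108-atom endpoint pair + ground truth + trained model; built once and
# shared by the liquid acceptance criteria (RMSD, g(r))
liquid_fit <- function() {
  memo("liquid_fit", {
    ini <- init_fcc_lattice(108, 0.8)
    gen <- make_endpoint_pair(ini$spec, ini$config, temperature = 0.75,
                              window = 0.5, seed = 42, stride = 20)
    grid <- time_grid(0, 0.5, 25)
    model <- init_model(ini$spec, 60, seed = 7, t0 = 0, t1 = 0.5,
                        baseline = list(q0 = gen$pair$q0, qT = gen$pair$qT))
    weights <- loss_weights(1e4, 1e4, 10)
    fit <- train(model, grid, ini$spec, gen$pair, weights,
                 train_config(epochs = 3000, learning_rate = 1e-3,
                              log_every = 1000),
                 polish = 4000)
    nn_traj <- phase_trajectory(grid$points,
                                model_positions(fit$model, grid$points),
                                model_derivatives(fit$model, grid$points, 1),
                                ini$spec)
    list(spec = ini$spec, pair = gen$pair, md = gen$trajectory, grid = grid,
         fit = fit, nn = nn_traj)
  })
}

# quenched 13-atom icosahedral global minimum (energy used by several tests)
lj13_min <- function() {
  memo("lj13_min", quench(build_lj13_icosahedron(), free_spec(13)))
}
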