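#' Phase-space trajectory container
#'
#' Positions and velocities of all atoms on a discrete time grid, as produced
#' by [run_verlet()] and consumed by the analysis routines.
#'
#' @param times Strictly increasing vector of frame times (tau units).
#' @param positions `(frames, N, d)` array of coordinates.
#' @param velocities `(frames, N, d)` array of velocities.
#' @param spec [system_spec()].
#' @return Object of class `phase_trajectory`.
#' @export
phase_trajectory <- function(times, positions, velocities, spec) {
  stopifnot(is.array(positions), length(dim(positions)) == 3L,
            identical(dim(positions), dim(velocities)),
            dim(positions)[1] == length(times),
            dim(positions)[2] == spec$n_atoms,
            dim(positions)[3] == spec$dim,
            all(diff(times) > 0))
  structure(list(times = times, positions = positions,
                 velocities = velocities, spec = spec),
            class = "phase_trajectory")
}

#' @export
print.phase_trajectory <- function(x, ...) {
  cat(sprintf("<phase_trajectory: %d frames, %d atoms, %dD, t in [%g, %g] tau>\n",
              length(x$times), x$spec$n_atoms, x$spec$dim,
              x$times[1], x$times[length(x$times)]))
  invisible(x)
}

# frame k of a trajectory as an N x d matrix
traj_frame <- function(traj, k, what = c("positions", "velocities")) {
  what <- match.arg(what)
  matrix(traj[[what]][k, , ], dim(traj[[what]])[2], dim(traj[[what]])[3])
}

#' Boundary data for the action boundary-value problem
#'
#' Holds the two endpoint configurations, the conserved total energy of the
#' generating dynamics, and the elapsed time window; the quantities the
#' boundary-condition and energy-conservation penalties constrain.
#'
#' @param q0,qT Initial/final N x d configurations.
#' @param e0 Total energy at `q0` with the generating velocities.
#' @param window Elapsed time `t1 - t0` (> 0), tau units.
#' @param seed Integer seed that generated the pair (or `NA`).
#' @param v0 Optional generating velocities at `q0`.
#' @return Object of class `endpoint_pair`.
#' @export
endpoint_pair <- function(q0, qT, e0, window, seed = NA_integer_, v0 = NULL) {
  q0 <- as.matrix(q0); qT <- as.matrix(qT)
  stopifnot(identical(dim(q0), dim(qT)), window > 0, is.finite(e0))
  structure(list(q0 = q0, qT = qT, e0 = e0, window = window,
                 seed = seed, v0 = v0),
            class = "endpoint_pair")
}

#' Initialize atoms on a perfect FCC lattice
#'
#' Standard liquid-state preparation: `n_atoms = 4 c^3` atoms on a
#' face-centred cubic lattice in a cubic periodic box of volume
#' `n_atoms / density`.
#'
#' @param n_atoms Atom count, must be `4 c^3` for integer c.
#' @param density Reduced number density (sigma^-3).
#' @param lj Pair interaction; default is the liquid convention, cutoff
#'   `2.5 sigma` with energy shift, reduced to just below half the box edge
#'   when the box is too small for 2.5 sigma.
#' @return List with `config` (N x 3 matrix) and `spec` ([system_spec()]).
#' @export
init_fcc_lattice <- function(n_atoms, density, lj = NULL) {
  stopifnot(n_atoms >= 4, density > 0)
  c3 <- round((n_atoms / 4)^(1 / 3))
  if (4 * c3^3 != n_atoms)
    stop(sprintf("n_atoms must be 4*c^3 for integer c (got %d)", n_atoms))
  edge <- (n_atoms / density)^(1 / 3)
  if (is.null(lj)) {
    rc <- min(2.5, 0.499 * edge)
    lj <- if (rc > 1) lj_params(cutoff = rc, shift = TRUE) else lj_params()
  }
  a <- edge / c3
  basis <- rbind(c(0, 0, 0), c(0.5, 0.5, 0), c(0.5, 0, 0.5), c(0, 0.5, 0.5))
  cells <- as.matrix(expand.grid(0:(c3 - 1), 0:(c3 - 1), 0:(c3 - 1)))
  pos <- matrix(0, n_atoms, 3)
  row <- 1L
  for (i in seq_len(nrow(cells))) {
    for (b in 1:4) {
      pos[row, ] <- a * (cells[i, ] + basis[b, ])
      row <- row + 1L
    }
  }
  spec <- system_spec(n_atoms, dim = 3, box = rep(edge, 3), lj = lj)
  list(config = pos, spec = spec)
}

#' Draw Maxwell-Boltzmann velocities
#'
#' Gaussian velocities at reduced temperature `T` (variance `T/m_i` per
#' component), with the centre-of-mass momentum removed.
#'
#' @param spec [system_spec()].
#' @param temperature Reduced temperature (>= 0).
#' @param seed Integer seed; the draw is reproducible.
#' @return N x d velocity matrix with zero total momentum.
#' @export
sample_velocities <- function(spec, temperature, seed) {
  stopifnot(temperature >= 0)
  if (temperature == 0) return(matrix(0, spec$n_atoms, spec$dim))
  v <- withr_seed(seed, {
    matrix(rnorm(spec$n_atoms * spec$dim, sd = sqrt(temperature / spec$masses)),
           spec$n_atoms, spec$dim)
  })
  # remove centre-of-mass momentum
  pcom <- colSums(spec$masses * v) / sum(spec$masses)
  sweep(v, 2, pcom, "-")
}

# evaluate expr under a temporary RNG seed, restoring the caller's RNG state
withr_seed <- function(seed, expr) {
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Velocity-Verlet NVE integration
#'
#' The standard symplectic second-order integrator; serves as the
#' ground-truth dynamics the trajectory network is validated against.
#'
#' @param start N x d initial configuration.
#' @param velocities N x d initial velocities.
#' @param spec [system_spec()].
#' @param dt Time step (tau units).
#' @param n_steps Number of steps; must be a multiple of `stride`.
#' @param stride Record every `stride`-th step (frame 0 always included).
#' @param t0 Time of the first frame.
#' @return [phase_trajectory()] with `n_steps/stride + 1` frames.
#' @export
run_verlet <- function(start, velocities, spec, dt, n_steps, stride = 1L,
                       t0 = 0) {
  start <- .check_config(start, spec)
  velocities <- .check_config(velocities, spec)
  stopifnot(dt > 0, n_steps >= 1, n_steps %% stride == 0)
  times <- t0 + dt * seq(0, n_steps, by = stride)
  if (spec$potential == "lj") {
    p <- spec$lj
    out <- .cpp_verlet(start, velocities, spec$masses, dt, as.integer(n_steps),
                       as.integer(stride), p$epsilon, p$sigma, p$cutoff %||% -1,
                       p$shift, .box_arg(spec))
    return(phase_trajectory(times, out$positions, out$velocities, spec))
  }
  # harmonic oracle: plain R loop (only used for small analytic test systems)
  nf <- n_steps / stride + 1
  qs <- array(0, c(nf, spec$n_atoms, spec$dim))
  vs <- array(0, c(nf, spec$n_atoms, spec$dim))
  q <- start; v <- velocities
  f <- forces(q, spec)
  qs[1, , ] <- q; vs[1, , ] <- v
  frame <- 2L
  for (s in seq_len(n_steps)) {
    v <- v + 0.5 * dt * f / spec$masses
    q <- q + dt * v
    f <- forces(q, spec)
    v <- v + 0.5 * dt * f / spec$masses
    if (s %% stride == 0) {
      if (!all(is.finite(q))) stop(sprintf("integration diverged at step %d", s))
      qs[frame, , ] <- q; vs[frame, , ] <- v
      frame <- frame + 1L
    }
  }
  phase_trajectory(times, qs, vs, spec)
}

#' Melt and equilibrate a configuration at a target temperature
#'
#' Crude but serviceable NVT-like preparation: repeated Maxwell-Boltzmann
#' velocity resampling followed by NVE stretches, then a few
#' rescale-and-relax cycles so the final kinetic temperature sits near the
#' request.
#'
#' @param start N x d initial configuration (e.g. from [init_fcc_lattice()]).
#' @param spec [system_spec()].
#' @param temperature Target reduced temperature.
#' @param seed Integer seed (drives all velocity draws).
#' @param n_cycles Resample-run cycles (default 10).
#' @param cycle_time NVE stretch length per cycle, tau units.
#' @param dt Integrator time step.
#' @return List with `config` and `velocities` of the equilibrated state.
#' @export
equilibrate <- function(start, spec, temperature, seed, n_cycles = 10,
                        cycle_time = 0.5, dt = 0.001) {
  q <- .check_config(start, spec)
  steps <- max(1L, round(cycle_time / dt))
  v <- NULL
  for (i in seq_len(n_cycles)) {
    v <- sample_velocities(spec, temperature, seed + i)
    tr <- run_verlet(q, v, spec, dt, steps, stride = steps)
    q <- traj_frame(tr, 2)
    v <- traj_frame(tr, 2, "velocities")
  }
  # rescale-and-relax so the NVE kinetic temperature lands near the target
  ndof <- spec$dim * (spec$n_atoms - 1)
  for (i in 1:3) {
    tk <- sum(spec$masses * rowSums(v^2)) / ndof
    v <- v * sqrt(temperature / tk)
    tr <- run_verlet(q, v, spec, dt, steps %/% 2, stride = steps %/% 2)
    q <- traj_frame(tr, 2)
    v <- traj_frame(tr, 2, "velocities")
  }
  list(config = q, velocities = v)
}

#' Kinetic temperature of a velocity set
#'
#' @param velocities N x d velocities.
#' @param spec [system_spec()].
#' @return `sum(m v^2) / (d (N - 1))`, the instantaneous temperature with the
#'   centre-of-mass degrees of freedom removed.
#' @export
kinetic_temperature <- function(velocities, spec) {
  sum(spec$masses * rowSums(as.matrix(velocities)^2)) /
    (spec$dim * (spec$n_atoms - 1))
}

#' Generate an endpoint pair plus its ground-truth trajectory
#'
#' Equilibrates a liquid, then runs one NVE window at fine time step.  The
#' first and last frames and the initial total energy form the boundary data
#' for action minimization; the full trajectory is the ground truth the
#' trained network is compared against.
#'
#' @param spec [system_spec()].
#' @param start Initial configuration handed to [equilibrate()].
#' @param temperature Reduced temperature (default 0.75, a liquid-argon-like
#'   state point).
#' @param window NVE window length in tau (default 0.5, i.e. 1 ps for argon).
#' @param seed Integer seed.
#' @param dt MD time step (default 0.001 tau, approximately 2 fs for argon).
#' @param stride Frame recording stride for the returned trajectory.
#' @param equil_args List of extra arguments for [equilibrate()].
#' @return List with `pair` ([endpoint_pair()]) and `trajectory`
#'   ([phase_trajectory()]).
#' @export
make_endpoint_pair <- function(spec, start, temperature = 0.75, window = 0.5,
                               seed = 1L, dt = 0.001, stride = 1L,
                               equil_args = list()) {
  stopifnot(window > 0)
  eq <- do.call(equilibrate, c(list(start = start, spec = spec,
                                    temperature = temperature, seed = seed,
                                    dt = dt), equil_args))
  n_steps <- round(window / dt)
  stopifnot(n_steps %% stride == 0)
  tr <- run_verlet(eq$config, eq$velocities, spec, dt, n_steps, stride = stride)
  nf <- length(tr$times)
  pair <- endpoint_pair(q0 = traj_frame(tr, 1), qT = traj_frame(tr, nf),
                        e0 = total_energy(eq$config, eq$velocities, spec),
                        window = window, seed = seed, v0 = eq$velocities)
  list(pair = pair, trajectory = tr)
}
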