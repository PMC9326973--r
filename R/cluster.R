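#' Icosahedral 13-atom cluster seed
#'
#' One central atom plus the 12 vertices of a regular icosahedron with edge
#' length `2^(1/6) sigma` (the pair-potential minimum distance), the seed
#' that quenches to the Mackay-icosahedron global minimum of the 13-atom
#' Lennard-Jones cluster.
#'
#' @return 13 x 3 coordinate matrix, centred on the origin.
#' @export
build_lj13_icosahedron <- function() {
  rbind(c(0, 0, 0), .ico_vertices(2^(1 / 6)))
}

# 12 icosahedron vertices for edge length `edge`
.ico_vertices <- function(edge) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(0,  1,  phi), c(0, -1,  phi), c(0,  1, -phi), c(0, -1, -phi),
    c(1,  phi, 0), c(-1,  phi, 0), c(1, -phi, 0), c(-1, -phi, 0),
    c(phi, 0,  1), c(phi, 0, -1), c(-phi, 0,  1), c(-phi, 0, -1))
  v * (edge / 2)   # raw vertices have edge length 2
}

#' Cuboctahedral (truncated-FCC) 13-atom cluster
#'
#' Central atom plus its 12 face-centred-cubic nearest neighbours.  With
#' `relaxed = TRUE` (default) the single radial degree of freedom compatible
#' with the octahedral symmetry is optimized, which yields an exact
#' stationary point of the potential: the unstable "truncated FCC" structure
#' that relaxes into the icosahedral global minimum.  Used as the initial
#' endpoint of the 13-atom transition-path example.
#'
#' @param relaxed Optimize the common center-vertex distance.
#' @return 13 x 3 coordinate matrix.
#' @export
build_lj13_cuboctahedron <- function(relaxed = TRUE) {
  v <- rbind(
    c(1, 1, 0), c(1, -1, 0), c(-1, 1, 0), c(-1, -1, 0),
    c(1, 0, 1), c(1, 0, -1), c(-1, 0, 1), c(-1, 0, -1),
    c(0, 1, 1), c(0, 1, -1), c(0, -1, 1), c(0, -1, -1)) / sqrt(2)
  q <- rbind(c(0, 0, 0), v * 2^(1 / 6))
  if (relaxed) {
    spec <- system_spec(13, lj = lj_params())
    scale <- stats::optimize(function(s) potential_energy(q * s, spec),
                             c(0.8, 1.2), tol = 1e-12)$minimum
    q <- q * scale
  }
  q
}

#' FCC truncated-octahedron seed for the 38-atom cluster
#'
#' The 38 face-centred-cubic lattice sites nearest an octahedral hole
#' (shells of 6, 8 and 24 sites), scaled so the nearest-neighbour distance
#' is `2^(1/6) sigma`.  Quenching this seed reaches the global minimum of
#' the 38-atom Lennard-Jones cluster, the Oh-symmetric truncated octahedron.
#'
#' @return 38 x 3 coordinate matrix, centred on the origin.
#' @export
build_lj38_fcc_octahedron <- function() {
  rng <- -3:3
  sites <- as.matrix(expand.grid(i = rng, j = rng, k = rng))
  sites <- sites[rowSums(sites) %% 2 == 0, , drop = FALSE]  # FCC sublattice
  center <- c(1, 0, 0)                                      # octahedral hole
  rel <- sweep(sites, 2, center, "-")
  d2 <- rowSums(rel^2)
  keep <- d2 <= 5 + 1e-9
  q <- rel[keep, , drop = FALSE] * (2^(1 / 6) / sqrt(2))
  stopifnot(nrow(q) == 38)
  sweep(q, 2, colMeans(q), "-")
}

#' Quench a configuration to its inherent structure
#'
#' Local minimization of the potential energy (L-BFGS with analytic forces,
#' restarted until the force infinity-norm is below `gtol`).  Maps any
#' trajectory frame onto the potential-energy surface of local minima.
#'
#' @param config N x d configuration (no coincident atoms).
#' @param spec [system_spec()].
#' @param gtol Convergence threshold on the force infinity-norm
#'   (epsilon/sigma units).
#' @param max_iter Total iteration cap across restarts.
#' @return List with `config` (minimized coordinates), `energy`, and
#'   `converged`.  Non-convergence within the cap produces a warning that
#'   reports the final gradient norm.
#' @export
quench <- function(config, spec, gtol = 1e-6, max_iter = 1e5) {
  q <- .check_config(config, spec)
  shape <- dim(q)
  fn <- function(x) potential_energy(matrix(x, shape[1], shape[2]), spec)
  gr <- function(x) -as.vector(forces(matrix(x, shape[1], shape[2]), spec))
  x <- as.vector(q)
  used <- 0L
  stalls <- 0L
  gnorm <- max(abs(gr(x)))
  while (gnorm > gtol && used < max_iter && stalls < 5L) {
    res <- optim(x, fn, gr, method = "L-BFGS-B",
                 control = list(maxit = min(5000L, max_iter - used),
                                factr = 1e1, pgtol = 0))
    x <- res$par
    used <- used + max(res$counts[1], 1L)
    gnew <- max(abs(gr(x)))
    if (gnew >= gnorm * (1 - 1e-8)) {
      # roundoff stall: a few Armijo steepest-descent steps, then retry
      stalls <- stalls + 1L
      g <- gr(x)
      f0 <- fn(x)
      step <- 1e-4 / max(abs(g))
      for (k in 1:20) {
        xn <- x - step * g
        if (fn(xn) < f0) { x <- xn; break }
        step <- step / 4
      }
      used <- used + 21L
    }
    gnorm <- max(abs(gr(x)))
  }
  if (gnorm > gtol)
    warning(sprintf("quench did not reach gtol: final |F|_inf = %.3g", gnorm))
  list(config = matrix(x, shape[1], shape[2]), energy = fn(x),
       converged = gnorm <= gtol)
}

#' Basin-hopping global optimization
#'
#' Monte-Carlo perturbation, quench, and Metropolis acceptance on quenched
#' energies; tracks the best minimum seen.  A containment radius rejects
#' moves that evaporate atoms off the cluster.
#'
#' @param start N x d starting configuration.
#' @param spec [system_spec()].
#' @param n_steps Number of hop attempts (>= 1).
#' @param step_size Maximum per-component displacement (sigma units).
#' @param temperature Metropolis acceptance scale on quenched energies.
#' @param seed Integer seed; the hop sequence is reproducible.
#' @param r_cap Containment radius; proposals with any atom farther than
#'   this from the centroid are rejected outright.
#' @return List with `config`, `energy` (best minimum found) and `trace`
#'   (data frame: step, energy of current minimum, best so far).
#' @export
basin_hop <- function(start, spec, n_steps, step_size = 0.4,
                      temperature = 0.4, seed = 1L,
                      r_cap = 1.5 + 1.3 * spec$n_atoms^(1 / 3)) {
  stopifnot(n_steps >= 1)
  cur <- quench(start, spec)
  best <- cur
  trace <- data.frame(step = 0L, energy = cur$energy, best = best$energy)
  withr_seed(seed, {
    for (s in seq_len(n_steps)) {
      prop <- cur$config +
        matrix(runif(length(cur$config), -step_size, step_size),
               nrow(cur$config))
      prop <- sweep(prop, 2, colMeans(prop), "-")
      if (max(sqrt(rowSums(prop^2))) <= r_cap) {
        # stalled quenches on wild proposals are routine here, not notable
        cand <- suppressWarnings(quench(prop, spec))
        de <- cand$energy - cur$energy
        if (de < 0 || runif(1) < exp(-de / temperature)) cur <- cand
        if (cur$energy < best$energy) best <- cur
      }
      trace <- rbind(trace,
                     data.frame(step = s, energy = cur$energy,
                                best = best$energy))
    }
  })
  list(config = best$config, energy = best$energy, trace = trace)
}

#' Generated icosahedral low-lying minimum of the 38-atom cluster
#'
#' Synthetic stand-in for the "incomplete Mackay icosahedron", the
#' second-lowest 38-atom minimum (which has no published coordinates to
#' build from): a 13-atom icosahedral (Mackay) core plus a 25-atom
#' overlayer chosen by deterministic enumeration of all five-fold-symmetric
#' subsets of the 42 second-shell Mackay sites (the second minimum is
#' C5v-symmetric, so the search is restricted to five orbits of five sites
#' about a vertex axis), each candidate quenched, keeping the lowest
#' minimum inside the icosahedral energy window (above the FCC funnel).
#' Optionally refined by a short small-step basin hop.  The returned energy
#' is whatever the generator actually reached; callers log it rather than
#' assuming the literature value.
#'
#' @param seed Integer seed for the optional refinement hops.
#' @param refine_steps Basin-hop refinement steps (0 = enumeration only).
#' @return List with `config` (38 x 3, centred), `energy`.
#' @export
build_lj38_icosahedral_minimum <- function(seed = 1L, refine_steps = 0) {
  spec <- system_spec(38, lj = lj_params())
  core <- build_lj13_icosahedron()
  v <- .ico_vertices(2^(1 / 6))
  # second Mackay shell: scaled vertices + midpoints of adjacent vertex pairs
  edges <- which(as.matrix(stats::dist(v)) < 2^(1 / 6) * 1.01, arr.ind = TRUE)
  edges <- edges[edges[, 1] < edges[, 2], , drop = FALSE]
  shell <- rbind(2 * v, v[edges[, 1], ] + v[edges[, 2], ])
  stopifnot(nrow(shell) == 42)
  # orbits of the shell under the C5 rotation about the first vertex axis
  axis <- v[1, ] / sqrt(sum(v[1, ]^2))
  th <- 2 * pi / 5
  K <- matrix(c(0, -axis[3], axis[2], axis[3], 0, -axis[1],
                -axis[2], axis[1], 0), 3, 3, byrow = TRUE)
  rot <- diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
  rotated <- shell %*% t(rot)
  nn_map <- apply(rotated, 1, function(x) which.min(colSums((t(shell) - x)^2)))
  seen <- rep(FALSE, nrow(shell))
  orbits <- list()
  for (i in seq_len(nrow(shell))) {
    if (seen[i]) next
    o <- i; j <- nn_map[i]
    while (j != i) { o <- c(o, j); j <- nn_map[j] }
    seen[o] <- TRUE
    orbits[[length(orbits) + 1L]] <- o
  }
  five <- orbits[lengths(orbits) == 5]
  combs <- utils::combn(length(five), 5)
  best <- list(energy = Inf)
  for (ci in seq_len(ncol(combs))) {
    q <- rbind(core, shell[unlist(five[combs[, ci]]), ])
    if (min(stats::dist(q)) < 0.5) next
    qn <- suppressWarnings(quench(q, spec))
    # stay in the icosahedral funnel: above the FCC global-minimum shelf
    if (qn$energy < best$energy && qn$energy > -173.6) best <- qn
  }
  if (refine_steps > 0) {
    bh <- basin_hop(best$config, spec, n_steps = refine_steps,
                    step_size = 0.12, temperature = 0.02, seed = seed)
    if (bh$energy < best$energy && bh$energy > -173.6)
      best <- list(config = bh$config, energy = bh$energy)
  }
  list(config = sweep(best$config, 2, colMeans(best$config), "-"),
       energy = best$energy)
}

#' Arc length of a discrete path in configuration space
#'
#' Sum of Euclidean distances between consecutive frames of the
#' `d*N`-dimensional path, the discrete form of the path-integral distance
#' \eqn{\int |d\bar Q|} between two cluster structures.  No rotational or
#' permutational alignment is applied (optional rigid-body pre-alignment of
#' the final endpoint is available in [transition_path()]).
#'
#' @param trajectory `(frames, N, d)` array, or a frames x (N*d) matrix.
#' @return Scalar length in sigma units.
#' @export
arc_length <- function(trajectory) {
  if (length(dim(trajectory)) == 3L) {
    d <- dim(trajectory)
    trajectory <- matrix(trajectory, d[1], d[2] * d[3])
  }
  stopifnot(nrow(trajectory) >= 2)
  steps <- diff(trajectory)
  sum(sqrt(rowSums(steps^2)))
}

# Hungarian algorithm (O(n^3)) for the square assignment problem;
# returns for each row the assigned column. Costs must be finite.
.hungarian <- function(cost) {
  n <- nrow(cost)
  u <- numeric(n + 1); v <- numeric(n + 1)
  p <- integer(n + 1); way <- integer(n + 1)
  for (i in seq_len(n)) {
    p[1] <- i
    j0 <- 0L
    minv <- rep(Inf, n + 1)
    used <- rep(FALSE, n + 1)
    repeat {
      used[j0 + 1] <- TRUE
      i0 <- p[j0 + 1]; delta <- Inf; j1 <- 0L
      for (j in seq_len(n)) {
        if (!used[j + 1]) {
          cur <- cost[i0, j] - u[i0 + 1] - v[j + 1]
          if (cur < minv[j + 1]) { minv[j + 1] <- cur; way[j + 1] <- j0 }
          if (minv[j + 1] < delta) { delta <- minv[j + 1]; j1 <- j }
        }
      }
      for (j in 0:n) {
        if (used[j + 1]) {
          u[p[j + 1] + 1] <- u[p[j + 1] + 1] + delta
          v[j + 1] <- v[j + 1] - delta
        } else minv[j + 1] <- minv[j + 1] - delta
      }
      j0 <- j1
      if (p[j0 + 1] == 0L) break
    }
    repeat {
      j1 <- way[j0 + 1]
      p[j0 + 1] <- p[j1 + 1]
      j0 <- j1
      if (j0 == 0L) break
    }
  }
  match <- integer(n)
  for (j in seq_len(n)) if (p[j + 1] > 0) match[p[j + 1]] <- j
  match
}

#' Superpose one cluster structure onto another
#'
#' Rigid-body (Kabsch) superposition, optionally alternated with an optimal
#' relabeling of identical atoms (Hungarian assignment on squared
#' distances), which is the natural metric between cluster structures whose
#' atom labels and orientations are arbitrary.
#'
#' @param b Structure to move (N x 3).
#' @param a Reference structure (N x 3).
#' @param permute Also optimize the atom correspondence.
#' @param max_sweeps Assignment/superposition alternations.
#' @return The transformed copy of `b` (rows reordered if `permute`).
#' @export
align_structures <- function(b, a, permute = FALSE, max_sweeps = 50) {
  out <- .kabsch_align(b, a)
  if (!permute) return(out)
  best <- sum((out - a)^2)
  for (s in seq_len(max_sweeps)) {
    cost <- outer(rowSums(out^2), rowSums(a^2), "+") - 2 * out %*% t(a)
    perm <- .hungarian(cost)
    out <- .kabsch_align(out[order(perm), ], a)
    new <- sum((out - a)^2)
    if (new >= best - 1e-12) break
    best <- new
  }
  out
}

# rigid-body superposition of b onto a (Kabsch); both N x 3
.kabsch_align <- function(b, a) {
  ca <- sweep(a, 2, colMeans(a), "-")
  cb <- sweep(b, 2, colMeans(b), "-")
  sv <- svd(crossprod(cb, ca))
  d <- sign(det(sv$v %*% t(sv$u)))
  rot <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  sweep(cb %*% t(rot), 2, colMeans(a), "+")
}

#' Find a structural transition pathway between two cluster minima
#'
#' Trains the trajectory network between two fixed cluster structures by
#' action minimization, then profiles the result: per-frame raw potential
#' energy per atom, the quenched (inherent-structure) energy per atom, the
#' barrier relative to the initial frame, and the arc length of the path.
#'
#' The reference energy `e0` defaults to the potential energy of the initial
#' structure (zero kinetic energy).  For barrier-crossing paths the energy
#' penalty must be off (`lambda_E = 0`, the default here): strict
#' conservation at the initial minimum energy would forbid ever climbing the
#' barrier.
#'
#' @param qi,qf Initial and final N x d structures (intended to be quenched
#'   minima or symmetric stationary points).
#' @param spec [system_spec()] (free boundaries, no cutoff for clusters).
#' @param grid [time_grid()] for the path.
#' @param weights [loss_weights()]; default has no energy penalty.
#' @param config [train_config()].
#' @param n_hidden Hidden width of the trajectory model.
#' @param model_seed Seed for the weight initialization.
#' @param align If `TRUE`, rigid-body superpose `qf` onto `qi` before
#'   training (off by default: the raw configuration-space path is profiled).
#' @param e0 Reference energy for the (optional) energy penalty.
#' @param quench_frames If `TRUE` (default) quench every frame for the
#'   inherent-structure profile.
#' @param polish Quasi-Newton polishing iterations passed to [train()].
#' @return Object of class `path_result`: list with `times`, `positions`
#'   (`(frames, N, d)`), `raw_energy` and `quenched_energy` (per atom),
#'   `barrier`, `arc_length`, `endpoint_distance`, `model`, `history`.
#' @export
transition_path <- function(qi, qf, spec, grid,
                            weights = loss_weights(1e3, 1e3, 0),
                            config = train_config(epochs = 20000),
                            n_hidden = 40, model_seed = 1L, align = FALSE,
                            e0 = NULL, quench_frames = TRUE, polish = 0) {
  qi <- .check_config(qi, spec)
  qf <- .check_config(qf, spec)
  if (align && spec$dim == 3L) qf <- .kabsch_align(qf, qi)
  if (is.null(e0)) e0 <- potential_energy(qi, spec)
  ep <- endpoint_pair(qi, qf, e0 = e0, window = grid$t1 - grid$t0,
                      seed = model_seed)
  model <- init_model(spec, n_hidden, seed = model_seed, t0 = grid$t0,
                      t1 = grid$t1, baseline = list(q0 = qi, qT = qf))
  fit <- train(model, grid, spec, ep, weights, config, polish = polish)
  pos <- model_positions(fit$model, grid$points)
  nf <- dim(pos)[1]
  raw <- vapply(seq_len(nf), function(k) {
    potential_energy(matrix(pos[k, , ], spec$n_atoms, spec$dim), spec)
  }, numeric(1)) / spec$n_atoms
  quenched <- rep(NA_real_, nf)
  if (quench_frames) {
    quenched <- vapply(seq_len(nf), function(k) {
      quench(matrix(pos[k, , ], spec$n_atoms, spec$dim), spec)$energy
    }, numeric(1)) / spec$n_atoms
  }
  structure(list(times = grid$points, positions = pos, raw_energy = raw,
                 quenched_energy = quenched,
                 barrier = max(raw) - raw[1],
                 arc_length = arc_length(pos),
                 endpoint_distance = sqrt(sum((qf - qi)^2)),
                 model = fit$model, history = fit$history),
            class = "path_result")
}

#' @export
print.path_result <- function(x, ...) {
  cat(sprintf(
    paste0("<path_result: %d frames, barrier %.4g eps/atom, ",
           "arc length %.4g sigma, endpoint distance %.4g sigma>\n"),
    length(x$times), x$barrier, x$arc_length, x$endpoint_distance))
  invisible(x)
}
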