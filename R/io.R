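#' Write configurations or trajectories as extended XYZ
#'
#' One frame per block: atom count line, a comment line carrying `key=value`
#' metadata (`time`, `energy`, `Lattice`, `Properties`), then one line per
#' atom with the element label, coordinates and (when present) velocities.
#' Numbers are written with 15 significant digits so round-trips are exact
#' to double precision for practical purposes.
#'
#' @param x [phase_trajectory()], or a single N x d configuration matrix.
#' @param path Output file path.
#' @param element Atom label written in column 1.
#' @param energies Optional per-frame energies recorded in the comment line.
#' @return `path`, invisibly.
#' @export
write_xyz <- function(x, path, element = "Ar", energies = NULL) {
  if (is.matrix(x)) {
    x <- list(times = 0,
              positions = array(x, c(1L, nrow(x), ncol(x))),
              velocities = NULL, spec = NULL)
  }
  pos <- x$positions
  nf <- dim(pos)[1]; n <- dim(pos)[2]; d <- dim(pos)[3]
  has_vel <- !is.null(x$velocities)
  lattice <- NULL
  if (!is.null(x$spec) && !is.null(x$spec$box)) {
    b <- x$spec$box
    m <- diag(b, nrow = 3)[seq_len(3), seq_len(3)]
    if (d == 2) m <- diag(c(b, 0), nrow = 3)
    lattice <- paste(sprintf("%.15g", as.vector(m)), collapse = " ")
  }
  props <- sprintf("species:S:1:pos:R:%d%s", d,
                   if (has_vel) sprintf(":vel:R:%d", d) else "")
  con <- file(path, "w")
  on.exit(close(con))
  for (f in seq_len(nf)) {
    meta <- sprintf('Properties=%s time=%.15g', props, x$times[f])
    if (!is.null(lattice)) meta <- sprintf('Lattice="%s" %s', lattice, meta)
    if (!is.null(energies)) meta <- sprintf("%s energy=%.15g", meta, energies[f])
    writeLines(c(as.character(n), meta), con)
    q <- matrix(pos[f, , ], n, d)
    rows <- apply(q, 1, function(r) paste(sprintf("%.15g", r), collapse = " "))
    if (has_vel) {
      v <- matrix(x$velocities[f, , ], n, d)
      rows <- paste(rows,
                    apply(v, 1, function(r)
                      paste(sprintf("%.15g", r), collapse = " ")))
    }
    writeLines(paste(element, rows), con)
  }
  invisible(path)
}

#' Read an extended XYZ file
#'
#' @param path File path.
#' @param dim Spatial dimensionality of the stored coordinates.
#' @return List with `times`, `positions` (`(frames, N, d)`),
#'   `velocities` (same shape, or `NULL`), `box` (edge lengths or `NULL`)
#'   and `comments`.  Malformed counts or ragged frames produce an error
#'   naming the offending frame.
#' @export
read_xyz <- function(path, dim = 3) {
  lines <- readLines(path)
  frames <- list()
  i <- 1L; f <- 0L
  while (i <= length(lines)) {
    if (!grepl("^\\s*\\d+\\s*$", lines[i]))
      stop(sprintf("frame %d: expected atom count at line %d", f + 1L, i))
    n <- as.integer(lines[i])
    f <- f + 1L
    if (i + 1L + n > length(lines))
      stop(sprintf("frame %d: truncated (expected %d atom lines)", f, n))
    comment <- lines[i + 1L]
    block <- lines[(i + 2L):(i + 1L + n)]
    toks <- strsplit(trimws(block), "\\s+")
    ncols <- lengths(toks)
    if (length(unique(ncols)) != 1L)
      stop(sprintf("frame %d: ragged atom lines", f))
    vals <- t(vapply(toks, function(tk) as.numeric(tk[-1]),
                     numeric(ncols[1] - 1L)))
    if (ncol(vals) < dim)
      stop(sprintf("frame %d: expected at least %d coordinate columns", f, dim))
    frames[[f]] <- list(comment = comment, pos = vals[, seq_len(dim), drop = FALSE],
                        vel = if (ncol(vals) >= 2 * dim)
                          vals[, dim + seq_len(dim), drop = FALSE] else NULL)
    i <- i + 2L + n
  }
  natoms <- vapply(frames, function(fr) nrow(fr$pos), integer(1))
  if (length(unique(natoms)) != 1L)
    stop(sprintf("frame %d: atom count %d differs from frame 1 (%d)",
                 which(natoms != natoms[1])[1], natoms[natoms != natoms[1]][1],
                 natoms[1]))
  nf <- length(frames); n <- natoms[1]
  pos <- array(0, c(nf, n, dim))
  has_vel <- !is.null(frames[[1]]$vel)
  vel <- if (has_vel) array(0, c(nf, n, dim)) else NULL
  for (k in seq_len(nf)) {
    pos[k, , ] <- frames[[k]]$pos
    if (has_vel) vel[k, , ] <- frames[[k]]$vel
  }
  meta_num <- function(comment, key) {
    m <- regmatches(comment,
                    regexpr(sprintf("%s=[-+0-9.eE]+", key), comment))
    if (!length(m)) return(NA_real_)
    as.numeric(sub(sprintf("%s=", key), "", m))
  }
  times <- vapply(frames, function(fr) meta_num(fr$comment, "time"), numeric(1))
  if (anyNA(times)) times <- seq_len(nf) - 1
  box <- NULL
  lat <- regmatches(frames[[1]]$comment,
                    regexpr('Lattice="[^"]*"', frames[[1]]$comment))
  if (length(lat)) {
    v <- as.numeric(strsplit(sub('Lattice="([^"]*)"', "\\1", lat), "\\s+")[[1]])
    m <- matrix(v, 3, 3)
    box <- diag(m)[seq_len(dim)]
  }
  list(times = times, positions = pos, velocities = vel, box = box,
       comments = vapply(frames, `[[`, character(1), "comment"))
}

#' Load and validate a pipeline run configuration
#'
#' JSON configuration with blocks `system`, `grid`, `model`, `loss`,
#' `training`, `output`.  Validation happens before any compute; unknown
#' modes, missing required keys and contradictory settings (a periodic box
#' in cluster mode) are all rejected.
#'
#' @param path JSON file path, or a named list already in memory.
#' @return Validated configuration list of class `run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- if (is.character(path)) jsonlite::read_json(path, simplifyVector = TRUE)
         else path
  need <- function(block, keys) {
    if (is.null(cfg[[block]]))
      stop(sprintf("config: missing block '%s'", block))
    miss <- setdiff(keys, names(cfg[[block]]))
    if (length(miss))
      stop(sprintf("config: block '%s' is missing %s", block,
                   paste(sQuote(miss), collapse = ", ")))
  }
  need("system", "mode")
  mode <- cfg$system$mode
  if (!mode %in% c("liquid", "cluster"))
    stop("config: system.mode must be 'liquid' or 'cluster'")
  if (mode == "liquid")
    need("system", c("n_atoms", "density", "temperature"))
  if (mode == "cluster" && !is.null(cfg$system$box))
    stop("config: cluster mode and a periodic box are mutually exclusive")
  need("grid", c("window", "n_t"))
  if (cfg$grid$n_t < 2) stop("config: grid.n_t must be >= 2")
  need("model", c("n_hidden", "seed"))
  need("training", c("epochs", "learning_rate"))
  cfg$model$activation <- cfg$model$activation %||% "tanh"
  cfg$loss <- cfg$loss %||% list()
  cfg$output <- cfg$output %||% list()
  cfg$output$log_every <- cfg$output$log_every %||% 100
  class(cfg) <- c("run_config", "list")
  cfg
}

#' Run the full pipeline described by a configuration
#'
#' Liquid mode: lattice initialization, equilibration, ground-truth NVE
#' window, action training against the endpoint pair, observable analysis.
#' Cluster mode: build/accept endpoint structures, train a transition path,
#' profile it.  All artifacts (extended XYZ trajectories, CSV logs and
#' observables, the resolved configuration with every seed) are written
#' under `out_dir`.
#'
#' @param config [read_run_config()] output, a path to a JSON config, or a
#'   config list.
#' @param out_dir Artifact directory (created if needed).
#' @return Named list of artifact paths, invisibly; the key results
#'   (`pair`, `fit`/`path`) are attached as attributes.
#' @export
run_pipeline <- function(config, out_dir) {
  cfg <- if (inherits(config, "run_config")) config else read_run_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list()
  stage <- "setup"
  on.exit({
    if (!identical(stage, "done"))
      message(sprintf("pipeline halted during stage '%s'; partial artifacts in %s",
                      stage, out_dir))
  })
  jsonlite::write_json(unclass(cfg), file.path(out_dir, "resolved_config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  paths$config <- file.path(out_dir, "resolved_config.json")
  seed <- cfg$model$seed
  tc <- train_config(epochs = cfg$training$epochs,
                     learning_rate = cfg$training$learning_rate,
                     seed = seed, log_every = cfg$output$log_every)
  lam <- cfg$loss
  weights <- loss_weights(lam$lambda_bc0 %||% 1e3, lam$lambda_bcT %||% 1e3,
                          lam$lambda_E %||% 0)

  if (cfg$system$mode == "liquid") {
    stage <- "generate"
    ini <- init_fcc_lattice(cfg$system$n_atoms, cfg$system$density)
    grid <- time_grid(0, cfg$grid$window, cfg$grid$n_t)
    stride <- round(cfg$grid$window / 0.001 / cfg$grid$n_t)
    stage <- "md"
    gen <- make_endpoint_pair(ini$spec, ini$config,
                              temperature = cfg$system$temperature,
                              window = cfg$grid$window, seed = seed,
                              stride = stride)
    paths$ground_truth <- file.path(out_dir, "ground_truth.xyz")
    write_xyz(gen$trajectory, paths$ground_truth)
    stage <- "train"
    model <- init_model(ini$spec, cfg$model$n_hidden, seed = seed,
                        t0 = 0, t1 = cfg$grid$window,
                        activation = cfg$model$activation,
                        baseline = list(q0 = gen$pair$q0, qT = gen$pair$qT))
    fit <- train(model, grid, ini$spec, gen$pair, weights, tc)
    paths$training_log <- file.path(out_dir, "training_log.csv")
    write.csv(fit$history, paths$training_log, row.names = FALSE)
    nn_traj <- phase_trajectory(
      grid$points, model_positions(fit$model, grid$points),
      model_derivatives(fit$model, grid$points, 1), ini$spec)
    paths$nn_trajectory <- file.path(out_dir, "nn_trajectory.xyz")
    write_xyz(nn_traj, paths$nn_trajectory)
    stage <- "analyze"
    r <- rmsd_per_frame(gen$trajectory, nn_traj)
    paths$rmsd <- file.path(out_dir, "rmsd.csv")
    write.csv(r, paths$rmsd, row.names = FALSE)
    gmd <- rdf(gen$trajectory, ini$spec)
    paths$rdf_md <- file.path(out_dir, "rdf_md.csv")
    write.csv(gmd, paths$rdf_md, row.names = FALSE)
    gnn <- rdf(nn_traj, ini$spec)
    paths$rdf_nn <- file.path(out_dir, "rdf_nn.csv")
    write.csv(gnn, paths$rdf_nn, row.names = FALSE)
    attr(paths, "pair") <- gen$pair
    attr(paths, "fit") <- fit
  } else {
    stage <- "generate"
    spec <- system_spec(cfg$system$n_atoms, lj = lj_params())
    structures <- list(
      lj13_icosahedron = build_lj13_icosahedron,
      lj13_cuboctahedron = build_lj13_cuboctahedron,
      lj38_fcc = build_lj38_fcc_octahedron)
    get_struct <- function(key) {
      if (!is.null(cfg$system[[key]]) && file.exists(cfg$system[[key]])) {
        x <- read_xyz(cfg$system[[key]])
        return(matrix(x$positions[1, , ], spec$n_atoms, spec$dim))
      }
      name <- cfg$system[[paste0(key, "_builder")]]
      if (is.null(name) || is.null(structures[[name]]))
        stop(sprintf("config: cluster mode needs '%s' (xyz path) or '%s_builder'",
                     key, key))
      structures[[name]]()
    }
    qi <- quench(get_struct("initial"), spec)$config
    qf <- quench(get_struct("final"), spec)$config
    grid <- time_grid(0, cfg$grid$window, cfg$grid$n_t)
    stage <- "path"
    pr <- transition_path(qi, qf, spec, grid, weights, tc,
                          n_hidden = cfg$model$n_hidden, model_seed = seed)
    paths$path_xyz <- file.path(out_dir, "path.xyz")
    write_xyz(list(times = pr$times, positions = pr$positions,
                   velocities = NULL, spec = spec),
              paths$path_xyz, energies = pr$raw_energy * spec$n_atoms)
    prof <- data.frame(frame = seq_along(pr$times) - 1L, time = pr$times,
                       raw = pr$raw_energy, quenched = pr$quenched_energy)
    paths$profile <- file.path(out_dir, "energy_profile.csv")
    write.csv(prof, paths$profile, row.names = FALSE)
    paths$training_log <- file.path(out_dir, "training_log.csv")
    write.csv(pr$history, paths$training_log, row.names = FALSE)
    attr(paths, "path") <- pr
  }
  stage <- "done"
  invisible(paths)
}
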