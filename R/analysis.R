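#' Observable series container
#'
#' A two-column data frame (abscissa, value) with a metadata attribute;
#' the common currency of the analysis routines.
#'
#' @param abscissa Strictly increasing grid (time in tau or separation in
#'   sigma).
#' @param values Per-point scalar values.
#' @param meta Named list of counts / normalization bookkeeping.
#' @param names Column names (length 2).
#' @return A `data.frame` of class `observable_series`.
#' @export
observable_series <- function(abscissa, values, meta = list(),
                              names = c("abscissa", "value")) {
  stopifnot(length(abscissa) == length(values), all(diff(abscissa) > 0),
            all(is.finite(values)))
  out <- data.frame(abscissa, values)
  colnames(out) <- names
  attr(out, "meta") <- meta
  class(out) <- c("observable_series", "data.frame")
  out
}

.traj_pos_matrix <- function(traj, what = "positions") {
  x <- if (inherits(traj, "phase_trajectory")) traj[[what]] else traj
  stopifnot(length(dim(x)) == 3L)
  x
}

#' Per-frame RMSD between two trajectories
#'
#' Frames are compared in a shared coordinate system: per frame,
#' `sqrt(mean((a - b)^2))` over all `N*d` components, in sigma.  No
#' alignment is performed; the grids and atom orderings must match.
#'
#' @param a,b [phase_trajectory()] objects (or bare position arrays on the
#'   same grid).
#' @return [observable_series()] with columns `t`, `rmsd`.
#' @export
rmsd_per_frame <- function(a, b) {
  pa <- .traj_pos_matrix(a); pb <- .traj_pos_matrix(b)
  if (!identical(dim(pa), dim(pb)))
    stop("trajectory grids/shapes do not match")
  if (inherits(a, "phase_trajectory") && inherits(b, "phase_trajectory") &&
      max(abs(a$times - b$times)) > 1e-9)
    stop("trajectory time grids do not match")
  times <- if (inherits(a, "phase_trajectory")) a$times else
    seq_len(dim(pa)[1])
  nf <- dim(pa)[1]
  qa <- matrix(pa, nf); qb <- matrix(pb, nf)
  observable_series(times, sqrt(rowMeans((qa - qb)^2)),
                    meta = list(n_atoms = dim(pa)[2]),
                    names = c("t", "rmsd"))
}

#' Per-frame RMSD between momenta of two phase trajectories
#'
#' As [rmsd_per_frame()] but on `m_i * v_i` components.
#'
#' @param a,b [phase_trajectory()] objects with matching grids.
#' @param spec [system_spec()] supplying masses; defaults to `a$spec`.
#' @return [observable_series()] with columns `t`, `rmsd`.
#' @export
momentum_rmsd_per_frame <- function(a, b, spec = a$spec) {
  va <- .traj_pos_matrix(a, "velocities")
  vb <- .traj_pos_matrix(b, "velocities")
  if (!identical(dim(va), dim(vb)))
    stop("trajectory grids/shapes do not match")
  m <- spec$masses
  pa <- sweep(va, 2, m, "*")
  pb <- sweep(vb, 2, m, "*")
  nf <- dim(va)[1]
  times <- if (inherits(a, "phase_trajectory")) a$times else seq_len(nf)
  observable_series(times, sqrt(rowMeans((matrix(pa, nf) - matrix(pb, nf))^2)),
                    meta = list(n_atoms = dim(va)[2]),
                    names = c("t", "rmsd"))
}

#' Radial distribution function
#'
#' Pair-distance histogram normalized by the ideal-gas expectation and
#' averaged over frames; requires a periodic box (minimum-image distances).
#'
#' @param traj [phase_trajectory()] or `(frames, N, d)` array.
#' @param spec [system_spec()] with a box.
#' @param r_max Histogram range; defaults to half the smallest box edge and
#'   may not exceed it.
#' @param n_bins Number of bins (default 200).
#' @return [observable_series()] with columns `r` (bin centres) and `g`.
#' @export
rdf <- function(traj, spec, r_max = NULL, n_bins = 200) {
  if (is.null(spec$box)) stop("rdf requires a periodic box")
  half <- min(spec$box) / 2
  if (is.null(r_max)) r_max <- half
  if (r_max > half + 1e-9) stop("r_max exceeds half the smallest box edge")
  pos <- .traj_pos_matrix(traj)
  nf <- dim(pos)[1]; n <- dim(pos)[2]
  counts <- .cpp_pair_histogram(pos, nf, n, r_max, as.integer(n_bins),
                                spec$box)
  w <- r_max / n_bins
  edges <- w * (0:n_bins)
  rho <- n / prod(spec$box)
  shell <- if (spec$dim == 3L) 4 / 3 * pi * diff(edges^3) else
    pi * diff(edges^2)
  g <- counts / (nf * n * rho * shell)
  observable_series(edges[-1] - w / 2, g,
                    meta = list(n_frames = nf, n_atoms = n, counts = counts,
                                rho = rho, bin_width = w),
                    names = c("r", "g"))
}

#' Velocity autocorrelation function and correlation time
#'
#' `C(t) = <v(t0 + t) . v(t0)>` averaged over all atoms and time origins,
#' normalized so `C(0) = 1`.  The correlation time `t_c` is the first sign
#' change, located by linear interpolation between the bracketing grid
#' points.
#'
#' @param traj [phase_trajectory()] on a uniform time grid.
#' @param max_lag Largest lag (in frames) to evaluate; defaults to half the
#'   trajectory.
#' @return List with `series` ([observable_series()], columns `t`, `C`) and
#'   `t_c` (first zero crossing in tau, or `NA` if none occurs).
#' @export
vaf <- function(traj, max_lag = NULL) {
  v <- .traj_pos_matrix(traj, "velocities")
  nf <- dim(v)[1]
  if (nf < 2) stop("too few frames for any lag")
  dt <- diff(traj$times)
  stopifnot(max(abs(dt - dt[1])) < 1e-9 * dt[1])
  if (is.null(max_lag)) max_lag <- nf %/% 2
  max_lag <- min(max_lag, nf - 1L)
  vm <- matrix(v, nf)
  s <- vm %*% t(vm)  # s[i, j] = sum over components of v_i . v_j
  c_raw <- vapply(0:max_lag, function(lag) {
    idx <- seq_len(nf - lag)
    mean(s[cbind(idx, idx + lag)])
  }, numeric(1))
  cn <- c_raw / c_raw[1]
  tgrid <- dt[1] * (0:max_lag)
  t_c <- NA_real_
  sc <- which(cn[-1] * cn[-length(cn)] <= 0 & cn[-length(cn)] > 0)
  if (length(sc)) {
    k <- sc[1]  # crossing between k and k+1 (1-based into cn)
    t_c <- tgrid[k] + dt[1] * cn[k] / (cn[k] - cn[k + 1])
  }
  list(series = observable_series(tgrid, cn,
                                  meta = list(n_origins = nf - max_lag),
                                  names = c("t", "C")),
       t_c = t_c)
}

#' Kinetic, potential and total energy time series
#'
#' @param traj [phase_trajectory()].
#' @param spec [system_spec()]; defaults to `traj$spec`.
#' @return List of three [observable_series()] (`kinetic`, `potential`,
#'   `total`), each with columns `t`, `E`.
#' @export
energy_series <- function(traj, spec = traj$spec) {
  nf <- length(traj$times)
  ke <- vapply(seq_len(nf), function(k) {
    0.5 * sum(spec$masses * rowSums(traj_frame(traj, k, "velocities")^2))
  }, numeric(1))
  pe <- vapply(seq_len(nf), function(k) {
    potential_energy(traj_frame(traj, k), spec)
  }, numeric(1))
  mk <- function(v) observable_series(traj$times, v, names = c("t", "E"))
  list(kinetic = mk(ke), potential = mk(pe), total = mk(ke + pe))
}
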