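#' Lennard-Jones interaction parameters
#'
#' Reduced-unit parameters of the 12-6 pair potential
#' \eqn{u(r) = 4\epsilon[(\sigma/r)^{12} - (\sigma/r)^6]}.
#'
#' @param epsilon Energy scale (reduced units, > 0).
#' @param sigma Length scale (reduced units, > 0).
#' @param cutoff Pair cutoff radius in units of `sigma`, or `NULL` for full
#'   pairwise summation. Must exceed `sigma` when given.
#' @param shift If `TRUE`, subtract the pair energy at the cutoff so the
#'   truncated potential is continuous at `r = cutoff`.
#' @return An object of class `lj_params`.
#' @export
#' @examples
#' lj_params()                      # epsilon = sigma = 1, no cutoff
#' lj_params(cutoff = 2.5, shift = TRUE)
lj_params <- function(epsilon = 1, sigma = 1, cutoff = NULL, shift = FALSE) {
  stopifnot(is.numeric(epsilon), length(epsilon) == 1L, epsilon > 0,
            is.numeric(sigma), length(sigma) == 1L, sigma > 0)
  if (!is.null(cutoff)) {
    stopifnot(is.numeric(cutoff), length(cutoff) == 1L, cutoff > sigma)
  }
  structure(list(epsilon = epsilon, sigma = sigma, cutoff = cutoff,
                 shift = isTRUE(shift)),
            class = "lj_params")
}

#' System specification
#'
#' Fixes the particle count, dimensionality, masses, optional periodic box and
#' interaction of a system, in reduced Lennard-Jones units
#' (\eqn{\epsilon = \sigma = m = 1}, time unit \eqn{\tau = \sigma\sqrt{m/\epsilon}}).
#'
#' @param n_atoms Number of atoms (>= 2, or 1 for the harmonic test system).
#' @param dim Dimensionality, 2 or 3.
#' @param masses Per-atom masses; a scalar is recycled.
#' @param box Optional periodic box edge lengths (length `dim`). When a cutoff
#'   is set, each edge must exceed twice the cutoff so the minimum-image
#'   convention is valid.
#' @param lj [lj_params()] describing the pair interaction.
#' @param potential `"lj"` for the Lennard-Jones system, `"harmonic"` for the
#'   closed-form isotropic oscillator used as a testing oracle.
#' @param stiffness Spring constant of the harmonic oracle (> 0).
#' @return An object of class `system_spec`.
#' @export
system_spec <- function(n_atoms, dim = 3, masses = 1, box = NULL,
                        lj = lj_params(), potential = c("lj", "harmonic"),
                        stiffness = 1) {
  potential <- match.arg(potential)
  stopifnot(n_atoms >= if (potential == "lj") 2L else 1L,
            dim %in% c(2L, 3L))
  masses <- rep_len(as.numeric(masses), n_atoms)
  stopifnot(all(masses > 0))
  if (!is.null(box)) {
    box <- as.numeric(box)
    stopifnot(length(box) == dim, all(box > 0))
    if (!is.null(lj$cutoff) && any(box <= 2 * lj$cutoff))
      stop("box edges must exceed twice the cutoff for minimum-image summation")
  }
  stopifnot(inherits(lj, "lj_params"), stiffness > 0)
  structure(list(n_atoms = as.integer(n_atoms), dim = as.integer(dim),
                 masses = masses, box = box, lj = lj, potential = potential,
                 stiffness = stiffness),
            class = "system_spec")
}

.check_config <- function(config, spec) {
  config <- as.matrix(config)
  if (!all(is.finite(config)))
    stop("configuration contains non-finite coordinates")
  if (nrow(config) != spec$n_atoms || ncol(config) != spec$dim)
    stop(sprintf("configuration is %d x %d but spec requires %d x %d",
                 nrow(config), ncol(config), spec$n_atoms, spec$dim))
  config
}

.box_arg <- function(spec) if (is.null(spec$box)) numeric(0) else spec$box

#' Lennard-Jones pair energy
#'
#' @param r Scalar (or vector of) pair separations, > 0.
#' @param params [lj_params()].
#' @return Pair energy `4*eps*((sig/r)^12 - (sig/r)^6)`, truncated (and
#'   shifted, if requested) at the cutoff.
#' @export
#' @examples
#' lj_pair_energy(2^(1 / 6))   # the minimum: -1
lj_pair_energy <- function(r, params = lj_params()) {
  if (any(r <= 0)) stop("invalid geometry: pair separation must be positive")
  sr6 <- (params$sigma / r)^6
  e <- 4 * params$epsilon * sr6 * (sr6 - 1)
  if (!is.null(params$cutoff)) {
    if (params$shift) {
      src6 <- (params$sigma / params$cutoff)^6
      e <- e - 4 * params$epsilon * src6 * (src6 - 1)
    }
    e[r >= params$cutoff] <- 0
  }
  e
}

#' Potential energy of a configuration
#'
#' Sums the pair potential over unique pairs, with minimum-image displacements
#' when the spec carries a periodic box.  For `potential = "harmonic"` the
#' energy is \eqn{\frac{1}{2} k \sum_i |q_i|^2}.
#'
#' @param config N x d coordinate matrix in sigma units.
#' @param spec [system_spec()].
#' @return Scalar energy in epsilon units.
#' @export
potential_energy <- function(config, spec) {
  config <- .check_config(config, spec)
  if (spec$potential == "harmonic")
    return(0.5 * spec$stiffness * sum(config^2))
  p <- spec$lj
  .cpp_lj_energy(config, p$epsilon, p$sigma, p$cutoff %||% -1, p$shift,
                 .box_arg(spec))
}

#' Forces on all atoms
#'
#' Analytic \eqn{-\nabla V}, consistent with any truncation/shift of the pair
#' potential.
#'
#' @inheritParams potential_energy
#' @return N x d matrix of force components.
#' @export
forces <- function(config, spec) {
  config <- .check_config(config, spec)
  if (spec$potential == "harmonic") return(-spec$stiffness * config)
  p <- spec$lj
  .cpp_lj_forces(config, p$epsilon, p$sigma, p$cutoff %||% -1, p$shift,
                 .box_arg(spec))
}

#' Total energy
#'
#' Kinetic plus potential energy,
#' \eqn{E = \sum_i \frac{1}{2} m_i |v_i|^2 + V(Q)}.
#'
#' @inheritParams potential_energy
#' @param velocities N x d velocity matrix.
#' @return Scalar total energy.
#' @export
total_energy <- function(config, velocities, spec) {
  velocities <- .check_config(velocities, spec)
  0.5 * sum(spec$masses * rowSums(velocities^2)) + potential_energy(config, spec)
}

#' Harmonic reference potential
#'
#' Closed-form isotropic oscillator \eqn{V = \frac{1}{2} k \sum_i |q_i|^2},
#' \eqn{F = -k q}; used as an analytic oracle by the tests and the
#' boundary-value training examples.
#'
#' @param config N x d coordinate matrix.
#' @param stiffness Spring constant k > 0.
#' @return List with elements `energy` and `forces`.
#' @export
harmonic_reference <- function(config, stiffness = 1) {
  stopifnot(stiffness > 0)
  config <- as.matrix(config)
  list(energy = 0.5 * stiffness * sum(config^2),
       forces = -stiffness * config)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# --- internal multi-frame dispatch used by the action loss -------------------

# pos: (F, N, d) array.  Returns list(energy = F-vector, grad = (F, N, d)).
.pe_grad_multi <- function(pos, spec) {
  if (spec$potential == "harmonic") {
    en <- 0.5 * spec$stiffness * apply(pos, 1, function(x) sum(x^2))
    return(list(energy = en, grad = spec$stiffness * pos))
  }
  p <- spec$lj
  out <- .cpp_lj_multi(pos, dim(pos)[1], spec$n_atoms, p$epsilon, p$sigma,
                       p$cutoff %||% -1, p$shift, .box_arg(spec))
  dim(out$grad) <- dim(pos)
  list(energy = out$energy, grad = out$grad)
}

# Hessian-vector products, frame by frame: pos and v are (F, N, d).
.hvp_multi <- function(pos, v, spec) {
  if (spec$potential == "harmonic") return(spec$stiffness * v)
  p <- spec$lj
  out <- .cpp_lj_multi_hvp(pos, v, dim(pos)[1], spec$n_atoms, p$epsilon,
                           p$sigma, p$cutoff %||% -1, p$shift, .box_arg(spec))
  dim(out) <- dim(pos)
  out
}
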