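#' @title Neural trajectory representation
#' @description A single-hidden-layer network mapping scalar time to all
#' `d * N` coordinates, `Q(t) = W2 act(w1 s(t) + b1) + b2 (+ baseline)`,
#' where `s(t)` maps the physical window `[t0, t1]` to `[0, 1]`.  Because the
#' map is a small closed-form composition, first and second time derivatives
#' (velocity and acceleration) are evaluated exactly, not by finite
#' differences.  Optionally the network output is added to the straight-line
#' interpolation between the boundary configurations, which starts training
#' from the linear path; the boundary penalties remain in force either way.
#' @name trajectory_model
NULL

# activation value and its first three derivatives, as functions of the
# pre-activation z; all must be C^3 (ReLU-like choices are rejected: a
# vanishing second derivative kills the action's curvature dependence)
.act_funs <- function(name) {
  switch(name,
    tanh = function(z) {
      h <- tanh(z); u <- 1 - h^2
      list(h = h, d1 = u, d2 = -2 * h * u, d3 = -2 * u * (u - 2 * h^2))
    },
    softplus = function(z) {
      s <- 1 / (1 + exp(-z)); su <- s * (1 - s)
      list(h = log1p(exp(-abs(z))) + pmax(z, 0), d1 = s, d2 = su,
           d3 = su * (1 - 2 * s))
    },
    stop(sprintf("unsupported activation '%s' (use 'tanh' or 'softplus')", name))
  )
}

#' Initialize a trajectory model
#'
#' @param spec [system_spec()]; fixes the output dimension `d * N`.
#' @param n_hidden Hidden-layer width (>= 1).
#' @param seed Integer seed for the weight draw (reproducible).
#' @param t0,t1 Physical time window represented by the model.
#' @param activation `"tanh"` (default) or `"softplus"`; must be twice
#'   continuously differentiable.
#' @param baseline Optional list with `q0` and `qT` (N x d matrices): the
#'   model output is added to the linear interpolation between them.
#' @param freq_scale Scale of the input-side weights, which sets the range
#'   of "frequencies" the hidden units cover across the normalized window;
#'   defaults to `max(2, n_hidden / 4)`.  With O(1) input weights every
#'   tanh unit is nearly linear over the window and the network cannot
#'   express the accelerations the action integrand demands.
#' @return Object of class `trajectory_model`.  Input-side weights are drawn
#'   uniform on `(-freq_scale, freq_scale)` with biases placing each unit's
#'   transition uniformly inside the window; output-side weights normal with
#'   sd `0.01 / sqrt(n_hidden)` so the initial path hugs the baseline.
#' @export
init_model <- function(spec, n_hidden, seed = 1L, t0 = 0, t1 = 1,
                       activation = "tanh", baseline = NULL,
                       freq_scale = NULL) {
  stopifnot(n_hidden >= 1, t1 > t0)
  .act_funs(activation)  # validate early
  if (is.null(freq_scale)) freq_scale <- max(2, n_hidden / 4)
  ndof <- spec$n_atoms * spec$dim
  par <- withr_seed(seed, {
    w1 <- runif(n_hidden, -freq_scale, freq_scale)
    list(w1 = w1,
         b1 = -w1 * runif(n_hidden),
         W2 = matrix(rnorm(ndof * n_hidden, sd = 0.01 / sqrt(n_hidden)),
                     ndof, n_hidden),
         b2 = rnorm(ndof, sd = 0.01 / sqrt(n_hidden)))
  })
  if (!is.null(baseline)) {
    baseline <- list(q0 = as.matrix(baseline$q0), qT = as.matrix(baseline$qT))
    stopifnot(nrow(baseline$q0) == spec$n_atoms,
              identical(dim(baseline$q0), dim(baseline$qT)))
  }
  structure(list(w1 = par$w1, b1 = par$b1, W2 = par$W2, b2 = par$b2,
                 n_hidden = as.integer(n_hidden), activation = activation,
                 t0 = t0, t1 = t1, n_atoms = spec$n_atoms, dim = spec$dim,
                 baseline = baseline),
            class = "trajectory_model")
}

#' @export
print.trajectory_model <- function(x, ...) {
  cat(sprintf(
    "<trajectory_model: 1 -> %d -> %d (%s), t in [%g, %g]%s>\n",
    x$n_hidden, x$n_atoms * x$dim, x$activation, x$t0, x$t1,
    if (is.null(x$baseline)) "" else ", linear baseline"))
  invisible(x)
}

# forward pass on a vector of times; returns hidden activations and their
# first/second physical-time derivatives as (n_t, n_hidden) matrices
.model_hidden <- function(model, tvec, third = FALSE) {
  a <- 1 / (model$t1 - model$t0)
  s <- (tvec - model$t0) * a
  z <- outer(s, model$w1) + rep(model$b1, each = length(s))
  act <- .act_funs(model$activation)(z)
  h1 <- a * sweep(act$d1, 2, model$w1, "*")
  h2 <- a^2 * sweep(act$d2, 2, model$w1^2, "*")
  out <- list(s = s, a = a, h = act$h, d1 = act$d1, d2 = act$d2,
              h1 = h1, h2 = h2)
  if (third) out$d3 <- act$d3
  out
}

.baseline_eval <- function(model, tvec) {
  ndof <- model$n_atoms * model$dim
  if (is.null(model$baseline))
    return(list(q = matrix(0, length(tvec), ndof),
                qdot = numeric(ndof)))
  q0 <- as.vector(model$baseline$q0)
  qT <- as.vector(model$baseline$qT)
  s <- (tvec - model$t0) / (model$t1 - model$t0)
  list(q = outer(1 - s, q0) + outer(s, qT),
       qdot = (qT - q0) / (model$t1 - model$t0))
}

# (n_t, ndof) matrices of positions and exact first/second time derivatives
.model_eval <- function(model, tvec) {
  hid <- .model_hidden(model, tvec)
  base <- .baseline_eval(model, tvec)
  q <- base$q + hid$h %*% t(model$W2) +
    rep(model$b2, each = length(tvec))
  qd <- sweep(hid$h1 %*% t(model$W2), 2, base$qdot, "+")
  qdd <- hid$h2 %*% t(model$W2)
  list(q = q, qd = qd, qdd = qdd, hid = hid, base = base)
}

#' Evaluate model positions
#'
#' @param model [init_model()] output.
#' @param t Scalar time or vector of times.
#' @return For scalar `t`, an N x d configuration matrix; for vector `t`, a
#'   `(length(t), N, d)` array.
#' @export
model_positions <- function(model, t) {
  q <- .model_eval(model, t)$q
  if (length(t) == 1L) return(matrix(q[1, ], model$n_atoms, model$dim))
  array(q, c(length(t), model$n_atoms, model$dim))
}

#' Exact time derivatives of model positions
#'
#' First derivative = velocity, second = acceleration, both computed in
#' closed form through the chain rule (time normalization included) rather
#' than by finite differences.
#'
#' @inheritParams model_positions
#' @param order 1 or 2.
#' @return Same shape convention as [model_positions()].
#' @export
model_derivatives <- function(model, t, order = 1) {
  if (!order %in% c(1, 2)) stop("order must be 1 or 2")
  ev <- .model_eval(model, t)
  d <- if (order == 1) ev$qd else ev$qdd
  if (length(t) == 1L) return(matrix(d[1, ], model$n_atoms, model$dim))
  array(d, c(length(t), model$n_atoms, model$dim))
}

# --- flat parameter vector interface (optimizer + serialization) ------------

.par_flatten <- function(model) {
  c(model$w1, model$b1, as.vector(model$W2), model$b2)
}

.par_unflatten <- function(model, par) {
  nh <- model$n_hidden
  ndof <- model$n_atoms * model$dim
  model$w1 <- par[seq_len(nh)]
  model$b1 <- par[nh + seq_len(nh)]
  model$W2 <- matrix(par[2 * nh + seq_len(ndof * nh)], ndof, nh)
  model$b2 <- par[2 * nh + ndof * nh + seq_len(ndof)]
  model
}

#' Serialize / restore a trajectory model as JSON
#'
#' Plain-text checkpoint: every layer stored as shape + values.
#'
#' @param model [init_model()] output.
#' @param path File path.
#' @return `model_from_json` returns the restored `trajectory_model`.
#' @export
model_to_json <- function(model, path) {
  payload <- list(
    w1 = model$w1, b1 = model$b1,
    W2 = list(shape = dim(model$W2), values = as.vector(model$W2)),
    b2 = model$b2, n_hidden = model$n_hidden, activation = model$activation,
    t0 = model$t0, t1 = model$t1, n_atoms = model$n_atoms, dim = model$dim,
    baseline = if (is.null(model$baseline)) NULL else
      list(q0 = as.vector(model$baseline$q0), qT = as.vector(model$baseline$qT))
  )
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname model_to_json
#' @export
model_from_json <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  baseline <- NULL
  if (!is.null(p$baseline)) {
    baseline <- list(q0 = matrix(p$baseline$q0, p$n_atoms, p$dim),
                     qT = matrix(p$baseline$qT, p$n_atoms, p$dim))
  }
  structure(list(w1 = p$w1, b1 = p$b1,
                 W2 = matrix(p$W2$values, p$W2$shape[1], p$W2$shape[2]),
                 b2 = p$b2, n_hidden = as.integer(p$n_hidden),
                 activation = p$activation, t0 = p$t0, t1 = p$t1,
                 n_atoms = as.integer(p$n_atoms), dim = as.integer(p$dim),
                 baseline = baseline),
            class = "trajectory_model")
}
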