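#' Uniform time grid for the discretized action
#'
#' @param t0,t1 Window endpoints (t1 > t0), tau units.
#' @param n_t Number of time increments (>= 2); the grid has `n_t + 1` points.
#' @return Object of class `time_grid` with fields `t0`, `t1`, `n_t`,
#'   `dt = (t1 - t0) / n_t` and `points`.
#' @export
time_grid <- function(t0, t1, n_t) {
  stopifnot(t1 > t0, n_t >= 2)
  n_t <- as.integer(n_t)
  structure(list(t0 = t0, t1 = t1, n_t = n_t, dt = (t1 - t0) / n_t,
                 points = seq(t0, t1, length.out = n_t + 1)),
            class = "time_grid")
}

#' Penalty weights of the training loss
#'
#' The lambda hyperparameters multiplying the initial-boundary,
#' final-boundary and energy-conservation penalties; chosen by hand or by
#' [random_search_lambdas()].
#'
#' @param lambda_bc0,lambda_bcT,lambda_E Non-negative weights.
#' @return Object of class `loss_weights`.
#' @export
loss_weights <- function(lambda_bc0 = 1, lambda_bcT = 1, lambda_E = 0) {
  stopifnot(lambda_bc0 >= 0, lambda_bcT >= 0, lambda_E >= 0)
  structure(list(lambda_bc0 = lambda_bc0, lambda_bcT = lambda_bcT,
                 lambda_E = lambda_E),
            class = "loss_weights")
}

# quadrature weights over the n_t + 1 grid points
.quad_weights <- function(grid, quadrature) {
  w <- rep(grid$dt, grid$n_t + 1)
  if (quadrature == "trapezoid") w[c(1L, grid$n_t + 1L)] <- grid$dt / 2
  w
}

# Full loss evaluation with optional analytic parameter gradient.
#
# The Onsager-Machlup integrand at grid point t_k is |R_k|^2 with
# R_k = m qdd_k + grad V(Q_k); the backward pass needs, per grid point, the
# adjoints of Q, Qdot, Qddot:
#   A_k = 2 w_k H(Q_k) R_k + 2 lambda_E w_k (E_k - E0) grad V + boundary terms
#   B_k = 2 lambda_E w_k (E_k - E0) m Qdot_k
#   C_k = 2 w_k m R_k
# (H = Hessian of V, applied as a Hessian-vector product) which are then
# pushed through the closed-form network Jacobians.
.loss_eval <- function(model, grid, spec, endpoints, weights,
                       want_grad = FALSE, quadrature = "riemann") {
  nk <- grid$n_t + 1L
  ndof <- spec$n_atoms * spec$dim
  mvec <- rep(spec$masses, spec$dim)
  wq <- .quad_weights(grid, quadrature)
  ev <- .model_eval(model, grid$points)
  qarr <- array(ev$q, c(nk, spec$n_atoms, spec$dim))
  pe <- .pe_grad_multi(qarr, spec)
  gmat <- matrix(pe$grad, nk, ndof)
  r <- sweep(ev$qdd, 2, mvec, "*") + gmat
  action <- sum(wq * rowSums(r^2))

  ek <- 0.5 * rowSums(sweep(ev$qd^2, 2, mvec, "*")) + pe$energy
  de <- ek - endpoints$e0
  energy <- sum(wq * de^2)

  dq0 <- ev$q[1, ] - as.vector(endpoints$q0)
  dqT <- ev$q[nk, ] - as.vector(endpoints$qT)
  bc0 <- sum(dq0^2)
  bcT <- sum(dqT^2)
  total <- action + weights$lambda_bc0 * bc0 + weights$lambda_bcT * bcT +
    weights$lambda_E * energy
  breakdown <- structure(list(action = action, bc0 = bc0, bcT = bcT,
                              energy = energy, total = total),
                         class = "loss_breakdown")
  if (!want_grad) return(list(breakdown = breakdown))

  hvp <- matrix(.hvp_multi(qarr, array(r, c(nk, spec$n_atoms, spec$dim)), spec),
                nk, ndof)
  escale <- 2 * weights$lambda_E * wq * de
  a_adj <- 2 * wq * hvp + escale * gmat
  a_adj[1, ] <- a_adj[1, ] + 2 * weights$lambda_bc0 * dq0
  a_adj[nk, ] <- a_adj[nk, ] + 2 * weights$lambda_bcT * dqT
  b_adj <- escale * sweep(ev$qd, 2, mvec, "*")
  c_adj <- 2 * wq * sweep(r, 2, mvec, "*")

  hid <- .model_hidden(model, grid$points, third = TRUE)
  a <- hid$a
  s <- hid$s
  w1 <- model$w1

  g_w2 <- t(a_adj) %*% hid$h + t(b_adj) %*% hid$h1 + t(c_adj) %*% hid$h2
  g_b2 <- colSums(a_adj)

  alpha <- a_adj %*% model$W2
  beta <- b_adj %*% model$W2
  gamma <- c_adj %*% model$W2

  wd2 <- sweep(hid$d2, 2, w1, "*")          # act'' * w1
  wd3 <- sweep(hid$d3, 2, w1^2, "*")        # act''' * w1^2
  dh_dw1 <- s * hid$d1
  dh1_dw1 <- a * hid$d1 + a * s * wd2
  dh2_dw1 <- 2 * a^2 * wd2 + a^2 * s * wd3
  g_w1 <- colSums(alpha * dh_dw1 + beta * dh1_dw1 + gamma * dh2_dw1)
  g_b1 <- colSums(alpha * hid$d1 + beta * (a * wd2) + gamma * (a^2 * wd3))

  list(breakdown = breakdown,
       grad = c(g_w1, g_b1, as.vector(g_w2), g_b2))
}

#' Discretized Onsager-Machlup action of a model trajectory
#'
#' Riemann-sum evaluation of
#' \eqn{\int \sum_i |m_i \ddot q_i(t) + \nabla_i V(Q(t))|^2 \, dt}
#' over the grid, with accelerations from the model's exact second time
#' derivative and the potential gradient from the force field.  Zero exactly
#' on a Newtonian path (up to discretization); always non-negative.  The
#' overall constant prefactor of the action is set to 1: only the minimizer
#' matters and the penalty weights absorb scale.
#'
#' @param model [init_model()] output.
#' @param grid [time_grid()].
#' @param spec [system_spec()].
#' @param quadrature `"riemann"` (uniform weights at all `n_t + 1` points,
#'   default) or `"trapezoid"` (half weights at the two boundary points).
#' @return Scalar action value (>= 0).
#' @export
om_action <- function(model, grid, spec, quadrature = "riemann") {
  nk <- grid$n_t + 1L
  mvec <- rep(spec$masses, spec$dim)
  wq <- .quad_weights(grid, quadrature)
  ev <- .model_eval(model, grid$points)
  qarr <- array(ev$q, c(nk, spec$n_atoms, spec$dim))
  pe <- .pe_grad_multi(qarr, spec)
  r <- sweep(ev$qdd, 2, mvec, "*") + matrix(pe$grad, nk, spec$n_atoms * spec$dim)
  sum(wq * rowSums(r^2))
}

#' Onsager-Machlup action of a discrete path
#'
#' Evaluates the same integrand on a stored path (e.g. an MD trajectory
#' restricted to the coarse grid, or a straight-line interpolation), with
#' accelerations from central second differences at the interior grid
#' points.  The two boundary points are excluded (no centred stencil there).
#'
#' @param positions `(frames, N, d)` array on a uniform time grid.
#' @param times Frame times (uniformly spaced).
#' @param spec [system_spec()].
#' @return Scalar action value.
#' @export
om_action_discrete <- function(positions, times, spec) {
  nk <- dim(positions)[1]
  stopifnot(nk >= 3, length(times) == nk)
  dt <- diff(times)
  stopifnot(max(abs(dt - dt[1])) < 1e-9 * dt[1])
  dt <- dt[1]
  ndof <- spec$n_atoms * spec$dim
  q <- matrix(positions, nk, ndof)
  qdd <- (q[3:nk, , drop = FALSE] - 2 * q[2:(nk - 1), , drop = FALSE] +
            q[1:(nk - 2), , drop = FALSE]) / dt^2
  interior <- array(q[2:(nk - 1), ], c(nk - 2L, spec$n_atoms, spec$dim))
  pe <- .pe_grad_multi(interior, spec)
  mvec <- rep(spec$masses, spec$dim)
  r <- sweep(qdd, 2, mvec, "*") + matrix(pe$grad, nk - 2L, ndof)
  dt * sum(r^2)
}

#' Boundary-condition penalties
#'
#' Squared deviation of the model path from the fixed endpoint
#' configurations: `bc0 = |Q(t0) - Q0|^2`, `bcT = |Q(t1) - QT|^2` (sums of
#' squared coordinate deviations).
#'
#' @inheritParams om_action
#' @param endpoints [endpoint_pair()].
#' @return List with `bc0` and `bcT`.
#' @export
boundary_penalty <- function(model, grid, endpoints) {
  q <- .model_eval(model, c(grid$t0, grid$t1))$q
  list(bc0 = sum((q[1, ] - as.vector(endpoints$q0))^2),
       bcT = sum((q[2, ] - as.vector(endpoints$qT))^2))
}

#' Energy-conservation penalty
#'
#' \eqn{\Delta t \sum_k (E(Q(t_k), \dot Q(t_k)) - E_0)^2} over all grid
#' points including the boundaries, with velocities from the model's exact
#' first derivative.
#'
#' @inheritParams om_action
#' @param e0 Reference total energy.
#' @return Scalar penalty (>= 0).
#' @export
energy_penalty <- function(model, grid, spec, e0, quadrature = "riemann") {
  nk <- grid$n_t + 1L
  mvec <- rep(spec$masses, spec$dim)
  wq <- .quad_weights(grid, quadrature)
  ev <- .model_eval(model, grid$points)
  qarr <- array(ev$q, c(nk, spec$n_atoms, spec$dim))
  pe <- .pe_grad_multi(qarr, spec)
  ek <- 0.5 * rowSums(sweep(ev$qd^2, 2, mvec, "*")) + pe$energy
  sum(wq * (ek - e0)^2)
}

#' Full training loss
#'
#' `total = action + lambda_bc0 * bc0 + lambda_bcT * bcT + lambda_E * energy`.
#'
#' @inheritParams om_action
#' @param endpoints [endpoint_pair()].
#' @param weights [loss_weights()].
#' @return Object of class `loss_breakdown`: list with `action`, `bc0`,
#'   `bcT`, `energy`, `total`.
#' @export
total_loss <- function(model, grid, spec, endpoints, weights,
                       quadrature = "riemann") {
  .loss_eval(model, grid, spec, endpoints, weights,
             quadrature = quadrature)$breakdown
}

#' @export
print.loss_breakdown <- function(x, ...) {
  cat(sprintf(
    "action %.6g | bc0 %.6g | bcT %.6g | energy %.6g | total %.6g\n",
    x$action, x$bc0, x$bcT, x$energy, x$total))
  invisible(x)
}
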