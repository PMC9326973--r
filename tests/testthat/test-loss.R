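# small harmonic and LJ toys used throughout
hspec <- system_spec(2, potential = "harmonic", stiffness = 1.5)

lj_toy <- function() {
  spec <- system_spec(3, lj = lj_params())
  q0 <- matrix(c(0, 0, 0, 1.2, 0, 0, 0.5, 1.1, 0.2), 3, 3, byrow = TRUE)
  qT <- q0 + 0.3
  list(spec = spec, q0 = q0, qT = qT,
       ep = endpoint_pair(q0, qT, e0 = potential_energy(q0, spec) + 0.4,
                          window = 0.5),
       grid = time_grid(0, 0.5, 8))
}

# a model whose path is exactly the linear interpolation q0 -> qT
linear_model <- function(spec, q0, qT, t1) {
  m <- init_model(spec, 4, seed = 1, t1 = t1,
                  baseline = list(q0 = q0, qT = qT))
  m$W2[] <- 0
  m$b2[] <- 0
  m
}

test_that("om_action vanishes on a frozen minimum", {
  qmin <- lj13_min()$config
  spec <- free_spec(13)
  m <- linear_model(spec, qmin, qmin, 1)
  expect_lt(om_action(m, time_grid(0, 1, 10), spec), 1e-10)
})

test_that("om_action on a straight harmonic path matches dense quadrature", {
  k <- 1.5
  q0 <- matrix(c(1, 0, 0, 0, -1, 0), 2, 3, byrow = TRUE)
  qT <- q0 + matrix(c(0.5, 0.2, 0, -0.3, 0.4, 0.1), 2, 3, byrow = TRUE)
  T1 <- 2
  m <- linear_model(hspec, q0, qT, T1)
  # independent oracle: brute-force Riemann sum at a 100x finer grid, using
  # only the closed-form harmonic integrand k^2 |q(t)|^2 (qddot = 0)
  nfine <- 80000
  tf <- seq(0, T1, length.out = nfine + 1)
  s <- tf / T1
  qf <- outer(1 - s, as.vector(q0)) + outer(s, as.vector(qT))
  oracle <- (T1 / nfine) * sum((k * qf)^2)
  act <- om_action(m, time_grid(0, T1, 800), hspec)
  expect_equal(act, oracle, tolerance = 0.01)
  # discretization convergence: Riemann rule, observed order >= 1
  e1 <- abs(om_action(m, time_grid(0, T1, 100), hspec) - oracle)
  e2 <- abs(om_action(m, time_grid(0, T1, 200), hspec) - oracle)
  expect_gt(e1 / e2, 1.8)
  # trapezoid weights converge too and differ only by the boundary halves
  expect_equal(om_action(m, time_grid(0, T1, 400), hspec,
                         quadrature = "trapezoid"),
               oracle, tolerance = 0.01)
})

test_that("om_action_discrete nulls Newtonian paths up to discretization", {
  # exact harmonic solution sampled on the grid: residual is O(dt^2) per
  # point, so the discrete action falls rapidly with n_t
  k <- 1.5; w <- sqrt(k)
  T1 <- 2
  act_at <- function(nt) {
    tg <- seq(0, T1, length.out = nt + 1)
    q <- array(0, c(nt + 1, 2, 3))
    q[, 1, 1] <- cos(w * tg)
    q[, 2, 2] <- 0.5 * sin(w * tg)
    om_action_discrete(q, tg, hspec)
  }
  expect_gt(act_at(25) / act_at(50), 8)  # ~O(dt^4) -> factor 16
})

test_that("om_action is invariant under consistent atom relabeling", {
  toy <- lj_toy()
  m <- init_model(toy$spec, 6, seed = 3, t1 = 0.5,
                  baseline = list(q0 = toy$q0, qT = toy$qT))
  a1 <- om_action(m, toy$grid, toy$spec)
  perm <- c(3, 1, 2)
  mp <- m
  # relabel atoms in baseline and in the output layer rows (atom index is
  # the fastest-varying index of the flattened N x d output)
  idx <- as.vector(matrix(seq_len(9), 3, 3)[perm, ])
  mp$W2 <- m$W2[idx, ]
  mp$b2 <- m$b2[idx]
  mp$baseline <- list(q0 = toy$q0[perm, ], qT = toy$qT[perm, ])
  expect_equal(om_action(mp, toy$grid, toy$spec), a1, tolerance = 1e-10)
})

test_that("boundary penalties follow their definition and symmetry", {
  toy <- lj_toy()
  m <- linear_model(toy$spec, toy$q0, toy$qT, 0.5)
  bp <- boundary_penalty(m, toy$grid, toy$ep)
  expect_equal(bp$bc0, 0, tolerance = 1e-20)
  expect_equal(bp$bcT, 0, tolerance = 1e-20)
  # uniform displacement delta at t1 only: bcT = N d delta^2
  delta <- 0.05
  m2 <- linear_model(toy$spec, toy$q0, toy$qT + delta, 0.5)
  bp2 <- boundary_penalty(m2, toy$grid, toy$ep)
  expect_equal(bp2$bcT, 9 * delta^2)
  expect_equal(bp2$bc0, 0)
  # swapping endpoints swaps the penalties (checked on a constant path,
  # where Q(t0) = Q(t1) and the symmetry is exact)
  cfg <- toy$q0 + 0.2
  mc <- linear_model(toy$spec, cfg, cfg, 0.5)
  bpc <- boundary_penalty(mc, toy$grid, toy$ep)
  eps <- endpoint_pair(toy$ep$qT, toy$ep$q0, toy$ep$e0, 0.5)
  bps <- boundary_penalty(mc, toy$grid, eps)
  expect_equal(bps$bc0, bpc$bcT)
  expect_equal(bps$bcT, bpc$bc0)
})

test_that("energy penalty follows its definition", {
  toy <- lj_toy()
  m <- linear_model(toy$spec, toy$q0, toy$q0, 0.5)  # frozen at q0
  e_true <- potential_energy(toy$q0, toy$spec)
  expect_equal(energy_penalty(m, toy$grid, toy$spec, e_true), 0,
               tolerance = 1e-18)
  # constant offset dE at every grid point: dt * (n_t + 1) * dE^2
  de <- 0.3
  expect_equal(energy_penalty(m, toy$grid, toy$spec, e_true + de),
               toy$grid$dt * 9 * de^2)
})

test_that("total loss composes its terms and its gradient is exact", {
  toy <- lj_toy()
  w <- loss_weights(3, 5, 2)
  m <- init_model(toy$spec, 7, seed = 3, t1 = 0.5,
                  baseline = list(q0 = toy$q0, qT = toy$qT))
  m$W2 <- m$W2 * 30
  b <- total_loss(m, toy$grid, toy$spec, toy$ep, w)
  expect_equal(b$total,
               b$action + 3 * b$bc0 + 5 * b$bcT + 2 * b$energy)
  expect_equal(b$action, om_action(m, toy$grid, toy$spec))
  expect_equal(b$energy,
               energy_penalty(m, toy$grid, toy$spec, toy$ep$e0))
  # all lambdas zero: total equals the bare action
  b0 <- total_loss(m, toy$grid, toy$spec, toy$ep, loss_weights(0, 0, 0))
  expect_equal(b0$total, b0$action)
  # analytic parameter gradient vs central differences
  ev <- ompath:::.loss_eval(m, toy$grid, toy$spec, toy$ep, w,
                            want_grad = TRUE)
  par <- ompath:::.par_flatten(m)
  h <- 1e-6
  idx <- round(seq(1, length(par), length.out = 25))
  for (i in idx) {
    pp <- par; pp[i] <- pp[i] + h
    fp <- ompath:::.loss_eval(ompath:::.par_unflatten(m, pp), toy$grid,
                              toy$spec, toy$ep, w)$breakdown$total
    pp[i] <- par[i] - h
    fm <- ompath:::.loss_eval(ompath:::.par_unflatten(m, pp), toy$grid,
                              toy$spec, toy$ep, w)$breakdown$total
    expect_equal(ev$grad[i], (fp - fm) / (2 * h),
                 tolerance = 1e-4 * max(1, abs(ev$grad[i])))
  }
})

test_that("grid and weight constructors validate", {
  expect_error(time_grid(0, 0, 5))
  expect_error(time_grid(0, 1, 1))
  g <- time_grid(0, 0.5, 25)
  expect_equal(g$dt, 0.02)
  expect_length(g$points, 26)
  expect_error(loss_weights(-1, 0, 0))
})
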