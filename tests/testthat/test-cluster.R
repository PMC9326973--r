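test_that("icosahedral seed has the right geometry and quenches to -44.33", {
  q <- build_lj13_icosahedron()
  expect_equal(nrow(q), 13)
  d_center <- sqrt(rowSums(sweep(q[-1, ], 2, q[1, ], "-")^2))
  expect_lt(max(d_center), 1.2)
  expect_lt(diff(range(d_center)), 1e-12)   # icosahedral symmetry
  qn <- lj13_min()
  expect_equal(qn$energy, -44.326801, tolerance = 1e-6)
})

test_that("relaxed cuboctahedron is a stationary point distinct from the minimum", {
  q <- build_lj13_cuboctahedron()
  expect_equal(nrow(q), 13)
  f <- forces(q, free_spec(13))
  expect_lt(max(abs(f)), 1e-6)
  e <- potential_energy(q, free_spec(13))
  expect_gt(e, lj13_min()$energy + 1)  # clearly above the global minimum
})

test_that("38-atom FCC seed is octahedrally symmetric and quenches to the global minimum", {
  q <- build_lj38_fcc_octahedron()
  expect_equal(nrow(q), 38)
  # invariance (as a point set) under the octahedral generators
  rot <- matrix(c(0, -1, 0, 1, 0, 0, 0, 0, 1), 3, 3)   # 90 deg about z
  mir <- diag(c(-1, 1, 1))
  for (op in list(rot, mir)) {
    qr <- q %*% t(op)
    dmat <- as.matrix(dist(rbind(q, qr)))[1:38, 39:76]
    expect_lt(max(apply(dmat, 2, min)), 1e-6)
  }
  qn <- memo("lj38_fcc_min", quench(q, free_spec(38)))
  expect_equal(qn$energy, -173.928427, tolerance = 1e-5)
})

test_that("basin hopping is monotone, reproducible and finds the LJ13 minimum", {
  spec <- free_spec(13)
  set.seed(99)
  found <- 0L
  for (s in 1:3) {
    start <- random_cluster(13, seed = 100 + s, spread = 0.75, min_sep = 0.9)
    bh <- basin_hop(start, spec, n_steps = 60, seed = s)
    expect_true(all(diff(bh$trace$best) <= 0))
    if (abs(bh$energy - lj13_min()$energy) < 1e-5) found <- found + 1L
  }
  expect_gte(found, 2L)
  # same seed, same hop sequence
  start <- random_cluster(13, seed = 101, spread = 0.75, min_sep = 0.9)
  b1 <- basin_hop(start, spec, n_steps = 15, seed = 7)
  b2 <- basin_hop(start, spec, n_steps = 15, seed = 7)
  expect_identical(b1$trace, b2$trace)
})

test_that("quench is idempotent and recovers a perturbed minimum", {
  spec <- free_spec(13)
  qmin <- lj13_min()
  again <- quench(qmin$config, spec)
  expect_lt(max(abs(again$config - qmin$config)), 1e-6)
  set.seed(5)
  noisy <- qmin$config + matrix(runif(39, -0.05, 0.05), 13, 3)
  back <- quench(noisy, spec)
  expect_equal(back$energy, qmin$energy, tolerance = 1e-6)
  expect_lte(back$energy, potential_energy(noisy, spec))
})

test_that("arc length is a path metric", {
  # uniform shift of every component by delta over one step: sqrt(N d) delta
  n <- 4; d <- 3; delta <- 0.2
  path <- array(0, c(2, n, d))
  path[2, , ] <- delta
  expect_equal(arc_length(path), sqrt(n * d) * delta)
  # straight-line path at any sampling: exactly the endpoint distance
  q0 <- random_cluster(n, seed = 1)
  qT <- random_cluster(n, seed = 2)
  for (nf in c(2, 7, 23)) {
    s <- seq(0, 1, length.out = nf)
    line <- array(outer(1 - s, as.vector(q0)) + outer(s, as.vector(qT)),
                  c(nf, n, d))
    expect_equal(arc_length(line), sqrt(sum((qT - q0)^2)), tolerance = 1e-12)
  }
  # invariant under a global rotation applied to all frames
  set.seed(3)
  path <- array(rnorm(5 * n * d), c(5, n, d))
  th <- 0.7
  rot <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  rotated <- path
  for (k in 1:5) rotated[k, , ] <- path[k, , ] %*% rot
  expect_equal(arc_length(rotated), arc_length(path), tolerance = 1e-12)
  # additive over concatenated sub-paths
  expect_equal(arc_length(path[1:3, , ]) + arc_length(path[3:5, , ]),
               arc_length(path), tolerance = 1e-12)
})

test_that("degenerate transition path (qi = qf) is flat and short", {
  spec <- free_spec(13)
  qmin <- lj13_min()$config
  grid <- time_grid(0, 0.5, 10)
  pr <- transition_path(qmin, qmin, spec, grid,
                        config = train_config(epochs = 200,
                                              learning_rate = 1e-3),
                        n_hidden = 10, quench_frames = FALSE)
  expect_lt(pr$arc_length, 0.05)
  expect_lt(diff(range(pr$raw_energy)), 1e-4)
  expect_equal(pr$endpoint_distance, 0)
})

test_that("path result invariants hold on a quick 13-atom transition", {
  pr <- memo("lj13_path_quick", {
    spec <- free_spec(13)
    qi <- build_lj13_cuboctahedron()
    qf <- lj13_min()$config
    transition_path(qi, qf, spec, time_grid(0, 0.5, 12),
                    weights = loss_weights(1e3, 1e3, 0),
                    config = train_config(epochs = 1500,
                                          learning_rate = 2e-3),
                    n_hidden = 20, model_seed = 2, polish = 1000)
  })
  expect_true(all(pr$quenched_energy <= pr$raw_energy + 1e-9))
  # quenched endpoint energies match the endpoint stationary energies
  expect_equal(pr$quenched_energy[length(pr$times)] * 13,
               lj13_min()$energy, tolerance = 1e-4)
  expect_gte(pr$arc_length,
             pr$endpoint_distance - 1e-9)
})
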