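test_that("FCC lattice construction is correct", {
  ini <- init_fcc_lattice(4, 0.5)
  expect_equal(ini$spec$box, rep(2, 3))
  expect_equal(nrow(ini$config), 4)
  ini <- init_fcc_lattice(256, 0.8)
  expect_equal(nrow(ini$config), 256)
  a <- ini$spec$box[1] / 4
  # nearest-neighbour distance in a perfect FCC lattice is a/sqrt(2)
  dmin <- min(dist(ini$config))
  expect_equal(dmin, a / sqrt(2), tolerance = 1e-10)
  expect_error(init_fcc_lattice(5, 0.8), "4\\*c\\^3")
})

test_that("velocity sampling is thermal, momentum-free and reproducible", {
  ini <- init_fcc_lattice(32, 0.8)
  expect_equal(sample_velocities(ini$spec, 0, seed = 1),
               matrix(0, 32, 3))
  v1 <- sample_velocities(ini$spec, 1, seed = 5)
  expect_lt(max(abs(colSums(v1))), 1e-12)
  expect_identical(v1, sample_velocities(ini$spec, 1, seed = 5))
  # equipartition: mean KE per degree of freedom = 1/2 within sampling error
  spec <- system_spec(500, box = rep(20, 3), lj = lj_params(cutoff = 2.5))
  ke_dof <- vapply(1:10, function(s) {
    v <- sample_velocities(spec, 1, seed = s)
    sum(v^2) / (2 * 3 * 500)
  }, numeric(1))
  expect_equal(mean(ke_dof), 0.5, tolerance = 0.05)
})

test_that("verlet reproduces free flight and the harmonic period", {
  # two atoms beyond the cutoff: free flight, position = t * v
  spec <- system_spec(2, box = rep(20, 3), lj = lj_params(cutoff = 2.5))
  q <- rbind(c(1, 1, 1), c(11, 11, 11))
  v <- rbind(c(0.3, -0.2, 0.1), c(0, 0, 0))
  tr <- run_verlet(q, v, spec, dt = 0.01, n_steps = 100, stride = 100)
  expect_equal(matrix(tr$positions[2, , ], 2, 3), q + 1.0 * v,
               tolerance = 1e-12)
  # harmonic oscillator, k = m = 1: period 2*pi
  hs <- system_spec(1, potential = "harmonic", stiffness = 1)
  x0 <- matrix(c(1, 0, 0), 1, 3)
  n <- round(2 * pi / 0.001)
  tr <- run_verlet(x0, matrix(0, 1, 3), hs, dt = 0.001, n_steps = n,
                   stride = n)
  expect_equal(tr$positions[2, 1, 1], 1, tolerance = 1e-3)
})

test_that("verlet is time reversible", {
  liq <- small_liquid()
  tr <- run_verlet(liq$config, liq$velocities, liq$spec, 0.001, 200,
                   stride = 200)
  qT <- matrix(tr$positions[2, , ], 32, 3)
  vT <- matrix(tr$velocities[2, , ], 32, 3)
  back <- run_verlet(qT, -vT, liq$spec, 0.001, 200, stride = 200)
  expect_lt(max(abs(matrix(back$positions[2, , ], 32, 3) - liq$config)), 1e-8)
})

test_that("verlet shows second-order endpoint convergence on the harmonic oracle", {
  hs <- system_spec(1, potential = "harmonic", stiffness = 1)
  x0 <- matrix(c(1, 0.3, -0.2), 1, 3)
  v0 <- matrix(c(0, 0.5, 0.1), 1, 3)
  endpoint <- function(dt) {
    n <- round(1 / dt)
    tr <- run_verlet(x0, v0, hs, dt, n, stride = n)
    tr$positions[2, 1, ]
  }
  ref <- endpoint(1 / 8000)
  e1 <- sqrt(sum((endpoint(1 / 500) - ref)^2))
  e2 <- sqrt(sum((endpoint(1 / 1000) - ref)^2))
  expect_equal(e1 / e2, 4, tolerance = 0.15)
})

test_that("NVE conserves energy and momentum", {
  liq <- small_liquid()
  tr <- run_verlet(liq$config, liq$velocities, liq$spec, 0.001, 1000,
                   stride = 100)
  es <- energy_series(tr)
  drift <- max(abs(es$total$E - es$total$E[1])) / abs(es$total$E[1])
  expect_lt(drift, 1e-4)
  p <- apply(tr$velocities, 1, function(v) colSums(liq$spec$masses * v))
  expect_lt(max(abs(p - p[, 1])), 1e-10)
})

test_that("equilibrate hits the requested temperature, reproducibly", {
  liq <- small_liquid()
  expect_equal(kinetic_temperature(liq$velocities, liq$spec), 0.75,
               tolerance = 0.1)
  again <- equilibrate(liq$lattice, liq$spec,
                       temperature = 0.75, seed = 11, n_cycles = 5)
  expect_identical(again$config, liq$config)
  expect_identical(again$velocities, liq$velocities)
})

test_that("make_endpoint_pair is self-consistent", {
  ini <- init_fcc_lattice(32, 0.8)
  gen <- make_endpoint_pair(ini$spec, ini$config, window = 0.1, seed = 3,
                            stride = 10,
                            equil_args = list(n_cycles = 2, cycle_time = 0.1))
  nf <- length(gen$trajectory$times)
  expect_identical(gen$pair$qT,
                   matrix(gen$trajectory$positions[nf, , ], 32, 3))
  expect_identical(gen$pair$q0,
                   matrix(gen$trajectory$positions[1, , ], 32, 3))
  expect_equal(gen$pair$e0,
               total_energy(gen$pair$q0, gen$pair$v0, ini$spec))
  gen2 <- make_endpoint_pair(ini$spec, ini$config, window = 0.1, seed = 4,
                             stride = 10,
                             equil_args = list(n_cycles = 2, cycle_time = 0.1))
  expect_gt(max(abs(gen2$pair$qT - gen$pair$qT)), 1e-6)
})
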