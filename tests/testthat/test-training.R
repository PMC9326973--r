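# harmonic boundary-value problem with a closed-form solution, shared below
harmonic_bvp <- function() {
  spec <- system_spec(1, potential = "harmonic", stiffness = 1)
  x0 <- matrix(c(1, 0, 0), 1, 3)
  xT <- matrix(c(0.2, 0.8, -0.5), 1, 3)
  T1 <- 2
  B <- (xT - x0 * cos(T1)) / sin(T1)   # x(t) = x0 cos t + B sin t
  list(spec = spec, x0 = x0, xT = xT, T1 = T1,
       sol = function(t) x0 * cos(t) + B * sin(t),
       ep = endpoint_pair(x0, xT, e0 = 0.5 * sum(B^2) + 0.5 * sum(x0^2),
                          window = T1),
       grid = time_grid(0, T1, 25))
}

test_that("a zero-epoch budget returns the initial model unchanged", {
  bvp <- harmonic_bvp()
  m <- init_model(bvp$spec, 8, seed = 1, t1 = bvp$T1)
  fit <- train(m, bvp$grid, bvp$spec, bvp$ep, loss_weights(1, 1, 1),
               train_config(epochs = 0))
  expect_identical(fit$model$W2, m$W2)
  expect_equal(nrow(fit$history), 1)
})

test_that("training is deterministic and best-so-far is non-increasing", {
  bvp <- harmonic_bvp()
  m <- init_model(bvp$spec, 8, seed = 2, t1 = bvp$T1,
                  baseline = list(q0 = bvp$x0, qT = bvp$xT))
  cfg <- train_config(epochs = 300, learning_rate = 2e-3, log_every = 50)
  f1 <- train(m, bvp$grid, bvp$spec, bvp$ep, loss_weights(10, 10, 1), cfg)
  f2 <- train(m, bvp$grid, bvp$spec, bvp$ep, loss_weights(10, 10, 1), cfg)
  expect_identical(f1$history, f2$history)
  expect_identical(f1$model$W2, f2$model$W2)
  best_total <- cummin(f1$history$total)
  final <- total_loss(f1$model, bvp$grid, bvp$spec, bvp$ep,
                      loss_weights(10, 10, 1))
  expect_lte(final$total, min(f1$history$total) + 1e-12)
  expect_true(all(diff(best_total) <= 0))
})

test_that("trained harmonic path matches the closed-form solution", {
  bvp <- harmonic_bvp()
  m <- init_model(bvp$spec, 20, seed = 1, t1 = bvp$T1,
                  baseline = list(q0 = bvp$x0, qT = bvp$xT))
  fit <- train(m, bvp$grid, bvp$spec, bvp$ep, loss_weights(1e3, 1e3, 10),
               train_config(epochs = 3000, learning_rate = 2e-3),
               polish = 3000)
  pred <- matrix(model_positions(fit$model, bvp$grid$points), 26, 3)
  exact <- t(vapply(bvp$grid$points, function(t) as.vector(bvp$sol(t)),
                    numeric(3)))
  expect_lt(max(abs(pred - exact)), 1e-3)
  # boundary fidelity in the infinity norm
  expect_lt(max(abs(model_positions(fit$model, 0) - bvp$x0)), 1e-3)
  expect_lt(max(abs(model_positions(fit$model, bvp$T1) - bvp$xT)), 1e-3)
})

test_that("training reports divergence with the failing epoch", {
  bvp <- harmonic_bvp()
  m <- init_model(bvp$spec, 8, seed = 3, t1 = bvp$T1)
  m$W2[1, 1] <- NaN
  expect_error(
    train(m, bvp$grid, bvp$spec, bvp$ep, loss_weights(1, 1, 1),
          train_config(epochs = 10, learning_rate = 1e-3)),
    "epoch")
})

test_that("random lambda search stays in range and balances components", {
  bvp <- harmonic_bvp()
  m <- init_model(bvp$spec, 10, seed = 4, t1 = bvp$T1,
                  baseline = list(q0 = bvp$x0, qT = bvp$xT))
  one <- random_search_lambdas(m, bvp$grid, bvp$spec, bvp$ep, budget = 1,
                               seed = 9, short_epochs = 50)
  expect_equal(nrow(one$log), 1)
  expect_equal(one$weights$lambda_bc0, one$log$lambda_bc0[1])

  rs <- random_search_lambdas(m, bvp$grid, bvp$spec, bvp$ep, budget = 6,
                              seed = 9, short_epochs = 400,
                              config = train_config(learning_rate = 2e-3))
  lam <- unlist(rs$weights)
  expect_true(all(lam >= 1e-1 & lam <= 1e5))
  # deterministic given the seed
  rs2 <- random_search_lambdas(m, bvp$grid, bvp$spec, bvp$ep, budget = 6,
                               seed = 9, short_epochs = 400,
                               config = train_config(learning_rate = 2e-3))
  expect_identical(rs$log, rs2$log)
  # rerun short training with the selected lambdas: weighted components
  # within the declared balance ratio of each other
  fit <- train(m, bvp$grid, bvp$spec, bvp$ep, rs$weights,
               train_config(epochs = 400, learning_rate = 2e-3))
  b <- tail(fit$history, 1)
  comp <- c(b$action, rs$weights$lambda_bc0 * b$bc0,
            rs$weights$lambda_bcT * b$bcT, rs$weights$lambda_E * b$energy)
  comp <- comp[comp > 0]
  expect_lt(max(comp) / min(comp), 1e3)
})
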