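#' Training configuration
#'
#' @param epochs Maximum epoch count (full-batch gradient steps).
#' @param learning_rate NADAM step size.
#' @param seed Integer seed recorded with the run.
#' @param tolerance Early-stop threshold: training stops when the relative
#'   improvement of the best total loss over `patience` epochs falls below
#'   this value.
#' @param patience Epoch window for the early-stop check.
#' @param log_every Epoch stride for history rows (the final epoch is always
#'   logged).
#' @return Object of class `train_config`.
#' @export
train_config <- function(epochs = 50000, learning_rate = 1e-3, seed = 1L,
                         tolerance = 1e-10, patience = 500, log_every = 100) {
  stopifnot(epochs >= 0, learning_rate > 0, tolerance >= 0, patience >= 1,
            log_every >= 1)
  structure(list(epochs = as.integer(epochs), learning_rate = learning_rate,
                 seed = as.integer(seed), tolerance = tolerance,
                 patience = as.integer(patience),
                 log_every = as.integer(log_every)),
            class = "train_config")
}

# one NADAM state update; returns list(par, m, v)
.nadam_step <- function(par, grad, state, lr, beta1 = 0.9, beta2 = 0.999,
                        eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- beta1 * state$m + (1 - beta1) * grad
  state$v <- beta2 * state$v + (1 - beta2) * grad^2
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  mhat <- state$m / bc1
  vhat <- state$v / bc2
  step <- lr * (beta1 * mhat + (1 - beta1) * grad / bc1) / (sqrt(vhat) + eps)
  state$par <- par - step
  state
}

#' Train a trajectory model by NADAM minimization of the action loss
#'
#' Full-batch gradient descent (Nesterov-accelerated Adam) on the total loss
#' over the whole time grid each epoch.  Returns the parameters achieving
#' the lowest recorded total loss; the history logs the loss breakdown at
#' `log_every` strides.
#'
#' @param model [init_model()] output (its `t0`/`t1` must match the grid).
#' @param grid [time_grid()].
#' @param spec [system_spec()].
#' @param endpoints [endpoint_pair()].
#' @param weights [loss_weights()].
#' @param config [train_config()].
#' @param quadrature Passed to the loss (see [om_action()]).
#' @param polish Number of quasi-Newton (L-BFGS) iterations run after NADAM
#'   from the best parameters found (default 0 = off).  First-order steps
#'   stall once the loss surface becomes a narrow quadratic valley; a short
#'   quasi-Newton finish reaches the tight optima that the per-frame RMSD
#'   targets require at a fraction of the epoch cost.
#' @return List with `model` (best parameters) and `history` (data frame:
#'   epoch, action, bc0, bcT, energy, total).
#' @export
train <- function(model, grid, spec, endpoints, weights,
                  config = train_config(), quadrature = "riemann",
                  polish = 0) {
  stopifnot(abs(model$t0 - grid$t0) < 1e-12, abs(model$t1 - grid$t1) < 1e-12)
  par <- .par_flatten(model)
  state <- list(par = par, m = numeric(length(par)),
                v = numeric(length(par)), t = 0L)
  hist_rows <- list()
  log_row <- function(epoch, b) {
    hist_rows[[length(hist_rows) + 1L]] <<- data.frame(
      epoch = epoch, action = b$action, bc0 = b$bc0, bcT = b$bcT,
      energy = b$energy, total = b$total)
  }
  ev <- .loss_eval(model, grid, spec, endpoints, weights, want_grad = TRUE,
                   quadrature = quadrature)
  best <- list(par = par, total = ev$breakdown$total)
  last_best <- best$total
  last_finite <- ev$breakdown
  log_row(0L, ev$breakdown)
  epoch <- 0L
  while (epoch < config$epochs) {
    epoch <- epoch + 1L
    state <- .nadam_step(state$par, ev$grad, state, config$learning_rate)
    model <- .par_unflatten(model, state$par)
    ev <- .loss_eval(model, grid, spec, endpoints, weights, want_grad = TRUE,
                     quadrature = quadrature)
    tot <- ev$breakdown$total
    if (!is.finite(tot))
      stop(sprintf(
        "training diverged at epoch %d (non-finite loss; last finite total %.6g)",
        epoch, last_finite$total))
    last_finite <- ev$breakdown
    if (tot < best$total) best <- list(par = state$par, total = tot)
    if (epoch %% config$log_every == 0L) log_row(epoch, ev$breakdown)
    if (epoch %% config$patience == 0L) {
      rel <- (last_best - best$total) / max(abs(last_best), 1e-300)
      if (rel < config$tolerance) break
      last_best <- best$total
    }
  }
  if (epoch %% config$log_every != 0L) log_row(epoch, ev$breakdown)
  if (polish > 0) {
    fn <- function(p) {
      .loss_eval(.par_unflatten(model, p), grid, spec, endpoints, weights,
                 quadrature = quadrature)$breakdown$total
    }
    gr <- function(p) {
      .loss_eval(.par_unflatten(model, p), grid, spec, endpoints, weights,
                 want_grad = TRUE, quadrature = quadrature)$grad
    }
    res <- optim(best$par, fn, gr, method = "L-BFGS-B",
                 control = list(maxit = as.integer(polish), factr = 1e1,
                                pgtol = 0))
    if (is.finite(res$value) && res$value < best$total) {
      best <- list(par = res$par, total = res$value)
      model <- .par_unflatten(model, best$par)
      b <- .loss_eval(model, grid, spec, endpoints, weights,
                      quadrature = quadrature)$breakdown
      log_row(epoch + as.integer(polish), b)
    }
  }
  list(model = .par_unflatten(model, best$par),
       history = do.call(rbind, hist_rows))
}

#' Random search over penalty weights
#'
#' Samples lambda triples log-uniformly from a declared range, short-trains
#' each from the same initial model, and selects the triple minimizing the
#' total loss subject to a balance criterion: after short training no
#' weighted loss component (action, lambda*bc0, lambda*bcT, lambda*energy)
#' may exceed `balance_ratio` times another.  If no trial is balanced the
#' least-imbalanced one is returned.
#'
#' @inheritParams train
#' @param budget Number of trials (>= 1).
#' @param seed Integer seed for the lambda draws.
#' @param range Length-2 vector, the log-uniform sampling range for every
#'   lambda.
#' @param short_epochs Epochs per trial.
#' @param balance_ratio Largest tolerated ratio between weighted components.
#' @param include_energy If `FALSE`, `lambda_E` is fixed at 0 (cluster
#'   barrier-crossing paths).
#' @return List with `weights` (the selected [loss_weights()]) and `log`
#'   (data frame, one row per trial).
#' @export
random_search_lambdas <- function(model, grid, spec, endpoints, budget = 10,
                                  seed = 1L, range = c(1e-1, 1e5),
                                  short_epochs = 500, balance_ratio = 1e3,
                                  include_energy = TRUE,
                                  config = train_config()) {
  stopifnot(budget >= 1, length(range) == 2, all(range > 0))
  lam <- withr_seed(seed, {
    matrix(exp(runif(3 * budget, log(range[1]), log(range[2]))), budget, 3)
  })
  if (!include_energy) lam[, 3] <- 0
  short <- train_config(epochs = short_epochs,
                        learning_rate = config$learning_rate,
                        seed = config$seed, tolerance = 0,
                        patience = short_epochs, log_every = short_epochs)
  rows <- vector("list", budget)
  for (i in seq_len(budget)) {
    w <- loss_weights(lam[i, 1], lam[i, 2], lam[i, 3])
    fit <- train(model, grid, spec, endpoints, w, short)
    b <- tail(fit$history, 1L)
    comp <- c(b$action, w$lambda_bc0 * b$bc0, w$lambda_bcT * b$bcT,
              w$lambda_E * b$energy)
    comp <- comp[c(TRUE, w$lambda_bc0 > 0, w$lambda_bcT > 0, w$lambda_E > 0)]
    ratio <- if (min(comp) <= 0) Inf else max(comp) / min(comp)
    rows[[i]] <- data.frame(trial = i, lambda_bc0 = lam[i, 1],
                            lambda_bcT = lam[i, 2], lambda_E = lam[i, 3],
                            total = b$total, imbalance = ratio,
                            balanced = is.finite(ratio) && ratio <= balance_ratio)
  }
  log <- do.call(rbind, rows)
  ok <- which(log$balanced)
  pick <- if (length(ok)) ok[which.min(log$total[ok])] else
    which.min(log$imbalance)
  list(weights = loss_weights(log$lambda_bc0[pick], log$lambda_bcT[pick],
                              log$lambda_E[pick]),
       log = log)
}
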