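test_that("training windows slice a series into one-step supervised pairs", {
  w <- make_training_windows(rnorm(100), 32)
  expect_equal(dim(w$x), c(68, 32))
  expect_length(w$y, 68)

  ramp <- make_training_windows(0:9, 3)
  expect_equal(ramp$x[1, ], c(0, 1, 2))
  expect_equal(ramp$y[1], 3)
  expect_equal(ramp$x[7, ], c(6, 7, 8))
  expect_equal(ramp$y[7], 9)

  expect_error(make_training_windows(1:10, 10), "lookback")
})

test_that("backpropagation matches a finite-difference gradient oracle", {
  set.seed(77)
  params <- fnirscast:::.init_params(c(5, 4))
  X <- matrix(rnorm(3 * 6), 3, 6)
  y <- rnorm(3)
  loss_fn <- function(p) mean((fnirscast:::.lstm_forward(p, X)[, 1] - y)^2)
  fwd <- fnirscast:::.lstm_forward(params, X, cache = TRUE)
  dy <- matrix(2 * (fwd$y[, 1] - y) / 3, 3, 1)
  grads <- fnirscast:::.lstm_backward(params, fwd, dy)

  assign_in <- function(obj, path, i, v) {
    if (length(path) == 0) {
      obj[i] <- obj[i] + v
      obj
    } else {
      obj[[path[[1]]]] <- assign_in(obj[[path[[1]]]], path[-1], i, v)
      obj
    }
  }
  eps <- 1e-6
  paths <- list(list("Wy"),
                list("layers", 1L, "Wx"), list("layers", 1L, "Wh"),
                list("layers", 1L, "b"),
                list("layers", 2L, "Wx"), list("layers", 2L, "Wh"),
                list("layers", 2L, "b"))
  for (path in paths) {
    g <- grads
    p <- params
    for (k in path) {
      g <- g[[k]]
      p <- p[[k]]
    }
    for (i in sample(length(p), min(4, length(p)))) {
      num <- (loss_fn(assign_in(params, path, i, eps)) -
                loss_fn(assign_in(params, path, i, -eps))) / (2 * eps)
      expect_lt(abs(num - g[i]), 1e-7)
    }
  }
})

test_that("normalization round-trips exactly and guards constant series", {
  x <- rnorm(50, mean = 3, sd = 7)
  np <- fnirscast:::.norm_params(x)
  expect_lt(max(abs(fnirscast:::.denormalize(fnirscast:::.normalize(x, np), np) - x)),
            1e-12)
  npc <- fnirscast:::.norm_params(rep(4, 20))
  expect_equal(npc$scale, 1)  # degenerate constant series: unit scale
})

test_that("a constant series is forecast as that constant", {
  cfg <- forecaster_config(hidden_units = c(6, 4), dropout = 0, max_epochs = 30,
                           minibatch = 16, lookback = 8, steps_per_epoch = 4,
                           seed = 5)
  m <- train_forecaster(rep(2.7, 60), cfg)
  pred <- predict(m, rep(2.7, 20), horizon = 10)
  expect_length(pred, 10)
  expect_lt(max(abs(pred - 2.7)), 1e-3)
})

test_that("training and forecasting are deterministic under a fixed seed", {
  set.seed(123)
  x <- as.numeric(oscillation(300, 8.138, 0.1, 0.01))
  cfg <- tiny_config(seed = 9)
  m1 <- train_forecaster(x, cfg)
  m2 <- train_forecaster(x, cfg)
  expect_identical(m1$params, m2$params)
  expect_identical(predict(m1, x, horizon = 20), predict(m2, x, horizon = 20))
})

test_that("the forecast honours the horizon contract", {
  cfg <- tiny_config(seed = 2)
  m <- train_forecaster(rnorm(100), cfg)
  for (h in c(1L, 7L, 50L)) expect_length(predict(m, rnorm(30), horizon = h), h)
  expect_error(predict(m, rnorm(30), horizon = 0), "horizon")
  expect_error(predict(m, rnorm(5), horizon = 3), "lookback")
  # default horizon is 244 samples = 30 s at 8.138 Hz
  expect_equal(eval(formals(predict.lstm_forecaster)$horizon), 244L)
  expect_equal(round(30 * 8.138), 244)
})

test_that("the training loss decreases and periodic signals are learned", {
  fs <- 8.138
  x <- sin(2 * pi * 0.05 * (0:4882) / fs)
  cfg <- forecaster_config(hidden_units = c(32, 16, 8), dropout = 0.2,
                           max_epochs = 20, minibatch = 128, lookback = 48,
                           steps_per_epoch = 40, seed = 3)
  m <- train_forecaster(x, cfg, wavelet_level = 7L)
  g <- glance(m)
  expect_lt(g$final_loss, g$initial_loss)

  # held-out one-step error, normalized units
  hold <- fnirscast:::.normalize(x, m$norm)
  w <- make_training_windows(hold[4400:4883], cfg$lookback)
  one_step <- fnirscast:::.lstm_forward(m$params, w$x)[, 1]
  expect_lt(mean(abs(one_step - w$y)), 0.05)

  # recursive 244-step forecast tracks the analytic continuation and
  # beats the last-value persistence baseline
  pred <- predict(m, x, horizon = 244)
  truth <- sin(2 * pi * 0.05 * (4883:(4883 + 243)) / fs)
  expect_lt(mae(truth, pred), 0.15)
  expect_lt(mae(truth, pred), mae(truth, rep(x[length(x)], 244)))
})

test_that("non-finite and too-short training input is rejected", {
  cfg <- tiny_config()
  expect_error(train_forecaster(c(rnorm(50), NA, rnorm(50)), cfg), "finite")
  expect_error(train_forecaster(rnorm(10), cfg), "lookback")
})
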