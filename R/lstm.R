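# Stacked LSTM forecaster for wavelet components, implemented directly in
# matrix algebra: gate equations, backpropagation through time, Adam.
#
# Gate layout within the concatenated weight matrices: [input, forget,
# candidate, output].  The cell follows the standard equations
#   i = sigm(W_i x + U_i h + b_i),  f = sigm(W_f x + U_f h + b_f),
#   g = tanh(W_c x + U_c h + b_c),  o = sigm(W_o x + U_o h + b_o),
#   c = f*c_prev + i*g,             h = o * tanh(c),
# with a linear read-out from the last layer's final hidden state.

#' Forecaster configuration
#'
#' Training hyperparameters for the per-wavelet LSTM forecaster.  The
#' defaults mirror the study protocol: three stacked LSTM layers of
#' `[128, 64, 32]` hidden units, dropout 0.2 between layers, Adam with
#' minibatches of 128 and at most 100 epochs.
#'
#' @param hidden_units Integer vector of hidden units per stacked layer.
#' @param dropout Dropout probability applied between recurrent layers
#'   during training only (`0 <= dropout < 1`).
#' @param max_epochs Maximum training epochs.
#' @param minibatch Minibatch size.
#' @param lookback Input window length in samples (default 64, about 7.9 s
#'   at 8.138 Hz -- at least one cycle of the fastest forecast band).
#' @param learning_rate Adam step size.
#' @param steps_per_epoch Number of minibatches per epoch; `NULL` means a
#'   full pass over every training window.  A fixed count turns an epoch
#'   into a stochastic subsample, which is how large pooled corpora are
#'   trained at desk scale.
#' @param seed Integer seed controlling initialization, dropout and batch
#'   order; `NULL` leaves the RNG state alone.
#' @return A list of class `forecaster_config`.
#' @export
forecaster_config <- function(hidden_units = c(128, 64, 32), dropout = 0.2,
                              max_epochs = 100L, minibatch = 128L,
                              lookback = 64L, learning_rate = 1e-3,
                              steps_per_epoch = NULL, seed = NULL) {
  if (any(hidden_units < 1)) rlang::abort("`hidden_units` must all be >= 1.")
  if (dropout < 0 || dropout >= 1) rlang::abort("`dropout` must be in [0, 1).")
  if (lookback < 1) rlang::abort("`lookback` must be >= 1.")
  structure(
    list(hidden_units = as.integer(hidden_units), dropout = dropout,
         max_epochs = as.integer(max_epochs), minibatch = as.integer(minibatch),
         lookback = as.integer(lookback), learning_rate = learning_rate,
         steps_per_epoch = if (is.null(steps_per_epoch)) NULL else as.integer(steps_per_epoch),
         seed = if (is.null(seed)) NULL else as.integer(seed)),
    class = "forecaster_config"
  )
}

#' Build supervised one-step training windows
#'
#' Slices a series into `(length(x) - lookback)` overlapping pairs: each
#' input is `lookback` consecutive samples and the target is the next
#' sample.
#'
#' @param x Numeric series.
#' @param lookback Window length in samples.
#' @return A list with `x` (matrix, one window per row) and `y` (numeric
#'   target vector).
#' @export
make_training_windows <- function(x, lookback) {
  x <- as.numeric(x)
  n <- length(x)
  if (n <= lookback) rlang::abort("Series must be longer than `lookback`.")
  m <- n - lookback
  idx <- outer(seq_len(m) - 1L, seq_len(lookback), `+`)
  list(x = matrix(x[idx], m, lookback), y = x[(lookback + 1):n])
}

.sigmoid <- function(x) 1 / (1 + exp(-x))

# Glorot-uniform initialization of one layer's parameters.
.init_layer <- function(d_in, H) {
  lim_x <- sqrt(6 / (d_in + 4 * H))
  lim_h <- sqrt(6 / (H + 4 * H))
  b <- numeric(4 * H)
  b[(H + 1):(2 * H)] <- 1  # forget-gate bias: remember by default
  list(
    Wx = matrix(stats::runif(d_in * 4 * H, -lim_x, lim_x), d_in, 4 * H),
    Wh = matrix(stats::runif(H * 4 * H, -lim_h, lim_h), H, 4 * H),
    b = b
  )
}

.init_params <- function(hidden, d_in = 1L) {
  layers <- vector("list", length(hidden))
  d <- d_in
  for (l in seq_along(hidden)) {
    layers[[l]] <- .init_layer(d, hidden[l])
    d <- hidden[l]
  }
  H_last <- hidden[length(hidden)]
  lim <- sqrt(6 / (H_last + 1))
  list(layers = layers,
       Wy = matrix(stats::runif(H_last, -lim, lim), H_last, 1),
       by = 0)
}

# Forward pass.  X: B x T matrix of (normalized) inputs.  Returns the
# B x 1 prediction; with cache = TRUE also everything BPTT needs.
# drop_masks: optional list of B x H masks (one per non-final layer).
.lstm_forward <- function(params, X, cache = FALSE, drop_masks = NULL) {
  B <- nrow(X)
  T_len <- ncol(X)
  n_layers <- length(params$layers)
  caches <- if (cache) vector("list", n_layers) else NULL
  inputs <- lapply(seq_len(T_len), function(t) X[, t, drop = FALSE])
  for (l in seq_len(n_layers)) {
    lay <- params$layers[[l]]
    H <- nrow(lay$Wh)
    h <- matrix(0, B, H)
    cc <- matrix(0, B, H)
    bmat <- matrix(lay$b, B, 4 * H, byrow = TRUE)
    st <- if (cache) vector("list", T_len) else NULL
    outs <- vector("list", T_len)
    sig_cols <- c(seq_len(2 * H), (3 * H + 1):(4 * H))
    for (t in seq_len(T_len)) {
      z <- inputs[[t]] %*% lay$Wx + h %*% lay$Wh + bmat
      zs <- .sigmoid(z[, sig_cols, drop = FALSE])
      i_g <- zs[, 1:H, drop = FALSE]
      f_g <- zs[, (H + 1):(2 * H), drop = FALSE]
      o_g <- zs[, (2 * H + 1):(3 * H), drop = FALSE]
      g_g <- tanh(z[, (2 * H + 1):(3 * H), drop = FALSE])
      c_new <- f_g * cc + i_g * g_g
      tc <- tanh(c_new)
      h_new <- o_g * tc
      if (cache) {
        st[[t]] <- list(x = inputs[[t]], i = i_g, f = f_g, g = g_g, o = o_g,
                        c_prev = cc, h_prev = h, tc = tc)
      }
      cc <- c_new
      h <- h_new
      outs[[t]] <- h
    }
    if (!is.null(drop_masks) && l < n_layers) {
      outs <- lapply(outs, function(o) o * drop_masks[[l]])
    }
    if (cache) caches[[l]] <- st
    inputs <- outs
  }
  y <- inputs[[T_len]] %*% params$Wy + params$by
  if (cache) list(y = y, caches = caches, top_h = inputs[[T_len]]) else y
}

# Backward pass (BPTT).  Returns gradients with the same structure as
# params.  fwd is the cached forward result; dy is dLoss/dy (B x 1).
.lstm_backward <- function(params, fwd, dy, drop_masks = NULL) {
  n_layers <- length(params$layers)
  T_len <- length(fwd$caches[[1]])
  B <- nrow(dy)
  grads <- list(layers = vector("list", n_layers),
                Wy = crossprod(fwd$top_h, dy),
                by = sum(dy))
  # gradient flowing into each layer's output sequence
  d_out <- vector("list", T_len)
  for (t in seq_len(T_len)) d_out[[t]] <- matrix(0, B, nrow(params$Wy))
  d_out[[T_len]] <- dy %*% t(params$Wy)
  for (l in rev(seq_len(n_layers))) {
    lay <- params$layers[[l]]
    H <- nrow(lay$Wh)
    st <- fwd$caches[[l]]
    if (!is.null(drop_masks) && l < n_layers) {
      d_out <- lapply(d_out, function(d) d * drop_masks[[l]])
    }
    dWx <- matrix(0, nrow(lay$Wx), 4 * H)
    dWh <- matrix(0, H, 4 * H)
    db <- numeric(4 * H)
    dh_next <- matrix(0, B, H)
    dc_next <- matrix(0, B, H)
    d_in <- vector("list", T_len)
    dz <- matrix(0, B, 4 * H)
    for (t in rev(seq_len(T_len))) {
      s <- st[[t]]
      dh <- d_out[[t]] + dh_next
      dc <- dc_next + dh * s$o * (1 - s$tc^2)
      do_ <- dh * s$tc
      di <- dc * s$g
      df <- dc * s$c_prev
      dg <- dc * s$i
      dz[, 1:H] <- di * s$i * (1 - s$i)
      dz[, (H + 1):(2 * H)] <- df * s$f * (1 - s$f)
      dz[, (2 * H + 1):(3 * H)] <- dg * (1 - s$g^2)
      dz[, (3 * H + 1):(4 * H)] <- do_ * s$o * (1 - s$o)
      dWx <- dWx + crossprod(s$x, dz)
      dWh <- dWh + crossprod(s$h_prev, dz)
      db <- db + colSums(dz)
      d_in[[t]] <- dz %*% t(lay$Wx)
      dh_next <- dz %*% t(lay$Wh)
      dc_next <- dc * s$f
    }
    grads$layers[[l]] <- list(Wx = dWx, Wh = dWh, b = db)
    d_out <- d_in
  }
  grads
}

# Adam update; state holds first/second moments and the step counter.
.adam_init <- function(params) {
  zero_like <- function(p) rapply(p, function(x) x * 0, how = "replace")
  list(m = zero_like(params), v = zero_like(params), t = 0L)
}

.adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                       eps = 1e-8) {
  state$t <- state$t + 1L
  t <- state$t
  upd <- function(p, g, m, v) {
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g^2
    mh <- m / (1 - beta1^t)
    vh <- v / (1 - beta2^t)
    list(p = p - lr * mh / (sqrt(vh) + eps), m = m, v = v)
  }
  walk <- function(p, g, m, v) {
    if (is.list(p)) {
      out_p <- p; out_m <- m; out_v <- v
      for (k in seq_along(p)) {
        r <- walk(p[[k]], g[[k]], m[[k]], v[[k]])
        out_p[[k]] <- r$p; out_m[[k]] <- r$m; out_v[[k]] <- r$v
      }
      list(p = out_p, m = out_m, v = out_v)
    } else {
      upd(p, g, m, v)
    }
  }
  r <- walk(params, grads, state$m, state$v)
  list(params = r$p, state = list(m = r$m, v = r$v, t = t))
}

# Normalization helpers: z-score with a guard for constant series.
.norm_params <- function(x) {
  s <- stats::sd(x)
  list(center = mean(x), scale = if (is.finite(s) && s > 0) s else 1)
}
.normalize <- function(x, np) (x - np$center) / np$scale
.denormalize <- function(x, np) x * np$scale + np$center

#' Train an LSTM forecaster on resting-state series
#'
#' Trains a stacked LSTM on one-step-ahead prediction of a wavelet
#' component.  The input may be a single series or a list of series
#' (e.g. the same wavelet level pooled over many training records); each
#' series is z-scored individually before windowing, so pooled training
#' operates in normalized units.  Loss is mean squared error; optimization
#' is Adam over shuffled minibatches with dropout between the recurrent
#' layers.
#'
#' @param x Numeric series, or a list of numeric series to pool.
#' @param config A [forecaster_config()].
#' @param wavelet_level Optional integer tag recording which wavelet
#'   component the model is bound to.
#' @return An object of class `lstm_forecaster`: `config`, `norm`
#'   (the normalization of the first series; the identity for pooled
#'   pre-normalized input is recoverable per record by the caller),
#'   `wavelet_level`, `params` (trained weights), `loss_history` (mean
#'   training loss per epoch, normalized units).
#' @export
train_forecaster <- function(x, config = forecaster_config(),
                             wavelet_level = NA_integer_) {
  series <- if (is.list(x) && !is.data.frame(x)) lapply(x, as.numeric) else list(as.numeric(x))
  if (any(vapply(series, function(s) any(!is.finite(s)), logical(1)))) {
    rlang::abort("Training series contain non-finite values.")
  }
  lb <- config$lookback
  if (any(vapply(series, length, integer(1)) <= lb)) {
    rlang::abort("Every training series must be longer than `lookback`.")
  }
  old <- .save_rng()
  on.exit(.restore_rng(old))
  if (!is.null(config$seed)) set.seed(config$seed)

  norms <- lapply(series, .norm_params)
  normed <- purrr::map2(series, norms, .normalize)
  # window index: (series id, window start)
  counts <- vapply(normed, length, integer(1)) - lb
  sid <- rep(seq_along(normed), counts)
  start <- unlist(lapply(counts, seq_len), use.names = FALSE)
  N <- length(sid)
  bs <- min(config$minibatch, N)
  steps_full <- ceiling(N / bs)
  steps <- if (is.null(config$steps_per_epoch)) steps_full else min(config$steps_per_epoch, steps_full)

  params <- .init_params(config$hidden_units)
  adam <- .adam_init(params)
  n_layers <- length(config$hidden_units)
  loss_hist <- numeric(config$max_epochs)

  gather <- function(ids) {
    Xb <- matrix(0, length(ids), lb)
    yb <- numeric(length(ids))
    for (k in seq_along(ids)) {
      s <- sid[ids[k]]; st <- start[ids[k]]
      Xb[k, ] <- normed[[s]][st:(st + lb - 1L)]
      yb[k] <- normed[[s]][st + lb]
    }
    list(x = Xb, y = yb)
  }

  for (epoch in seq_len(config$max_epochs)) {
    ord <- if (is.null(config$steps_per_epoch)) sample.int(N) else NULL
    ep_loss <- 0
    for (s in seq_len(steps)) {
      ids <- if (is.null(ord)) sample.int(N, bs) else {
        ord[((s - 1L) * bs + 1L):min(s * bs, N)]
      }
      batch <- gather(ids)
      B <- nrow(batch$x)
      masks <- if (config$dropout > 0) {
        lapply(config$hidden_units[-n_layers], function(H) {
          matrix(stats::rbinom(B * H, 1, 1 - config$dropout), B, H) /
            (1 - config$dropout)
        })
      } else {
        NULL
      }
      fwd <- .lstm_forward(params, batch$x, cache = TRUE, drop_masks = masks)
      err <- fwd$y[, 1] - batch$y
      ep_loss <- ep_loss + mean(err^2)
      dy <- matrix(2 * err / B, B, 1)
      grads <- .lstm_backward(params, fwd, dy, drop_masks = masks)
      upd <- .adam_step(params, grads, adam, config$learning_rate)
      params <- upd$params
      adam <- upd$state
    }
    loss_hist[epoch] <- ep_loss / steps
  }

  structure(
    list(config = config, norm = norms[[1]], wavelet_level = wavelet_level,
         params = params, loss_history = loss_hist, n_windows = N,
         n_series = length(series)),
    class = "lstm_forecaster"
  )
}

#' Forecast ahead of a context window by recursive one-step prediction
#'
#' Normalizes the context with the model's stored normalization, then
#' repeatedly predicts the next sample from the last `lookback` samples,
#' appending each prediction to the context.  Dropout is disabled, so
#' prediction is deterministic.  Output is de-normalized.
#'
#' @param object A trained [train_forecaster()] model.
#' @param context Numeric vector of at least `lookback` recent samples, in
#'   original units.
#' @param horizon Number of samples to predict (default 244, i.e. 30 s at
#'   8.138 Hz).
#' @param norm Normalization override: a `list(center, scale)` to use
#'   instead of the model's own (used when a pooled model is applied to a
#'   record with its own normalization), or `NULL` for the model's.
#' @param ... Unused.
#' @return Numeric vector of length `horizon`, in original units.
#' @export
predict.lstm_forecaster <- function(object, context, horizon = 244L,
                                    norm = NULL, ...) {
  out <- .forecast_batch(object, matrix(as.numeric(context), nrow = 1),
                         horizon, norm = norm)
  out[1, ]
}

# Batched recursive forecast: contexts is B x (>= lookback) in original
# units; returns B x horizon in original units.  norm: NULL (model's own),
# or list(center, scale) with scalar or length-B entries.
.forecast_batch <- function(model, contexts, horizon, norm = NULL) {
  horizon <- as.integer(horizon)
  if (horizon < 1L) rlang::abort("`horizon` must be >= 1.")
  lb <- model$config$lookback
  if (ncol(contexts) < lb) {
    rlang::abort("Context must supply at least `lookback` samples.")
  }
  np <- if (is.null(norm)) model$norm else norm
  B <- nrow(contexts)
  win <- (contexts[, (ncol(contexts) - lb + 1L):ncol(contexts), drop = FALSE] -
            np$center) / np$scale
  preds <- matrix(0, B, horizon)
  for (k in seq_len(horizon)) {
    y <- .lstm_forward(model$params, win)
    preds[, k] <- y[, 1]
    win <- cbind(win[, -1L, drop = FALSE], y)
  }
  preds * np$scale + np$center
}

#' @export
print.lstm_forecaster <- function(x, ...) {
  cat("<lstm_forecaster> layers [",
      paste(x$config$hidden_units, collapse = ", "),
      "], lookback ", x$config$lookback,
      if (!is.na(x$wavelet_level)) paste0(", wavelet ", x$wavelet_level),
      "; trained ", length(x$loss_history), " epochs on ",
      x$n_windows, " windows\n", sep = "")
  invisible(x)
}

#' Glance at a trained forecaster
#'
#' @param x An `lstm_forecaster`.
#' @param ... Unused.
#' @return One-row tibble: `wavelet_level`, `epochs`, `final_loss`,
#'   `initial_loss`, `n_windows`, `n_series`, `n_parameters`.
#' @export
glance.lstm_forecaster <- function(x, ...) {
  n_par <- sum(rapply(x$params, length, how = "unlist"))
  tibble::tibble(
    wavelet_level = x$wavelet_level,
    epochs = length(x$loss_history),
    initial_loss = x$loss_history[1],
    final_loss = x$loss_history[length(x$loss_history)],
    n_windows = x$n_windows, n_series = x$n_series, n_parameters = n_par
  )
}

#' Tidy the training trajectory of a forecaster
#'
#' @param x An `lstm_forecaster`.
#' @param ... Unused.
#' @return Tibble with `epoch` and `loss` (mean training MSE, normalized
#'   units).
#' @export
tidy.lstm_forecaster <- function(x, ...) {
  tibble::tibble(epoch = seq_along(x$loss_history), loss = x$loss_history)
}
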