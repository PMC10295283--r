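# Full method orchestration: decompose resting-state data, train per-
# wavelet LSTM forecasters, predict into the task window, subtract, and
# score -- over the data-segmentation conditions and the with/without-
# response comparison, plus the leave-one-subject-out protocol for
# multi-channel recordings.

#' The six data-segmentation conditions
#'
#' Each condition pairs a decomposition length (how much trailing
#' resting-state data enters the MODWT) with an LSTM training length
#' (how much of the decomposed wavelet is used for training).  Condition 1
#' decomposes 600 s but trains on the final 300 s; conditions 2-6 train on
#' everything they decompose.
#'
#' @return Tibble with columns `id`, `modwt_length_s`, `lstm_train_length_s`.
#' @export
segmentation_conditions <- function() {
  tibble::tibble(
    id = 1:6,
    modwt_length_s = c(600, 600, 300, 150, 90, 60),
    lstm_train_length_s = c(300, 600, 300, 150, 90, 60)
  )
}

.get_condition <- function(condition) {
  tab <- segmentation_conditions()
  if (is.numeric(condition) && length(condition) == 1L) {
    if (!condition %in% tab$id) rlang::abort("`condition` must be an id in 1..6.")
    as.list(tab[tab$id == condition, ])
  } else if (is.list(condition) &&
             all(c("modwt_length_s", "lstm_train_length_s") %in% names(condition))) {
    if (condition$lstm_train_length_s > condition$modwt_length_s) {
      rlang::abort("Training length cannot exceed the decomposition length.")
    }
    condition$id <- condition$id %||% NA_integer_
    condition
  } else {
    rlang::abort("`condition` must be an id (1..6) or a list with modwt/train lengths.")
  }
}

# Decompose a record and return the per-level component series.
# levels are 1..J (details) and J+1 (approximation).
.wavelet_components <- function(x, fs, J = 8L, levels) {
  m <- suppressWarnings(mra(modwt(x, fs = fs, levels = J)))
  stats::setNames(
    lapply(levels, function(l) if (l <= J) m$D[[l]] else m$A),
    as.character(levels)
  )
}

#' Run the synthetic with/without-response experiment
#'
#' For one segmentation condition: decomposes the trailing
#' `modwt_length_s` of each record's resting state at `J = 8`, z-scores
#' each record's wavelet over its training segment, trains one pooled
#' LSTM forecaster per requested wavelet level on the training records,
#' recursively forecasts `horizon` samples into the task window of each
#' test record, and scores the forecasts (MAE/RMSE, normalized units)
#' against the reference: the same wavelet level of the *full-record*
#' decomposition restricted to the horizon.  Per-record errors are split
#' by the presence of a hemodynamic response and compared with a Welch
#' two-sample t-test.
#'
#' @param dataset Tibble from [fnirs_simulate()].
#' @param condition Condition id 1-6 (see [segmentation_conditions()]) or
#'   a list with `modwt_length_s` and `lstm_train_length_s`.
#' @param config A [forecaster_config()].
#' @param split_seed Seed for the train/test split (drawn once,
#'   stratified by response presence).
#' @param levels Wavelet levels to forecast (default 5:9; level 9 is the
#'   approximation `A_8`).
#' @param horizon Forecast length in samples (default 244 = 30 s at
#'   8.138 Hz).
#' @param n_train,n_test Split sizes; default 90%/10% of the dataset.
#' @param modwt_levels Decomposition depth (default 8, fixed across
#'   conditions as in the study protocol).
#' @return An object of class `fnirs_experiment`; see [tidy.fnirs_experiment()],
#'   [windowed_metrics()], [autoplot.fnirs_experiment()].
#' @export
run_synthetic_experiment <- function(dataset, condition, config = forecaster_config(),
                                     split_seed = 1L, levels = 5:9,
                                     horizon = 244L,
                                     n_train = NULL, n_test = NULL,
                                     modwt_levels = 8L) {
  cond <- .get_condition(condition)
  fs <- attr(dataset, "fs") %||% 8.138
  rest_s <- attr(dataset, "rest_duration_s") %||% 600
  rest_n <- round(rest_s * fs)
  n_rec <- nrow(dataset)
  modwt_n <- round(cond$modwt_length_s * fs)
  train_n <- round(cond$lstm_train_length_s * fs)
  if (modwt_n > rest_n) {
    rlang::abort("Condition decomposition length exceeds the record's rest duration.")
  }
  n_total <- nrow(dataset$signal[[1]])
  if (n_total < rest_n + horizon) {
    rlang::abort("Records are shorter than rest + horizon.")
  }
  if (is.null(n_train)) n_train <- floor(0.9 * n_rec)
  if (is.null(n_test)) n_test <- n_rec - n_train
  if (n_train + n_test > n_rec) rlang::abort("Split sizes exceed the dataset.")

  # stratified split drawn once
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(as.integer(split_seed))
  split <- .stratified_split(dataset$has_dhrf, n_train, n_test)

  lev_names <- as.character(levels)
  # per record: training series, forecast context, normalized reference
  prep <- purrr::map(seq_len(n_rec), function(i) {
    if (!(i %in% split$train || i %in% split$test)) return(NULL)
    x <- dataset$signal[[i]]$combined
    rest_seg <- x[(rest_n - modwt_n + 1):rest_n]
    rest_comp <- .wavelet_components(rest_seg, fs, modwt_levels, levels)
    full_comp <- .wavelet_components(x, fs, modwt_levels, levels)
    lapply(lev_names, function(l) {
      w <- rest_comp[[l]]
      train_series <- w[(length(w) - train_n + 1):length(w)]
      np <- .norm_params(train_series)
      list(
        train = .normalize(train_series, np),
        context = .normalize(w, np),
        reference = .normalize(full_comp[[l]][(rest_n + 1):(rest_n + horizon)], np),
        norm = np
      )
    }) |> stats::setNames(lev_names)
  })

  models <- list()
  traces <- list()
  for (l in lev_names) {
    pool <- lapply(split$train, function(i) prep[[i]][[l]]$train)
    # series are pre-normalized per record; the model trains in pooled
    # normalized units (its own norm on such input is ~identity)
    model <- train_forecaster(pool, config, wavelet_level = as.integer(l))
    models[[l]] <- model
    contexts <- do.call(rbind, lapply(split$test, function(i) {
      ctx <- prep[[i]][[l]]$context
      ctx[(length(ctx) - config$lookback + 1):length(ctx)]
    }))
    preds <- .forecast_batch(model, contexts, horizon,
                             norm = list(center = 0, scale = 1))
    traces[[l]] <- tibble::tibble(
      record_id = dataset$record_id[split$test],
      wavelet_level = as.integer(l),
      has_dhrf = dataset$has_dhrf[split$test],
      predicted = lapply(seq_along(split$test), function(k) preds[k, ]),
      reference = lapply(split$test, function(i) prep[[i]][[l]]$reference),
      norm = lapply(split$test, function(i) prep[[i]][[l]]$norm)
    )
  }
  traces <- dplyr::bind_rows(traces)
  errors <- traces |>
    dplyr::mutate(
      mae = purrr::map2_dbl(.data$reference, .data$predicted, mae),
      rmse = purrr::map2_dbl(.data$reference, .data$predicted, rmse)
    ) |>
    dplyr::select("record_id", "wavelet_level", "has_dhrf", "mae", "rmse")

  structure(
    list(
      metrics = .summarize_errors(errors, cond$id),
      comparisons = .compare_by_level(errors),
      errors = errors, traces = traces, models = models,
      condition = cond, config = config, fs = fs, horizon = horizon,
      split = split, levels = as.integer(levels)
    ),
    class = "fnirs_experiment"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.stratified_split <- function(strata, n_train, n_test) {
  n <- length(strata)
  prop <- n_train / (n_train + n_test)
  train <- integer(0); test <- integer(0)
  for (g in unique(strata)) {
    ids <- sample(which(strata == g))
    k <- round(prop * length(ids) * (n_train + n_test) / n)
    k <- min(k, length(ids))
    train <- c(train, ids[seq_len(k)])
    test <- c(test, ids[setdiff(seq_along(ids), seq_len(k))])
  }
  # trim to the exact requested sizes
  list(train = sort(train[seq_len(min(n_train, length(train)))]),
       test = sort(test[seq_len(min(n_test, length(test)))]))
}

.summarize_errors <- function(errors, condition_id) {
  errors |>
    dplyr::mutate(group = ifelse(.data$has_dhrf, "with_dhrf", "without_dhrf")) |>
    dplyr::group_by(.data$wavelet_level, .data$group) |>
    dplyr::summarise(
      n = dplyr::n(),
      mae_mean = mean(.data$mae), mae_std = stats::sd(.data$mae),
      rmse_mean = mean(.data$rmse), rmse_std = stats::sd(.data$rmse),
      .groups = "drop"
    ) |>
    dplyr::mutate(condition_id = condition_id, .before = 1)
}

.compare_by_level <- function(errors) {
  errors |>
    dplyr::group_by(.data$wavelet_level) |>
    dplyr::group_modify(function(d, key) {
      a <- d$mae[d$has_dhrf]; b <- d$mae[!d$has_dhrf]
      if (length(a) < 2 || length(b) < 2) {
        return(tibble::tibble(p_value_mae = NA_real_, p_value_rmse = NA_real_,
                              significance_mae = NA_character_,
                              significance_rmse = NA_character_))
      }
      cm <- compare_groups(a, b)
      cr <- compare_groups(d$rmse[d$has_dhrf], d$rmse[!d$has_dhrf])
      tibble::tibble(p_value_mae = cm$p_value, p_value_rmse = cr$p_value,
                     significance_mae = cm$significance,
                     significance_rmse = cr$significance)
    }) |>
    dplyr::ungroup()
}

#' Windowed error metrics of an experiment
#'
#' Rescores the stored forecast/reference traces cumulatively from the
#' task onset over several window lengths, yielding the early-detection
#' profile of the prediction error.
#'
#' @param x An `fnirs_experiment`.
#' @param windows_s Window lengths in seconds.
#' @return Tibble: `wavelet_level`, `window_s`, `group`, `n`, `mae_mean`,
#'   `mae_std`, `rmse_mean`, `rmse_std`, plus Welch `p_value_mae` /
#'   `p_value_rmse` per (level, window).
#' @export
windowed_metrics <- function(x, windows_s = c(1, 3, 5, 10, 15, 30)) {
  stopifnot(inherits(x, "fnirs_experiment"))
  per <- x$traces |>
    dplyr::mutate(win = purrr::map2(.data$reference, .data$predicted,
                                    windowed_errors, fs = x$fs,
                                    windows_s = windows_s)) |>
    dplyr::select("record_id", "wavelet_level", "has_dhrf", "win") |>
    tidyr::unnest("win")
  sums <- per |>
    dplyr::mutate(group = ifelse(.data$has_dhrf, "with_dhrf", "without_dhrf")) |>
    dplyr::group_by(.data$wavelet_level, .data$window_s, .data$group) |>
    dplyr::summarise(
      n = dplyr::n(),
      mae_mean = mean(.data$mae), mae_std = stats::sd(.data$mae),
      rmse_mean = mean(.data$rmse), rmse_std = stats::sd(.data$rmse),
      .groups = "drop"
    )
  comps <- per |>
    dplyr::group_by(.data$wavelet_level, .data$window_s) |>
    dplyr::group_modify(function(d, key) {
      a <- d$mae[d$has_dhrf]; b <- d$mae[!d$has_dhrf]
      if (length(a) < 2 || length(b) < 2) {
        return(tibble::tibble(p_value_mae = NA_real_, p_value_rmse = NA_real_))
      }
      tibble::tibble(
        p_value_mae = compare_groups(a, b)$p_value,
        p_value_rmse = compare_groups(d$rmse[d$has_dhrf], d$rmse[!d$has_dhrf])$p_value
      )
    }) |>
    dplyr::ungroup()
  dplyr::left_join(sums, comps, by = c("wavelet_level", "window_s"))
}

#' Subtract predicted physiological noise from a task segment
#'
#' Decomposes the resting-state part of a record, forecasts the selected
#' wavelet components across the task window with the supplied per-level
#' models, and returns the task-window signal minus the summed
#' predictions.  What remains is the part of the task window the
#' resting-state dynamics do not explain -- the putative task-evoked
#' response plus unpredicted high-frequency noise.
#'
#' @param record Numeric vector (or data frame, see [modwt()]): the full
#'   recording, rest followed by task.
#' @param rest_end_index Index of the last resting-state sample.
#' @param models Named list of trained forecasters, names `"5"` ... `"9"`
#'   (or any subset of levels used at decomposition depth 8).
#' @param levels Wavelet levels to subtract (default 5:9); every requested
#'   level must have a model.
#' @param horizon Number of task samples to denoise (default 244).
#' @param fs Sampling rate in Hz.
#' @param modwt_length_s Length of trailing rest to decompose (default:
#'   all of it).
#' @param modwt_levels Decomposition depth (default 8).
#' @return Tibble with columns `time_s` (0 at task onset), `observed`,
#'   `predicted_noise`, `denoised`.
#' @export
denoise_task_segment <- function(record, rest_end_index, models,
                                 levels = 5:9, horizon = 244L, fs = 8.138,
                                 modwt_length_s = NULL, modwt_levels = 8L) {
  sig <- as_signal(record, fs = fs)
  x <- sig$samples
  if (length(x) < rest_end_index + horizon) {
    rlang::abort("Record must extend at least `horizon` past `rest_end_index`.")
  }
  missing <- setdiff(as.character(levels), names(models))
  if (length(missing) > 0) {
    rlang::abort(paste0("No model supplied for wavelet level(s) ",
                        paste(missing, collapse = ", "), "."))
  }
  modwt_n <- if (is.null(modwt_length_s)) rest_end_index else round(modwt_length_s * fs)
  rest_seg <- x[(rest_end_index - modwt_n + 1):rest_end_index]
  comps <- .wavelet_components(rest_seg, fs, modwt_levels, levels)
  pred_noise <- numeric(horizon)
  for (l in as.character(levels)) {
    w <- comps[[l]]
    np <- .norm_params(w)
    model <- models[[l]]
    ctx <- matrix(w[(length(w) - model$config$lookback + 1):length(w)], 1)
    pred <- .forecast_batch(model, ctx, horizon, norm = np)
    pred_noise <- pred_noise + pred[1, ]
  }
  observed <- x[(rest_end_index + 1):(rest_end_index + horizon)]
  tibble::tibble(
    time_s = (seq_len(horizon) - 1) / fs,
    observed = observed,
    predicted_noise = pred_noise,
    denoised = observed - pred_noise
  )
}

#' Leave-one-subject-out evaluation on multi-channel recordings
#'
#' For each subject in turn: trains one pooled forecaster per wavelet
#' level on all channels of the remaining subjects (their trailing
#' `train_length_s` of decomposed data), then forecasts `horizon_s` ahead
#' on each held-out channel and scores MAE/RMSE cumulatively over the
#' requested windows against the full-record decomposition.  Aggregated
#' over channels and folds this is the real-data validation table shape.
#'
#' @param channels Tibble with columns `subject`, `channel` and `signal`
#'   (list-column of numeric vectors, all the same length).
#' @param config A [forecaster_config()].
#' @param fs Sampling rate in Hz.
#' @param levels Wavelet levels (default 5:9 at depth 8).
#' @param train_length_s Training length in seconds (protocol: 570 of a
#'   600-s recording).
#' @param horizon_s Forecast length in seconds (protocol: 30).
#' @param windows_s Scoring windows in seconds.
#' @param modwt_levels Decomposition depth (default 8).
#' @return Tibble: `wavelet_level`, `window_s`, `n`, `mae_mean`,
#'   `mae_std`, `rmse_mean`, `rmse_std`.
#' @export
run_leave_one_out <- function(channels, config = forecaster_config(),
                              fs = 8.138, levels = 5:9,
                              train_length_s = 570, horizon_s = 30,
                              windows_s = c(1, 3, 5, 10, 15, 30),
                              modwt_levels = 8L) {
  subjects <- unique(channels$subject)
  if (length(subjects) < 2) rlang::abort("Leave-one-out needs at least 2 subjects.")
  train_n <- round(train_length_s * fs)
  horizon <- round(horizon_s * fs)
  lev_names <- as.character(levels)

  prep <- purrr::map(channels$signal, function(x) {
    x <- as.numeric(x)
    if (length(x) < train_n + horizon) {
      rlang::abort("Channels must be at least train_length_s + horizon_s long.")
    }
    train_seg <- x[1:train_n]
    rest_comp <- .wavelet_components(train_seg, fs, modwt_levels, levels)
    full_comp <- .wavelet_components(x[1:(train_n + horizon)], fs, modwt_levels, levels)
    lapply(lev_names, function(l) {
      np <- .norm_params(rest_comp[[l]])
      list(train = .normalize(rest_comp[[l]], np),
           reference = .normalize(full_comp[[l]][(train_n + 1):(train_n + horizon)], np))
    }) |> stats::setNames(lev_names)
  })

  res <- purrr::map_dfr(subjects, function(held) {
    test_idx <- which(channels$subject == held)
    train_idx <- which(channels$subject != held)
    purrr::map_dfr(lev_names, function(l) {
      pool <- lapply(train_idx, function(i) prep[[i]][[l]]$train)
      model <- train_forecaster(pool, config, wavelet_level = as.integer(l))
      contexts <- do.call(rbind, lapply(test_idx, function(i) {
        tr <- prep[[i]][[l]]$train
        tr[(length(tr) - config$lookback + 1):length(tr)]
      }))
      preds <- .forecast_batch(model, contexts, horizon,
                               norm = list(center = 0, scale = 1))
      purrr::map_dfr(seq_along(test_idx), function(k) {
        we <- windowed_errors(prep[[test_idx[k]]][[l]]$reference, preds[k, ],
                              fs = fs, windows_s = windows_s)
        we$subject <- held
        we$channel <- channels$channel[test_idx[k]]
        we$wavelet_level <- as.integer(l)
        we
      })
    })
  })
  res |>
    dplyr::group_by(.data$wavelet_level, .data$window_s) |>
    dplyr::summarise(
      n = dplyr::n(),
      mae_mean = mean(.data$mae), mae_std = stats::sd(.data$mae),
      rmse_mean = mean(.data$rmse), rmse_std = stats::sd(.data$rmse),
      .groups = "drop"
    )
}

# ---- experiment methods --------------------------------------------------

#' @export
print.fnirs_experiment <- function(x, ...) {
  cat("<fnirs_experiment> condition ", x$condition$id %||% NA,
      " (MODWT ", x$condition$modwt_length_s, " s / LSTM ",
      x$condition$lstm_train_length_s, " s), levels ",
      paste(x$levels, collapse = ","), ", ",
      length(x$split$train), " train / ", length(x$split$test),
      " test records\n", sep = "")
  print(tidy(x))
  invisible(x)
}

#' Tidy an experiment into the per-wavelet metrics table
#'
#' @param x An `fnirs_experiment`.
#' @param ... Unused.
#' @return Tibble joining per-group error summaries with the Welch
#'   group-comparison p-values per wavelet level.
#' @export
tidy.fnirs_experiment <- function(x, ...) {
  dplyr::left_join(x$metrics, x$comparisons, by = "wavelet_level")
}

#' Glance at an experiment
#'
#' @param x An `fnirs_experiment`.
#' @param ... Unused.
#' @export
glance.fnirs_experiment <- function(x, ...) {
  tibble::tibble(
    condition_id = x$condition$id %||% NA_integer_,
    modwt_length_s = x$condition$modwt_length_s,
    lstm_train_length_s = x$condition$lstm_train_length_s,
    n_train = length(x$split$train), n_test = length(x$split$test),
    horizon = x$horizon, levels = paste(x$levels, collapse = ",")
  )
}

#' Plot per-wavelet forecast errors by group
#'
#' @param object An `fnirs_experiment`.
#' @param metric `"mae"` or `"rmse"`.
#' @param ... Unused.
#' @return A ggplot object: grouped bars with standard-deviation error
#'   bars, one bar pair per wavelet level.
#' @export
autoplot.fnirs_experiment <- function(object, metric = c("mae", "rmse"), ...) {
  metric <- match.arg(metric)
  m <- object$metrics
  m$mean <- m[[paste0(metric, "_mean")]]
  m$std <- m[[paste0(metric, "_std")]]
  ggplot2::ggplot(m, ggplot2::aes(x = factor(.data$wavelet_level),
                                  y = .data$mean, fill = .data$group)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(0.8), width = 0.7) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = pmax(0, .data$mean - .data$std),
                   ymax = .data$mean + .data$std),
      position = ggplot2::position_dodge(0.8), width = 0.2
    ) +
    ggplot2::labs(x = "wavelet level", y = toupper(metric), fill = NULL)
}
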