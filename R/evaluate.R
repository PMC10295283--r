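# Forecast error metrics and group comparison statistics.

.check_pair <- function(y, y_hat) {
  if (length(y) != length(y_hat)) {
    rlang::abort("`y` and `y_hat` must have equal length.")
  }
  if (length(y) < 1L) rlang::abort("Need at least one sample.")
}

#' Mean absolute error
#'
#' @param y Reference (original) signal.
#' @param y_hat Predicted signal, same length.
#' @return `mean(|y - y_hat|)`.
#' @export
mae <- function(y, y_hat) {
  .check_pair(y, y_hat)
  mean(abs(y - y_hat))
}

#' Root mean squared error
#'
#' Always `>=` [mae()] for the same pair (Jensen's inequality, with
#' equality only when all absolute errors are equal).
#'
#' @inheritParams mae
#' @return `sqrt(mean((y - y_hat)^2))`.
#' @export
rmse <- function(y, y_hat) {
  .check_pair(y, y_hat)
  sqrt(mean((y - y_hat)^2))
}

#' Compare error distributions of two groups
#'
#' Welch two-sample t-test between per-record error values of two
#' conditions (e.g. records with vs without a hemodynamic response).
#' Welch's unequal-variance form is used because the two groups typically
#' have visibly different spreads.  Identical zero-variance groups are
#' degenerate; by convention they return `p = 1` with a flag.
#'
#' @param values_a,values_b Numeric vectors of per-record errors (each of
#'   length >= 2).
#' @return A one-row tibble: `statistic`, `df`, `p_value`, `mean_a`,
#'   `mean_b`, `significance` (`""`, `"*"` for p < 0.05, `"**"` for
#'   p < 0.01), `degenerate`.
#' @export
compare_groups <- function(values_a, values_b) {
  if (length(values_a) < 2L || length(values_b) < 2L) {
    rlang::abort("Each group needs at least 2 values.")
  }
  degenerate <- stats::sd(values_a) == 0 && stats::sd(values_b) == 0
  if (degenerate) {
    stat <- 0
    df <- NA_real_
    p <- 1
  } else {
    tt <- stats::t.test(values_a, values_b, var.equal = FALSE)
    stat <- unname(tt$statistic)
    df <- unname(tt$parameter)
    p <- tt$p.value
  }
  tibble::tibble(
    statistic = stat, df = df, p_value = p,
    mean_a = mean(values_a), mean_b = mean(values_b),
    significance = .sig_label(p), degenerate = degenerate
  )
}

.sig_label <- function(p) {
  dplyr::case_when(p < 0.01 ~ "**", p < 0.05 ~ "*", TRUE ~ "")
}

#' Cumulative windowed forecast errors
#'
#' Computes MAE and RMSE over the first `round(w * fs)` samples of the
#' forecast horizon for each window length `w` -- i.e. cumulatively from
#' the task onset, which is how early detectability of a slowly rising
#' hemodynamic response is assessed.
#'
#' @inheritParams mae
#' @param fs Sampling rate in Hz.
#' @param windows_s Window lengths in seconds (default
#'   `c(1, 3, 5, 10, 15, 30)`).
#' @return A tibble with columns `window_s`, `n`, `mae`, `rmse`.
#' @export
windowed_errors <- function(y, y_hat, fs, windows_s = c(1, 3, 5, 10, 15, 30)) {
  .check_pair(y, y_hat)
  purrr::map_dfr(windows_s, function(w) {
    k <- round(w * fs)
    if (k > length(y)) {
      rlang::abort(paste0("Window ", w, " s exceeds the horizon length."))
    }
    k <- max(1L, k)
    tibble::tibble(window_s = w, n = k,
                   mae = mae(y[seq_len(k)], y_hat[seq_len(k)]),
                   rmse = rmse(y[seq_len(k)], y_hat[seq_len(k)]))
  })
}
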