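# Maximal overlap discrete wavelet transform (MODWT): filter bank,
# pyramid transform, multiresolution analysis, level selection.
#
# Conventions: scaling (low-pass) filters g are stored in the standard
# quadrature-mirror order with sum(g) = sqrt(2); the wavelet (high-pass)
# filter is h[l] = (-1)^l * g[L-1-l] (l = 0..L-1).  MODWT filters are the
# DWT filters rescaled by 2^(-j/2); boundaries are circular ("mod n").

# Standard orthogonal scaling filter coefficients (Daubechies & Symlet
# families; published values, 16 significant digits).
.scaling_filters <- list(
  haar = c(0.7071067811865476, 0.7071067811865476),
  db2 = c(0.4829629131445342, 0.8365163037378079,
          0.2241438680420134, -0.1294095225512604),
  sym4 = c(0.03222310060404270, -0.01260396726203783,
           -0.09921954357684722, 0.29785779560527736,
           0.80373875180591614, 0.49761866763201545,
           -0.02963552764599851, -0.07576571478927333)
)

#' Construct a MODWT filter bank
#'
#' Builds the per-level MODWT wavelet (high-pass) and scaling (low-pass)
#' filters for an orthogonal mother wavelet.  The level-1 filters are the
#' base DWT pair divided by `sqrt(2)`; the level-`j` equivalent filter is
#' obtained by the standard cascade (the level-1 filter upsampled with
#' `2^(j-1) - 1` interleaved zeros, convolved with the level-`(j-1)`
#' equivalent low-pass filter), which carries the overall `2^(-j/2)`
#' rescaling.
#'
#' `sym4` (Symlet with 4 vanishing moments, 8 taps) is the default mother
#' wavelet: its shape resembles the canonical hemodynamic response, which
#' makes the detail components physiologically interpretable for fNIRS.
#'
#' @param wavelet Name of the mother wavelet: one of
#'   `r paste0('"', names(.scaling_filters), '"', collapse = ", ")`.
#' @param levels Number of decomposition levels `J >= 1`.
#' @return An object of class `modwt_filter_bank`: a list with elements
#'   `wavelet`, `levels`, `high_pass` and `low_pass` (each a list of `J`
#'   numeric vectors, the equivalent level-`j` MODWT filters).
#' @examples
#' bank <- modwt_filter_bank("sym4", 3)
#' sum(bank$high_pass[[1]])  # ~0
#' sum(bank$low_pass[[1]])   # ~1
#' @export
modwt_filter_bank <- function(wavelet = "sym4", levels = 1L) {
  if (!is.character(wavelet) || length(wavelet) != 1L ||
      !wavelet %in% names(.scaling_filters)) {
    rlang::abort(paste0(
      "Unknown wavelet '", as.character(wavelet)[1], "'. Available: ",
      paste(names(.scaling_filters), collapse = ", "), "."
    ))
  }
  levels <- as.integer(levels)
  if (is.na(levels) || levels < 1L) {
    rlang::abort("`levels` must be an integer >= 1.")
  }
  g <- .scaling_filters[[wavelet]]
  L <- length(g)
  h <- (-1)^(seq_len(L) - 1) * rev(g)
  # MODWT level-1 filters
  g1 <- g / sqrt(2)
  h1 <- h / sqrt(2)
  low <- vector("list", levels)
  high <- vector("list", levels)
  low[[1]] <- g1
  high[[1]] <- h1
  if (levels > 1L) {
    for (j in 2:levels) {
      up <- .upsample(cbind(g1, h1), 2^(j - 1))
      low[[j]] <- stats::convolve(up[, 1], rev(low[[j - 1]]), type = "open")
      high[[j]] <- stats::convolve(up[, 2], rev(low[[j - 1]]), type = "open")
    }
  }
  structure(
    list(wavelet = wavelet, levels = levels, high_pass = high, low_pass = low),
    class = "modwt_filter_bank"
  )
}

# insert (factor - 1) zeros between taps of each column
.upsample <- function(f, factor) {
  n <- nrow(f)
  out <- matrix(0, (n - 1) * factor + 1, ncol(f))
  out[seq(1, nrow(out), by = factor), ] <- f
  out
}

#' Select the MODWT decomposition level for a signal length
#'
#' Returns the largest integer strictly less than `log2(n)`, the deepest
#' level at which every equivalent filter still fits the data more than
#' once.  For a 60-s resting-state segment at 8.138 Hz (488 samples) this
#' gives 8, the depth used throughout the synthetic experiments.
#'
#' @param n Signal length in samples (`n >= 2`).
#' @return Integer decomposition level.
#' @examples
#' select_level(488)  # 8
#' select_level(256)  # 7: log2 is exactly 8, so one less
#' @export
select_level <- function(n) {
  n <- as.numeric(n)
  if (length(n) != 1L || !is.finite(n) || n < 2) {
    rlang::abort("`n` must be a single integer >= 2.")
  }
  j <- floor(log2(n))
  # guard against log2 rounding at exact powers of two
  while (2^j >= n) j <- j - 1
  as.integer(j)
}

# Coerce user input (numeric vector or data frame with time/value columns)
# to an internal signal: list(samples, fs, label).
as_signal <- function(x, fs = NULL, label = "") {
  if (is.data.frame(x)) {
    val_col <- intersect(c("value", "combined", "signal"), names(x))
    if (length(val_col) == 0) {
      num <- names(x)[vapply(x, is.numeric, logical(1))]
      num <- setdiff(num, c("time", "time_s"))
      if (length(num) == 0) rlang::abort("No numeric signal column found.")
      val_col <- num[1]
    } else {
      val_col <- val_col[1]
    }
    samples <- x[[val_col]]
    t_col <- intersect(c("time_s", "time"), names(x))
    if (is.null(fs) && length(t_col) > 0) {
      tt <- x[[t_col[1]]]
      dt <- diff(tt)
      if (length(dt) == 0 || any(!is.finite(dt))) {
        rlang::abort("Cannot derive a sampling rate from the time column.")
      }
      if (max(dt) - min(dt) > 1e-3 * stats::median(dt)) {
        rlang::abort("Time stamps are not uniformly spaced; supply `fs` explicitly.")
      }
      fs <- 1 / stats::median(dt)
    }
  } else {
    samples <- as.numeric(x)
  }
  if (is.null(fs)) {
    rlang::abort("Sampling rate `fs` is required when the input carries no time column.")
  }
  if (fs <= 0) rlang::abort("`fs` must be > 0.")
  if (length(samples) < 2) rlang::abort("Signal must have at least 2 samples.")
  if (any(!is.finite(samples))) rlang::abort("Signal contains non-finite values.")
  list(samples = samples, fs = as.numeric(fs), label = label)
}

# One pyramid filtering step: y[t] = sum_l f[l+1] * x[(t - stride*l) mod n]
.circular_filter <- function(x, f, stride) {
  n <- length(x)
  t0 <- seq_len(n) - 1L
  y <- numeric(n)
  for (l in seq_along(f) - 1L) {
    y <- y + f[l + 1L] * x[((t0 - stride * l) %% n) + 1L]
  }
  y
}

#' Maximal overlap discrete wavelet transform
#'
#' Decomposes a uniformly sampled signal into `J` wavelet coefficient
#' vectors `W_1 ... W_J` and one scaling vector `V_J`, each of the same
#' length as the input (the MODWT is non-decimated and defined for
#' arbitrary signal lengths).  Boundaries are treated circularly, and the
#' transform conserves energy: `||x||^2 = sum_j ||W_j||^2 + ||V_J||^2`.
#'
#' The fast pyramid algorithm is used; its output is identical to direct
#' circular convolution of the signal with the periodized equivalent
#' level-`j` filters.
#'
#' @param x A numeric vector, or a data frame with a time column
#'   (`time`/`time_s`) and a signal column (`value`/`combined`, or the
#'   first numeric non-time column).
#' @param wavelet Mother wavelet name (see [modwt_filter_bank()]).
#' @param levels Decomposition level `J`; defaults to [select_level()] of
#'   the signal length.  Levels beyond `select_level(n)` are allowed with
#'   a warning (the analysis pipeline fixes `J = 8` even for short
#'   segments).
#' @param fs Sampling rate in Hz; required for numeric input, otherwise
#'   derived from the time column.
#' @param bank Optionally, a prebuilt [modwt_filter_bank()] (overrides
#'   `wavelet`/`levels`).
#' @return An object of class `modwt`: list with `W` (list of `J` numeric
#'   vectors), `V` (numeric vector), `bank`, `fs`, `n`, and the original
#'   `samples`.
#' @examples
#' x <- sin(2 * pi * 0.025 * (0:487) / 8.138)
#' w <- modwt(x, fs = 8.138, levels = 8)
#' sapply(w$W, function(v) sum(v^2)) / sum(x^2)
#' @export
modwt <- function(x, wavelet = "sym4", levels = NULL, fs = NULL, bank = NULL) {
  sig <- as_signal(x, fs = fs)
  n <- length(sig$samples)
  if (is.null(bank)) {
    if (is.null(levels)) levels <- select_level(n)
    bank <- modwt_filter_bank(wavelet, levels)
  }
  J <- bank$levels
  if (J > select_level(n)) {
    rlang::warn(paste0(
      "Decomposition level ", J, " exceeds select_level(n) = ",
      select_level(n), " for n = ", n, "; proceeding anyway."
    ))
  }
  g1 <- bank$low_pass[[1]]
  h1 <- bank$high_pass[[1]]
  W <- vector("list", J)
  v <- sig$samples
  for (j in seq_len(J)) {
    stride <- 2^(j - 1)
    W[[j]] <- .circular_filter(v, h1, stride)
    v <- .circular_filter(v, g1, stride)
  }
  structure(
    list(W = W, V = v, bank = bank, fs = sig$fs, n = n, samples = sig$samples),
    class = "modwt"
  )
}

# Periodize a filter to length n: fold taps beyond n back (circularly).
.periodize <- function(f, n) {
  if (length(f) <= n) {
    out <- c(f, numeric(n - length(f)))
  } else {
    out <- numeric(n)
    idx <- ((seq_along(f) - 1L) %% n) + 1L
    for (k in seq_along(f)) out[idx[k]] <- out[idx[k]] + f[k]
  }
  out
}

# Circular cross-correlation y[t] = sum_l f[l+1] * x[(t + l) mod n], via FFT.
.circular_correlate <- function(x, f) {
  n <- length(x)
  fp <- .periodize(f, n)
  Re(stats::fft(stats::fft(x) * Conj(stats::fft(fp)), inverse = TRUE)) / n
}

#' Multiresolution analysis from MODWT coefficients
#'
#' Projects each coefficient vector back to the signal domain, yielding
#' additive detail components `D_1 ... D_J` and the approximation `A_J`
#' with `x = sum_j D_j + A_J` (to floating-point accuracy).  Each `D_j`
#' carries the content of the dyadic band `[fs/2^(j+1), fs/2^j]`; `A_J`
#' carries everything below `fs/2^(J+1)`.
#'
#' In the fNIRS pipeline with `J = 8` the nine components are referred to
#' as wavelets 1-9, wavelet 9 being the approximation `A_8`.
#'
#' @param x A `modwt` object.
#' @return An object of class `modwt_mra`: list with `D` (list of `J`
#'   numeric vectors), `A` (numeric vector), `fs`, `n`, `bank` and
#'   `samples` (the reconstructed original).
#' @examples
#' w <- modwt(rnorm(100), fs = 8.138, levels = 4)
#' m <- mra(w)
#' max(abs(Reduce(`+`, m$D) + m$A - w$samples))  # ~1e-15
#' @export
mra <- function(x) {
  if (!inherits(x, "modwt")) rlang::abort("`x` must be a `modwt` object.")
  J <- x$bank$levels
  D <- vector("list", J)
  for (j in seq_len(J)) {
    D[[j]] <- .circular_correlate(x$W[[j]], x$bank$high_pass[[j]])
  }
  A <- .circular_correlate(x$V, x$bank$low_pass[[J]])
  structure(
    list(D = D, A = A, fs = x$fs, n = x$n, bank = x$bank, samples = x$samples),
    class = "modwt_mra"
  )
}

#' Dyadic frequency bands of a decomposition
#'
#' @param levels Number of detail levels `J`.
#' @param fs Sampling rate in Hz.
#' @return A tibble with columns `component` (`"D1"..."DJ"`, `"AJ"`),
#'   `level`, `f_low`, `f_high` in Hz.
#' @export
modwt_bands <- function(levels, fs) {
  j <- seq_len(levels)
  tibble::tibble(
    component = c(paste0("D", j), paste0("A", levels)),
    level = c(j, levels + 1L),
    f_low = c(fs / 2^(j + 1), 0),
    f_high = c(fs / 2^j, fs / 2^(levels + 1))
  )
}

# ---- tidy/format methods -------------------------------------------------

#' @export
print.modwt <- function(x, ...) {
  cat("<modwt> ", x$bank$wavelet, ", J = ", x$bank$levels,
      ", n = ", x$n, ", fs = ", signif(x$fs, 6), " Hz\n", sep = "")
  invisible(x)
}

#' @export
print.modwt_mra <- function(x, ...) {
  cat("<modwt_mra> ", x$bank$levels + 1L, " components (D1..D",
      x$bank$levels, ", A", x$bank$levels, "), n = ", x$n, "\n", sep = "")
  invisible(x)
}

#' Tidy a MODWT decomposition into a long tibble
#'
#' @param x A `modwt` or `modwt_mra` object.
#' @param ... Unused.
#' @return A tibble with columns `time_s`, `component`, `value`.
#' @exportS3Method generics::tidy
tidy.modwt <- function(x, ...) {
  comps <- c(stats::setNames(x$W, paste0("W", seq_along(x$W))),
             list(V = x$V))
  names(comps)[length(comps)] <- paste0("V", x$bank$levels)
  .tidy_components(comps, x$fs)
}

#' @rdname tidy.modwt
#' @exportS3Method generics::tidy
tidy.modwt_mra <- function(x, ...) {
  comps <- c(stats::setNames(x$D, paste0("D", seq_along(x$D))),
             list(A = x$A))
  names(comps)[length(comps)] <- paste0("A", x$bank$levels)
  .tidy_components(comps, x$fs)
}

.tidy_components <- function(comps, fs) {
  n <- length(comps[[1]])
  purrr::imap_dfr(comps, function(v, nm) {
    tibble::tibble(time_s = (seq_len(n) - 1) / fs, component = nm, value = v)
  })
}

#' Convert a multiresolution analysis to a wide tibble
#'
#' One row per sample; columns `time_s`, `D1` ... `DJ`, `AJ`.  This is the
#' interchange layout written by [write_decomposition()].
#'
#' @param x A `modwt_mra` object.
#' @param ... Unused.
#' @exportS3Method tibble::as_tibble
as_tibble.modwt_mra <- function(x, ...) {
  out <- tibble::tibble(time_s = (seq_len(x$n) - 1) / x$fs)
  for (j in seq_along(x$D)) out[[paste0("D", j)]] <- x$D[[j]]
  out[[paste0("A", x$bank$levels)]] <- x$A
  out
}

#' Plot a multiresolution analysis
#'
#' Facets the detail and approximation components over time.
#'
#' @param object A `modwt_mra` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.modwt_mra <- function(object, ...) {
  dat <- tidy(object)
  dat$component <- factor(dat$component, levels = unique(dat$component))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$time_s, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$component), scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = NULL)
}
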