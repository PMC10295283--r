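# Synthetic HbO signal generator: autoregressive baseline noise, four
# band-limited physiological oscillations (cardiac, respiratory, Mayer,
# very-low-frequency), and an optional task-evoked hemodynamic response
# built from a two-gamma kernel.

#' Default physiological oscillation specifications
#'
#' Four band-limited sinusoidal components contaminate hemodynamic
#' recordings: cardiac pulsation near 1 Hz, respiration near 0.25 Hz,
#' Mayer waves (arterial-pressure oscillations) near 0.1 Hz, and a
#' very-low-frequency component near 0.01 Hz.  For each synthetic record a
#' constant frequency is drawn uniformly from `center +/- halfwidth` and a
#' constant amplitude uniformly from `[amp_low, amp_high]`.
#'
#' @return A tibble with columns `kind`, `center_freq`, `freq_halfwidth`,
#'   `amp_low`, `amp_high` (Hz and arbitrary units).
#' @export
component_specs <- function() {
  tibble::tibble(
    kind = c("cardiac", "respiratory", "mayer", "vlf"),
    center_freq = c(1, 0.25, 0.1, 0.01),
    freq_halfwidth = c(0.1, 0.01, 0.01, 0.001),
    amp_low = 0.01,
    amp_high = 0.03
  )
}

# Levinson-Durbin step recursion: map partial autocorrelations to AR
# coefficients.  |pacf| < 1 guarantees a stable (stationary) AR process.
pacf_to_ar <- function(pacf) {
  p <- length(pacf)
  a <- numeric(0)
  for (k in seq_len(p)) {
    a_new <- c(if (k > 1) a - pacf[k] * rev(a), pacf[k])
    a <- a_new
  }
  a
}

#' Generate stable autoregressive baseline noise
#'
#' Draws a random stable AR(`order`) process: partial autocorrelations are
#' sampled uniformly in (-0.5, 0.5) and mapped to AR coefficients through
#' the Levinson-Durbin recursion, which guarantees stationarity by
#' construction.  The realization (Gaussian innovations, with burn-in) is
#' centred and scaled to unit sample variance.  Uses the current RNG
#' state; seed with [set.seed()] for reproducibility.
#'
#' @param n Number of samples (`n > order`).
#' @param order AR order (default 30).
#' @return Numeric vector of length `n`, zero mean, unit sample variance,
#'   with the AR coefficients attached as attribute `"ar"`.
#' @export
ar_noise <- function(n, order = 30L) {
  order <- as.integer(order)
  if (order < 1L) rlang::abort("`order` must be >= 1.")
  if (n <= order) rlang::abort("`n` must exceed the AR order.")
  phi <- pacf_to_ar(stats::runif(order, -0.5, 0.5))
  burn <- 10L * order
  innov <- stats::rnorm(n + burn)
  x <- stats::filter(innov, phi, method = "recursive")
  x <- as.numeric(x)[(burn + 1):(burn + n)]
  x <- x - mean(x)
  s <- stats::sd(x)
  if (s > 0) x <- x / s
  attr(x, "ar") <- phi
  x
}

#' Generate a band-limited physiological oscillation
#'
#' A pure sinusoid whose frequency, phase and amplitude are drawn once for
#' the whole record: frequency uniform in
#' `[center_freq - freq_halfwidth, center_freq + freq_halfwidth]`, phase
#' uniform in `[0, 2*pi)`, amplitude uniform in `[amp_low, amp_high]`.
#'
#' @param n Number of samples.
#' @param fs Sampling rate in Hz.
#' @param center_freq Band center in Hz.
#' @param freq_halfwidth Half-width of the frequency band in Hz.
#' @param amp_low,amp_high Amplitude range in arbitrary units.
#' @return Numeric vector of length `n` with the drawn `"freq"`, `"amp"`
#'   and `"phase"` attached as attributes.
#' @export
oscillation <- function(n, fs, center_freq, freq_halfwidth = 0,
                        amp_low = 0.01, amp_high = 0.03) {
  if (center_freq - freq_halfwidth < 0) {
    rlang::abort("Frequency band extends below 0 Hz.")
  }
  f <- stats::runif(1, center_freq - freq_halfwidth, center_freq + freq_halfwidth)
  phase <- stats::runif(1, 0, 2 * pi)
  amp <- stats::runif(1, amp_low, amp_high)
  t <- (seq_len(n) - 1) / fs
  x <- amp * sin(2 * pi * f * t + phase)
  attr(x, "freq") <- f
  attr(x, "amp") <- amp
  attr(x, "phase") <- phase
  x
}

# Two-gamma impulse response sampled at fs, normalized to unit peak.
# Canonical parameters: peak at ~6 s, undershoot at ~16 s, ratio 1/6.
two_gamma_kernel <- function(fs, peak_delay_s = 6, undershoot_delay_s = 16,
                             peak_dispersion = 1, undershoot_dispersion = 1,
                             undershoot_ratio = 1 / 6, length_s = 32) {
  t <- seq(0, length_s, by = 1 / fs)
  k <- stats::dgamma(t, shape = peak_delay_s / peak_dispersion,
                     scale = peak_dispersion) -
    undershoot_ratio * stats::dgamma(t, shape = undershoot_delay_s / undershoot_dispersion,
                                     scale = undershoot_dispersion)
  k / max(k)
}

#' Generate a task-evoked hemodynamic response
#'
#' The desired hemodynamic response (dHRF): a two-gamma kernel convolved
#' with a boxcar spanning the task period, renormalized to unit peak and
#' scaled by `amplitude`.  The response is zero before `onset_s`; its tail
#' is truncated at the end of the record.
#'
#' @param n Number of samples in the record.
#' @param fs Sampling rate in Hz.
#' @param onset_s Task onset in seconds from the start of the record.
#' @param task_duration_s Task (boxcar) duration in seconds (default 20).
#' @param post_rest_s Post-task rest within the modelled window (default
#'   20); `onset_s + task_duration_s + post_rest_s` must fit in the record.
#' @param amplitude Peak amplitude in arbitrary units.
#' @param peak_delay_s,undershoot_delay_s,peak_dispersion,undershoot_dispersion,undershoot_ratio
#'   Two-gamma kernel parameters (canonical defaults: 6 s peak, 16 s
#'   undershoot, unit dispersions, undershoot ratio 1/6).
#' @return Numeric vector of length `n`.
#' @export
dhrf <- function(n, fs, onset_s, task_duration_s = 20, post_rest_s = 20,
                 amplitude = 0.2, peak_delay_s = 6, undershoot_delay_s = 16,
                 peak_dispersion = 1, undershoot_dispersion = 1,
                 undershoot_ratio = 1 / 6) {
  if (onset_s + task_duration_s + post_rest_s > (n + 0.5) / fs) {
    rlang::abort("The modelled response window extends past the record end.")
  }
  if (amplitude == 0) return(numeric(n))
  kern <- two_gamma_kernel(fs, peak_delay_s, undershoot_delay_s,
                           peak_dispersion, undershoot_dispersion,
                           undershoot_ratio)
  box <- rep(1, max(1L, round(task_duration_s * fs)))
  resp <- stats::convolve(box, rev(kern), type = "open")
  resp <- amplitude * resp / max(resp)
  out <- numeric(n)
  i0 <- round(onset_s * fs) + 1L
  idx <- i0:min(n, i0 + length(resp) - 1L)
  out[idx] <- resp[seq_along(idx)]
  out
}

#' Simulate a labelled synthetic fNIRS (HbO) dataset
#'
#' Generates `n_records` single-channel records, each the sum of six
#' labelled components: unit-variance AR baseline noise scaled into the
#' common amplitude range, four band-limited oscillations (cardiac,
#' respiratory, Mayer, very-low-frequency), and -- for a fixed fraction of
#' records -- a two-gamma hemodynamic response whose task starts at the
#' end of the resting period.  Every combined record is offset so that its
#' first sample is exactly zero.
#'
#' Per-record seeds are derived deterministically from `master_seed`, so
#' the whole dataset is bitwise reproducible.
#'
#' @param n_records Number of records (study default 1000).
#' @param fraction_with_dhrf Fraction of records carrying a hemodynamic
#'   response (default 0.5); exactly `round(fraction * n_records)` records
#'   receive one, assigned at random.
#' @param fs Sampling rate in Hz (default 8.138).
#' @param rest_duration_s Resting-state length in seconds (default 600).
#' @param task_window_s Task window appended after rest (default 40 s:
#'   20 s task + 20 s rest).
#' @param master_seed Integer master seed.
#' @param ar_order Order of the baseline AR noise (default 30).
#' @param components Component specification tibble as returned by
#'   [component_specs()].
#' @param dhrf_amp_range Amplitude range of the hemodynamic response
#'   (default `c(0.1, 0.35)`).
#' @return A tibble with one row per record: `record_id`, `seed`,
#'   `has_dhrf`, `dhrf_amplitude` (`NA` when absent), one `freq_*` and
#'   `amp_*` column per oscillation, and a `signal` list-column holding a
#'   per-record tibble with columns `time_s`, `combined` and one column
#'   per component (`baseline_ar`, `cardiac`, `respiratory`, `mayer`,
#'   `vlf`, `dhrf`).
#' @examples
#' ds <- fnirs_simulate(n_records = 2, rest_duration_s = 60,
#'                      task_window_s = 40, master_seed = 1)
#' ds$signal[[1]]
#' @export
fnirs_simulate <- function(n_records = 1000L, fraction_with_dhrf = 0.5,
                           fs = 8.138, rest_duration_s = 600,
                           task_window_s = 40, master_seed = 1L,
                           ar_order = 30L, components = component_specs(),
                           dhrf_amp_range = c(0.1, 0.35)) {
  n_records <- as.integer(n_records)
  if (n_records < 1L) rlang::abort("`n_records` must be >= 1.")
  if (fraction_with_dhrf < 0 || fraction_with_dhrf > 1) {
    rlang::abort("`fraction_with_dhrf` must lie in [0, 1].")
  }
  n <- round((rest_duration_s + task_window_s) * fs)
  n_dhrf <- round(fraction_with_dhrf * n_records)
  base_seed <- as.integer(abs(master_seed) %% 1e9)

  # dHRF assignment drawn once from the master seed
  dhrf_ids <- local({
    old <- .save_rng()
    on.exit(.restore_rng(old))
    set.seed(base_seed)
    sort(sample.int(n_records, n_dhrf))
  })

  rows <- purrr::map(seq_len(n_records), function(i) {
    rec_seed <- base_seed + i
    old <- .save_rng()
    on.exit(.restore_rng(old))
    set.seed(rec_seed)
    has_dhrf <- i %in% dhrf_ids

    amp_ar <- stats::runif(1, 0.01, 0.03)
    baseline <- amp_ar * ar_noise(n, ar_order)
    osc <- purrr::pmap(components, function(kind, center_freq, freq_halfwidth,
                                            amp_low, amp_high) {
      oscillation(n, fs, center_freq, freq_halfwidth, amp_low, amp_high)
    })
    names(osc) <- components$kind
    dhrf_amp <- if (has_dhrf) stats::runif(1, dhrf_amp_range[1], dhrf_amp_range[2]) else NA_real_
    hrf <- if (has_dhrf) {
      dhrf(n, fs, onset_s = rest_duration_s, amplitude = dhrf_amp)
    } else {
      numeric(n)
    }
    combined <- as.numeric(baseline) + Reduce(`+`, lapply(osc, as.numeric)) + hrf
    combined <- combined - combined[1]

    sig <- tibble::tibble(
      time_s = (seq_len(n) - 1) / fs,
      combined = combined,
      baseline_ar = as.numeric(baseline)
    )
    for (k in names(osc)) sig[[k]] <- as.numeric(osc[[k]])
    sig$dhrf <- hrf

    meta <- tibble::tibble(
      record_id = i, seed = rec_seed, has_dhrf = has_dhrf,
      dhrf_amplitude = dhrf_amp, amp_baseline = amp_ar
    )
    for (k in names(osc)) {
      meta[[paste0("freq_", k)]] <- attr(osc[[k]], "freq")
      meta[[paste0("amp_", k)]] <- attr(osc[[k]], "amp")
    }
    meta$signal <- list(sig)
    meta
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "fs") <- fs
  attr(out, "rest_duration_s") <- rest_duration_s
  attr(out, "task_window_s") <- task_window_s
  attr(out, "master_seed") <- master_seed
  out
}

.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
}

.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Write a simulated dataset to per-record CSV files plus a manifest
#'
#' @param dataset A tibble from [fnirs_simulate()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, the manifest tibble (with a `file` column).
#' @export
write_fnirs_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- sprintf("record_%04d.csv", dataset$record_id)
  purrr::walk2(dataset$signal, files, function(sig, f) {
    utils::write.csv(sig, file.path(dir, f), row.names = FALSE)
  })
  manifest <- dplyr::select(dataset, -"signal")
  manifest$file <- files
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}

#' Plot one synthetic record and its components
#'
#' @param dataset A tibble from [fnirs_simulate()].
#' @param record Which record (row index) to plot.
#' @return A ggplot object, components faceted over time.
#' @export
plot_fnirs_record <- function(dataset, record = 1L) {
  sig <- dataset$signal[[record]]
  long <- tidyr::pivot_longer(sig, -"time_s",
                              names_to = "component", values_to = "value")
  long$component <- factor(long$component, levels = setdiff(names(sig), "time_s"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time_s, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$component), scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = "concentration change (a.u.)")
}
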