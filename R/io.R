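# File readers and writers: delimited time series, decomposition export,
# metrics tables.

#' Read a single-channel time series from delimited text
#'
#' Expects a header row with a time column (`time_s` or `time`, seconds)
#' and a value column (`value`, `combined`, or the first numeric non-time
#' column).  The sampling rate is derived from the time stamps, which
#' must be uniform to within 0.1% of the median step, or supplied
#' explicitly.
#'
#' @param path File path (CSV; TSV autodetected from a `.tsv` extension
#'   or `sep`).
#' @param fs Sampling rate override in Hz.
#' @param sep Field separator (default `","`).
#' @param value_col Optional name of the signal column.
#' @return A tibble with columns `time_s` and `value`, with the sampling
#'   rate attached as attribute `"fs"`.
#' @export
read_timeseries <- function(path, fs = NULL, sep = NULL, value_col = NULL) {
  if (!file.exists(path)) rlang::abort(paste0("File not found: ", path))
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("snirf", "h5", "hdf5")) {
    rlang::abort("Unsupported format: only delimited text (CSV/TSV) is supported.")
  }
  if (is.null(sep)) sep <- if (ext == "tsv") "\t" else ","
  dat <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE)
  if (!is.null(value_col)) {
    if (!value_col %in% names(dat)) {
      rlang::abort(paste0("Column '", value_col, "' not found in ", path))
    }
    dat <- dat[, c(intersect(c("time_s", "time"), names(dat)), value_col)]
    names(dat)[ncol(dat)] <- "value"
  }
  sig <- as_signal(dat, fs = fs)
  out <- tibble::tibble(time_s = (seq_along(sig$samples) - 1) / sig$fs,
                        value = sig$samples)
  attr(out, "fs") <- sig$fs
  out
}

#' Write a time series to CSV
#'
#' @param x Numeric vector or tibble with `time_s`/`value`.
#' @param path Output path.
#' @param fs Sampling rate (required for numeric input).
#' @export
write_timeseries <- function(x, path, fs = NULL) {
  sig <- as_signal(x, fs = fs)
  utils::write.csv(
    data.frame(time_s = (seq_along(sig$samples) - 1) / sig$fs,
               value = sig$samples),
    path, row.names = FALSE
  )
  invisible(path)
}

#' Write a multiresolution decomposition to wide CSV
#'
#' Columns `time_s`, `D1` ... `DJ`, `AJ`, one row per sample.
#'
#' @param x A `modwt_mra` object.
#' @param path Output path.
#' @export
write_decomposition <- function(x, path) {
  stopifnot(inherits(x, "modwt_mra"))
  utils::write.csv(as.data.frame(as_tibble(x)), path, row.names = FALSE)
  invisible(path)
}

#' Write an experiment metrics table to long CSV
#'
#' @param x An `fnirs_experiment` (its tidy metrics are written) or a
#'   metrics tibble.
#' @param path Output path.
#' @export
write_metrics <- function(x, path) {
  tab <- if (inherits(x, "fnirs_experiment")) tidy(x) else x
  utils::write.csv(as.data.frame(tab), path, row.names = FALSE)
  invisible(path)
}
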