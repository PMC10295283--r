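# Brute-force oracles and small fixtures shared across tests.

# Direct evaluation of the MODWT analysis equations: circular convolution
# of the signal with the periodized equivalent level-j filter.  O(n^2);
# independent of the pyramid implementation.
direct_modwt_filter <- function(x, f) {
  n <- length(x)
  fp <- if (length(f) <= n) c(f, numeric(n - length(f))) else {
    out <- numeric(n)
    for (k in seq_along(f)) {
      i <- ((k - 1) %% n) + 1
      out[i] <- out[i] + f[k]
    }
    out
  }
  vapply(seq_len(n) - 1L, function(t) {
    sum(fp * x[((t - (seq_len(n) - 1L)) %% n) + 1L])
  }, numeric(1))
}

direct_modwt <- function(x, bank) {
  list(
    W = lapply(bank$high_pass, function(f) direct_modwt_filter(x, f)),
    V = direct_modwt_filter(x, bank$low_pass[[bank$levels]])
  )
}

# circular shift by k (positive = delay)
circ_shift <- function(x, k) {
  n <- length(x)
  k <- k %% n
  if (k == 0) return(x)
  c(x[(n - k + 1):n], x[1:(n - k)])
}

# small, fast forecaster configuration for structural pipeline tests
tiny_config <- function(seed = 1) {
  forecaster_config(hidden_units = c(8, 6, 4), dropout = 0.1, max_epochs = 2,
                    minibatch = 64, lookback = 16, steps_per_epoch = 5,
                    seed = seed)
}

# short synthetic dataset (60-s rest) for structural pipeline tests
tiny_dataset <- function(n_records = 8, master_seed = 99) {
  fnirs_simulate(n_records = n_records, rest_duration_s = 60,
                 task_window_s = 40, master_seed = master_seed)
}
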