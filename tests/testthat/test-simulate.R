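test_that("the Levinson-Durbin mapping gives stable AR coefficients", {
  expect_equal(fnirscast:::pacf_to_ar(0.4), 0.4)
  expect_equal(fnirscast:::pacf_to_ar(c(0, 0, 0)), c(0, 0, 0))
  set.seed(5)
  for (rep in 1:20) {
    phi <- fnirscast:::pacf_to_ar(runif(30, -0.5, 0.5))
    roots <- polyroot(c(1, -phi))
    expect_true(all(Mod(roots) > 1))  # stationarity
  }
})

test_that("AR noise is reproducible, normalized and colored", {
  set.seed(11); a <- ar_noise(4883, 30)
  set.seed(11); b <- ar_noise(4883, 30)
  expect_identical(a, b)
  expect_equal(mean(a), 0, tolerance = 1e-12)
  expect_equal(stats::sd(a), 1, tolerance = 1e-12)
  expect_error(ar_noise(10, 30), "order")
})

test_that("a trivial AR(1) with zero partial autocorrelation is white", {
  # pacf 0 -> coefficient 0 -> white noise; check lag-1 autocorrelation
  expect_equal(fnirscast:::pacf_to_ar(0), 0)
  set.seed(2)
  n <- 4000
  x <- stats::filter(rnorm(n), fnirscast:::pacf_to_ar(0), method = "recursive")
  r1 <- stats::acf(as.numeric(x), lag.max = 1, plot = FALSE)$acf[2]
  expect_lt(abs(r1), 3 / sqrt(n))
})

test_that("oscillations respect their frequency band and amplitude range", {
  set.seed(21)
  fs <- 8.138
  n <- 4883
  x <- oscillation(n, fs, center_freq = 1, freq_halfwidth = 0.1)
  expect_gte(attr(x, "freq"), 0.9)
  expect_lte(attr(x, "freq"), 1.1)
  expect_gte(attr(x, "amp"), 0.01)
  expect_lte(attr(x, "amp"), 0.03)
  # periodogram peak inside the cardiac band
  sp <- stats::spec.pgram(x, plot = FALSE, taper = 0)
  f_peak <- sp$freq[which.max(sp$spec)] * fs
  expect_gte(f_peak, 0.9)
  expect_lte(f_peak, 1.1)
})

test_that("degenerate oscillation parameters give an exact unit sinusoid", {
  set.seed(1)
  x <- oscillation(1000, 10, center_freq = 0.5, freq_halfwidth = 0,
                   amp_low = 1, amp_high = 1)
  ph <- attr(x, "phase")
  expect_equal(as.numeric(x), sin(2 * pi * 0.5 * (0:999) / 10 + ph),
               tolerance = 1e-12)
})

test_that("the very-low-frequency component completes 5.4-6.6 cycles in 600 s", {
  set.seed(31)
  fs <- 8.138
  n <- round(600 * fs)
  for (rep in 1:5) {
    x <- as.numeric(oscillation(n, fs, 0.01, 0.001))
    crossings <- sum(diff(sign(x)) != 0)
    expect_gte(crossings / 2, 5)
    expect_lte(crossings / 2, 7)
  }
})

test_that("the hemodynamic response has unit-peak scaling and a slow rise", {
  fs <- 8.138
  n <- round(640 * fs)
  d <- dhrf(n, fs, onset_s = 600, amplitude = 0.2)
  expect_equal(max(d), 0.2, tolerance = 1e-9)
  expect_true(all(d[1:round(600 * fs)] == 0))  # zero before onset
  peak_s <- (which.max(d) - 1) / fs - 600
  expect_gt(peak_s, 10)  # takes more than 10 s to rise to maximum
  expect_equal(dhrf(n, fs, 600, amplitude = 0), numeric(n))
  expect_error(dhrf(100, fs, onset_s = 600), "record end")
})

test_that("simulated datasets are reproducible and correctly labelled", {
  ds1 <- fnirs_simulate(n_records = 6, rest_duration_s = 60, master_seed = 7)
  ds2 <- fnirs_simulate(n_records = 6, rest_duration_s = 60, master_seed = 7)
  expect_identical(ds1$signal, ds2$signal)
  expect_identical(sum(ds1$has_dhrf), 3L)

  ds3 <- fnirs_simulate(n_records = 2, rest_duration_s = 60, master_seed = 8)
  expect_identical(sum(ds3$has_dhrf), 1L)
})

test_that("each record starts at zero and is the sum of its components", {
  ds <- fnirs_simulate(n_records = 4, rest_duration_s = 60, master_seed = 13)
  for (i in 1:4) {
    s <- ds$signal[[i]]
    expect_identical(s$combined[1], 0)
    parts <- s$baseline_ar + s$cardiac + s$respiratory + s$mayer + s$vlf + s$dhrf
    offset <- s$combined - parts
    expect_lt(max(offset) - min(offset), 1e-12)  # constant zeroing offset
  }
  # dHRF only in labelled records, placed after the rest period
  rest_n <- round(60 * 8.138)
  for (i in which(ds$has_dhrf)) {
    expect_true(all(ds$signal[[i]]$dhrf[1:rest_n] == 0))
    expect_gt(max(ds$signal[[i]]$dhrf), 0)
  }
  for (i in which(!ds$has_dhrf)) expect_equal(max(abs(ds$signal[[i]]$dhrf)), 0)
})

test_that("drawn amplitudes respect the stated ranges", {
  ds <- fnirs_simulate(n_records = 10, rest_duration_s = 60, master_seed = 17)
  amps <- c(ds$amp_baseline, ds$amp_cardiac, ds$amp_respiratory,
            ds$amp_mayer, ds$amp_vlf)
  expect_true(all(amps >= 0.01 & amps <= 0.03))
  damps <- ds$dhrf_amplitude[ds$has_dhrf]
  expect_true(all(damps >= 0.1 & damps <= 0.35))
  expect_true(all(is.na(ds$dhrf_amplitude[!ds$has_dhrf])))
})

test_that("default record geometry matches the study protocol", {
  ds <- fnirs_simulate(n_records = 1, master_seed = 1)
  expect_equal(nrow(ds$signal[[1]]), round(640 * 8.138))  # 5208 samples
  expect_equal(attr(ds, "fs"), 8.138)
  expect_equal(attr(ds, "rest_duration_s"), 600)
})
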