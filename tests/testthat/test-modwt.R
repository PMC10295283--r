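test_that("filter bank satisfies the defining sum and rescaling identities", {
  bank <- modwt_filter_bank("sym4", 3)
  expect_length(bank$high_pass[[1]], 8)
  expect_lt(abs(sum(bank$high_pass[[1]])), 1e-10)
  expect_lt(abs(sum(bank$low_pass[[1]]) - 1), 1e-10)
  # level-1 filters are the DWT pair over sqrt(2): unit DWT energy halves
  expect_equal(sum(bank$low_pass[[1]]^2), 0.5, tolerance = 1e-12)

  haar <- modwt_filter_bank("haar", 1)
  expect_equal(haar$low_pass[[1]], c(0.5, 0.5))
  expect_equal(haar$high_pass[[1]], c(0.5, -0.5))

  # every level's high-pass sums to zero, low-pass to 2^-j... the cascade
  # keeps sum(g_j) = 1 at every level
  deep <- modwt_filter_bank("sym4", 6)
  for (j in 1:6) {
    expect_lt(abs(sum(deep$high_pass[[j]])), 1e-10)
    expect_lt(abs(sum(deep$low_pass[[j]]) - 1), 1e-10)
  }
})

test_that("unknown wavelet names are rejected by name", {
  expect_error(modwt_filter_bank("coif5", 2), "coif5")
  expect_error(modwt_filter_bank("sym4", 0), "levels")
})

test_that("level-8 squared gain concentrates in its dyadic band", {
  fs <- 8.138
  bank <- modwt_filter_bank("sym4", 8)
  f_grid <- seq(0, fs / 2, length.out = 4096)
  h <- bank$high_pass[[8]]
  gain <- vapply(f_grid, function(f) {
    Mod(sum(h * exp(-2i * pi * f * (seq_along(h) - 1) / fs)))^2
  }, numeric(1))
  in_band <- f_grid >= fs / 2^9 & f_grid <= fs / 2^8
  # peak response lies inside the band and dominates out-of-band response
  expect_true(in_band[which.max(gain)])
  expect_gt(sum(gain[in_band]), sum(gain[!in_band]))
})

test_that("pyramid output equals the direct-convolution oracle", {
  set.seed(101)
  for (n in c(64, 100, 200, 256)) {
    x <- rnorm(n)
    J <- 4
    bank <- modwt_filter_bank("sym4", J)
    w <- modwt(x, fs = 1, bank = bank)
    oracle <- direct_modwt(x, bank)
    for (j in 1:J) expect_lt(max(abs(w$W[[j]] - oracle$W[[j]])), 1e-10)
    expect_lt(max(abs(w$V - oracle$V)), 1e-10)
  }
})

test_that("a constant signal has vanishing details and a constant scaling", {
  w <- modwt(rep(2.5, 64), fs = 1, levels = 3)
  for (j in 1:3) expect_lt(max(abs(w$W[[j]])), 1e-10)
  expect_equal(w$V, rep(2.5, 64), tolerance = 1e-10)
  m <- mra(w)
  for (j in 1:3) expect_lt(max(abs(m$D[[j]])), 1e-10)
  expect_equal(m$A, rep(2.5, 64), tolerance = 1e-10)
})

test_that("the transform is shift-equivariant", {
  set.seed(7)
  x <- rnorm(128)
  w <- modwt(x, fs = 1, levels = 4)
  for (k in c(1, 17, 100)) {
    ws <- modwt(circ_shift(x, k), fs = 1, levels = 4)
    for (j in 1:4) {
      expect_lt(max(abs(ws$W[[j]] - circ_shift(w$W[[j]], k))), 1e-10)
    }
    expect_lt(max(abs(ws$V - circ_shift(w$V, k))), 1e-10)
  }
})

test_that("perfect reconstruction and energy conservation hold on random input", {
  set.seed(42)
  for (rep in 1:20) {
    n <- sample(50:600, 1)
    x <- rnorm(n) * runif(1, 0.1, 10)
    J <- select_level(n)
    w <- modwt(x, fs = 1, levels = J)
    m <- mra(w)
    recon <- Reduce(`+`, m$D) + m$A
    expect_lt(max(abs(recon - x)) / sqrt(sum(x^2)), 1e-8)
    energy <- sum(vapply(w$W, function(v) sum(v^2), numeric(1))) + sum(w$V^2)
    expect_lt(abs(energy - sum(x^2)) / sum(x^2), 1e-6)
  }
})

test_that("reconstruction holds for arbitrary (non power of two) lengths", {
  set.seed(3)
  x <- rnorm(487)
  m <- mra(modwt(x, fs = 8.138, levels = 8))
  expect_lt(max(abs(Reduce(`+`, m$D) + m$A - x)) / sqrt(sum(x^2)), 1e-8)
  expect_length(m$D, 8)  # eight details + one approximation = nine signals
})

test_that("a slow sinusoid lands in the deepest detail band", {
  fs <- 8.138
  x <- sin(2 * pi * 0.025 * (0:4882) / fs)
  m <- mra(suppressWarnings(modwt(x, fs = fs, levels = 8)))
  energies <- vapply(m$D, function(v) sum(v^2), numeric(1))
  expect_identical(which.max(energies), 8L)
})

test_that("band selectivity: sinusoids at dyadic band centers stay in their level", {
  fs <- 8.138
  n <- 2048
  J <- 8
  for (j in 2:(J - 1)) {
    f_c <- sqrt((fs / 2^(j + 1)) * (fs / 2^j))  # geometric band center
    x <- sin(2 * pi * f_c * (0:(n - 1)) / fs)
    m <- mra(modwt(x, fs = fs, levels = J))
    e <- c(vapply(m$D, function(v) sum(v^2), numeric(1)), sum(m$A^2))
    expect_gt(e[j] / sum(e), 0.6)
  }
})

test_that("level selection returns the largest integer strictly below log2(n)", {
  expect_identical(select_level(487), 8L)
  expect_identical(select_level(round(60 * 8.138)), 8L)
  expect_identical(select_level(256), 7L)
  expect_identical(select_level(4883), 12L)
  expect_identical(select_level(2), 0L)
  expect_error(select_level(1), "n")
})

test_that("requesting more levels than select_level warns but proceeds", {
  x <- rnorm(100)
  expect_warning(w <- modwt(x, fs = 8.138, levels = 8), "exceeds")
  expect_length(w$W, 8)
  m <- mra(w)
  expect_lt(max(abs(Reduce(`+`, m$D) + m$A - x)) / sqrt(sum(x^2)), 1e-8)
})

test_that("non-finite samples are rejected", {
  expect_error(modwt(c(1, NA, 3, 4), fs = 1, levels = 1), "finite")
  expect_error(modwt(c(1, Inf, 3, 4), fs = 1, levels = 1), "finite")
})

test_that("tidy and wide layouts expose all components", {
  x <- rnorm(64)
  m <- mra(modwt(x, fs = 2, levels = 3))
  wide <- as_tibble(m)
  expect_named(wide, c("time_s", "D1", "D2", "D3", "A3"))
  expect_equal(nrow(wide), 64)
  long <- tidy(m)
  expect_setequal(unique(long$component), c("D1", "D2", "D3", "A3"))
  # additive reconstruction visible from the wide table too
  expect_equal(rowSums(wide[, -1]), x, tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("dyadic band table matches fs and level count", {
  b <- modwt_bands(8, 8.138)
  expect_equal(nrow(b), 9)
  expect_equal(b$f_low[8], 8.138 / 2^9)
  expect_equal(b$f_high[8], 8.138 / 2^8)
  expect_equal(b$f_low[9], 0)
})
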