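# Frequencies aligned to DFT bins of a 150-sample, 3.3 Hz series
# (bin k -> k * 0.022 Hz) so the single-bin DFT is an exact oracle.
bin_freq <- function(k, n = 150, fs = 3.3) k * fs / n

test_that("pencil matches the DFT oracle on noiseless bin-aligned tone sums", {
  fs <- 3.3; n <- 150
  t <- (0:(n - 1)) / fs
  cases <- list(
    list(dc = 7, tones = list()),
    list(dc = 5, tones = list(c(bin_freq(15), 2))),
    list(dc = 5, tones = list(c(bin_freq(15), 2), c(bin_freq(50), 0.5))),
    list(dc = 0.3, tones = list(c(bin_freq(9), 1.5), c(bin_freq(23), 0.8),
                                c(bin_freq(61), 0.2))))
  for (cs in cases) {
    y <- rep(cs$dc, n)
    for (tn in cs$tones) y <- y + tn[2] * sin(2 * pi * tn[1] * t + 0.7)
    comps <- matrix_pencil_decompose(y, fs)
    expect_equal(nrow(comps), 1 + length(cs$tones))
    expect_equal(comps$frequency,
                 c(0, vapply(cs$tones, `[`, 0, 1)), tolerance = 1e-9)
    for (f0 in comps$frequency) {
      expect_equal(component_amplitude_at(comps, f0, tol = 0.01),
                   dft_amplitude_oracle(y, fs, f0), tolerance = 1e-6)
    }
  }
})

test_that("amplitudes are linear in the signal scale", {
  t <- (0:99) / 3.3
  y <- 4 + 1.3 * sin(2 * pi * 0.31 * t)
  a1 <- matrix_pencil_decompose(y, 3.3)$amplitude
  a5 <- matrix_pencil_decompose(5 * y, 3.3)$amplitude
  expect_equal(a5, 5 * a1, tolerance = 1e-9)
})

test_that("real input reconstructs from merged real components", {
  set.seed(1)
  t <- (0:119) / 3.3
  y <- 2 + sin(2 * pi * 0.3 * t + 1) + 0.4 * sin(2 * pi * 1.2 * t + 2)
  comps <- matrix_pencil_decompose(y, 3.3)
  recon <- mplung:::reconstruct_components(comps, length(y), 3.3)
  expect_equal(recon, y, tolerance = 1e-8)
  expect_true(all(comps$amplitude >= 0))
})

test_that("tone amplitude bias stays below 5% at SNR 20", {
  fs <- 3.3; n <- 150
  t <- (0:(n - 1)) / fs
  amp <- 2; noise_sd <- amp / 20
  est <- vapply(1:50, function(s) {
    set.seed(s)
    y <- 5 + amp * sin(2 * pi * 0.31 * t) + rnorm(n, sd = noise_sd)
    component_amplitude_at(matrix_pencil_decompose(y, fs), 0.31, tol = 0.05)
  }, numeric(1))
  expect_lt(abs(mean(est) / amp - 1), 0.05)
})

test_that("component matching ties break toward the lower frequency", {
  comps <- data.frame(frequency = c(0.26, 0.34), damping = 0,
                      amplitude = c(1.5, 2.5), phase = 0)
  expect_equal(component_amplitude_at(comps, 0.30, tol = 0.1), 1.5)
  expect_equal(component_amplitude_at(comps, 0.32, tol = 0.1), 2.5)
  expect_equal(component_amplitude_at(comps, 0.5, tol = 0.1), 0)
})

test_that("the DFT oracle rejects off-bin frequencies and tracks noise mildly", {
  y <- rep(1, 150)
  expect_error(dft_amplitude_oracle(y, 3.3, 0.3), "bin")
  expect_equal(dft_amplitude_oracle(y, 3.3, 0), 1)
  t <- (0:149) / 3.3
  est <- vapply(1:10, function(s) {
    set.seed(s)
    dft_amplitude_oracle(2 * sin(2 * pi * bin_freq(15) * t) +
                           rnorm(150, sd = 0.02), 3.3, bin_freq(15))
  }, numeric(1))
  expect_true(all(abs(est - 2) < 0.02))
})

test_that("cardinal frequencies are recovered from phantoms", {
  ph <- generate_phantom_series(small_phantom_config(noise_sd = 0, seed = 6))
  ser <- ph$series; ser$registered <- TRUE  # phantom has no planted motion
  fr <- estimate_cardinal_frequencies(ser, ph$mask)
  expect_equal(fr$f_resp, 0.30, tolerance = 0.005)
  expect_equal(fr$f_card, 1.25, tolerance = 0.005)
})

test_that("cardinal frequency estimates are stable under noise across seeds", {
  for (s in 0:9) {
    ph <- generate_phantom_series(
      small_phantom_config(noise_sd = 0.05, seed = s))
    ser <- ph$series; ser$registered <- TRUE
    fr <- estimate_cardinal_frequencies(ser, ph$mask)
    expect_lt(abs(fr$f_resp - 0.30), 0.02)
    expect_lt(abs(fr$f_card - 1.25), 0.02)
  }
})

test_that("a band without signal raises an error naming the band", {
  ph <- generate_phantom_series(small_phantom_config(card_amp_mean = 0,
                                                     noise_sd = 0, seed = 8))
  # remove the heart label so the cardiac search runs on the lung series
  labels <- ph$mask$labels
  labels[labels == 3L] <- 0L
  ser <- ph$series; ser$registered <- TRUE
  expect_error(estimate_cardinal_frequencies(ser, lung_mask(labels)),
               "cardiac")
})

test_that("degenerate pencil inputs are rejected", {
  expect_error(matrix_pencil_decompose(1:5, 1), "short")
  expect_error(matrix_pencil_decompose(c(1:100, NA, 1:49), 3.3), "finite")
  expect_error(matrix_pencil_decompose(rnorm(100), 3.3, pencil_L = 10),
               "pencil_L")
})
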