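test_that("ROI traces are per-frame means; degenerate ROIs behave", {
  stack <- array(7, dim = c(64, 8, 8))
  tr <- extract_roi_trace(stack, c(1, 1, 8, 8), 100)
  expect_equal(tr$values, rep(7, 64))

  # a 1x1 ROI is that pixel's time series
  set.seed(1)
  stack[, 3, 5] <- rnorm(64)
  tr1 <- extract_roi_trace(stack, c(5, 3, 1, 1), 100)
  expect_equal(tr1$values, stack[, 3, 5])

  expect_error(extract_roi_trace(stack, c(6, 6, 4, 4), 100), "outside")
  expect_error(extract_roi_trace(array(0, c(16, 4, 4)), c(1, 1, 2, 2), 100),
               "T >= 32")
})

test_that("an on-bin noiseless sinusoid is estimated exactly", {
  fs <- 100; n <- 1000
  t <- (0:(n - 1)) / fs
  tr <- intensity_trace(100 + sin(2 * pi * 8 * t), fs)
  est <- cbf_fft(tr)
  expect_equal(est$frequency, 8.0, tolerance = 1e-6)
  expect_gt(est$power_fraction, 0.9)
})

test_that("off-bin frequencies are recovered by quadratic refinement", {
  # 8.83 Hz sits between bins at 100 fps / 1024 frames (~0.098 Hz bins)
  g <- gen_cilia_trace(f0 = 8.83, frame_rate = 100, n_frames = 1024,
                       snr = 5, seed = 42)
  est <- cbf_fft(g$trace, band = c(1, 20))
  expect_lt(abs(est$frequency - 8.83), 0.1)

  g2 <- gen_cilia_trace(f0 = 6.34, frame_rate = 100, n_frames = 1024,
                        snr = 5, seed = 42)
  expect_lt(abs(cbf_fft(g2$trace)$frequency - 6.34), 0.1)
})

test_that("estimates are invariant to gain and offset of the trace", {
  g <- gen_cilia_trace(f0 = 7.3, snr = 4, seed = 9)
  f_ref <- cbf_fft(g$trace)$frequency
  tr2 <- intensity_trace(3.7 * g$trace$values + 250, g$trace$frame_rate)
  expect_equal(cbf_fft(tr2)$frequency, f_ref, tolerance = 1e-12)
})

test_that("spatial averaging does not shift the dominant frequency", {
  g <- gen_cilia_stack(f0 = 8.2, height = 16, width = 16, snr = 5, seed = 21)
  f_small <- cbf_fft(extract_roi_trace(g$stack, c(7, 7, 2, 2), 100))$frequency
  f_large <- cbf_fft(extract_roi_trace(g$stack, c(1, 1, 16, 16), 100))$frequency
  expect_lt(abs(f_small - 8.2), 0.1)
  expect_lt(abs(f_large - 8.2), 0.1)
})

test_that("flat and noise-only traces are rejected rather than estimated", {
  expect_error(cbf_fft(intensity_trace(rep(5, 256), 100)), "flat trace")

  # noise-only traces: either rejected outright or their peak power
  # fraction sits far below that of a genuine oscillation
  set.seed(33)
  signal_frac <- cbf_fft(gen_cilia_trace(f0 = 8, snr = 5,
                                         seed = 1)$trace)$power_fraction
  n_weak <- 0L
  for (i in 1:50) {
    tr <- intensity_trace(rnorm(512), 100)
    res <- tryCatch(cbf_fft(tr), error = function(e) NULL)
    if (is.null(res) || res$power_fraction < signal_frac / 2)
      n_weak <- n_weak + 1L
  }
  expect_equal(n_weak, 50L)
})

test_that("band validation guards against Nyquist violations", {
  tr <- intensity_trace(rnorm(128), 100)
  expect_error(cbf_fft(tr, band = c(1, 60)), "Nyquist")
  expect_error(cbf_fft(tr, band = c(0, 20)), "f_lo")
  expect_error(cbf_fft(tr, band = c(20, 10)), "f_lo")
})

test_that("cycle counting converts cycles and frames to Hz", {
  expect_equal(cbf_cycle_count(100, 50, 5), 10.0)
  expect_equal(cbf_cycle_count(100, 500, 5), 1.0)
  expect_error(cbf_cycle_count(100, 0, 5), "frames_elapsed")

  # cross-method agreement on a noiseless tone: 8 Hz = 8 cycles in 100
  # frames at 100 fps; FFT agrees within one spectral bin
  fs <- 100; n <- 1024
  tr <- intensity_trace(sin(2 * pi * 8 * (0:(n - 1)) / fs), fs)
  f_fft <- cbf_fft(tr)$frequency
  f_count <- cbf_cycle_count(fs, 100, 8)
  expect_lt(abs(f_fft - f_count), fs / n)
})

test_that("FFT recovery holds across the physiological band (seeded replicates)", {
  set.seed(202)
  n_rep <- 200
  ok <- 0L
  for (i in seq_len(n_rep)) {
    f0 <- runif(1, 4, 12)
    snr <- runif(1, 2, 8)
    g <- gen_cilia_trace(f0 = f0, frame_rate = 100, n_frames = 1024,
                         snr = snr, seed = 5000 + i)
    est <- tryCatch(cbf_fft(g$trace), error = function(e) NULL)
    if (!is.null(est) && abs(est$frequency - f0) <= max(0.1, 100 / 1024))
      ok <- ok + 1L
  }
  expect_gte(ok, 0.95 * n_rep)
})

test_that("group summaries report medians and quartiles", {
  s <- summarize_cbf(c(6, 7, 8))
  expect_equal(s$median, 7)
  expect_equal(s$n, 3)
  expect_equal(summarize_cbf(5.5)$median, 5.5)

  two <- summarize_cbf(c(6, 7, 8, 9, 10, 11),
                       group = rep(c("a", "b"), each = 3))
  expect_equal(two$median[two$group == "a"], 7)
  expect_equal(two$median[two$group == "b"], 10)
  expect_error(summarize_cbf(numeric(0)), "no CBF")

  # three ROIs simulated at one frequency: pooled median recovers it
  f <- vapply(1:3, function(i) {
    cbf_fft(gen_cilia_trace(f0 = 6.34, snr = 5, seed = 60 + i)$trace)$frequency
  }, numeric(1))
  expect_lt(abs(summarize_cbf(f)$median - 6.34), 0.1)
})
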