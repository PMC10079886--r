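test_that("band-pass rejects the static gravity component", {
  tr <- accel_trace(cbind(0.2, -0.1, rep(1, 60 * 200)), 200)
  out <- bandpass_filter(tr)
  expect_lt(max(abs(out$samples)), 0.01)
})

test_that("band-pass magnitude matches the analytic Butterworth response", {
  fs <- 200
  # in-band tone: gain within 5% of the transfer-function value (~1)
  g5 <- butter_fb_gain(5, fs)
  out5 <- bandpass_filter(tone_trace(5, fs, 60))
  amp5 <- max(abs(out5$samples[4000:8000, 1]))
  expect_lt(abs(amp5 - g5) / g5, 0.05)
  expect_gt(amp5, 0.95)

  # out-of-band tone: strong attenuation, consistent with the same oracle
  g50 <- butter_fb_gain(50, fs)
  out50 <- bandpass_filter(tone_trace(50, fs, 60))
  amp50 <- max(abs(out50$samples[4000:8000, 1]))
  expect_lt(amp50, 0.2)
  expect_lt(abs(amp50 - g50) / g50, 0.05)
})

test_that("band-pass validates its preconditions", {
  tr <- accel_trace(cbind(0, 0, rep(1, 1000)), 30)  # Nyquist 15 < 20 Hz
  expect_error(bandpass_filter(tr), class = "accelmix_config_error")
  short <- accel_trace(cbind(0, 0, rep(1, 50)), 200)
  expect_error(bandpass_filter(short), class = "accelmix_input_error")
})

test_that("vector norm is exact on known triples", {
  tr <- accel_trace(rbind(c(3, 4, 0), c(0, 0, 0), c(1, 2, 2)), 100)
  expect_equal(vector_norm(tr)$values, c(5, 0, 3))
})

test_that("vector norm is invariant to axis permutation and sign flips", {
  set.seed(31)
  m <- matrix(rnorm(300), ncol = 3)
  base <- vector_norm(accel_trace(m, 100))$values
  for (perm in list(c(2, 1, 3), c(3, 2, 1), c(2, 3, 1))) {
    expect_equal(vector_norm(accel_trace(m[, perm], 100))$values, base)
  }
  flip <- m %*% diag(c(-1, 1, -1))
  expect_equal(vector_norm(accel_trace(flip, 100))$values, base)
})

test_that("moving average reproduces hand-computed shrunken-edge means", {
  s <- scalar_series(c(0, 0, 1, 0, 0), 1, kind = "norm")
  expect_equal(moving_average(s, 3)$values, c(0, 1 / 3, 1 / 3, 1 / 3, 0))
  # constant in, constant out
  cs <- scalar_series(rep(0.7, 40), 10, kind = "norm")
  expect_equal(moving_average(cs, 1.5)$values, rep(0.7, 40))
  # one-sample window is the identity
  set.seed(9)
  r <- scalar_series(runif(25), 10, kind = "norm")
  expect_equal(moving_average(r, 0.1)$values, r$values)
  # window longer than the series
  expect_error(moving_average(r, 10), class = "accelmix_input_error")
})

test_that("moving average agrees with a brute-force oracle and preserves order", {
  set.seed(17)
  for (w_s in c(0.3, 1, 2.1)) {
    x <- runif(200)
    s <- scalar_series(x, 10, kind = "norm")
    got <- moving_average(s, w_s)$values
    w <- round(w_s * 10)
    if (w %% 2 == 0) w <- w + 1
    expect_equal(got, naive_moving_average(x, w))
    # stays inside the running min/max of its own window
    h <- (w - 1) %/% 2
    for (i in seq_along(x)) {
      win <- x[max(1, i - h):min(length(x), i + h)]
      expect_gte(got[i] + 1e-12, min(win))
      expect_lte(got[i] - 1e-12, max(win))
    }
  }
})

test_that("acceleration index is the composition of its stages", {
  rec <- simulate_match(synth_match_config(sample_rate_hz = 50,
                                           duration_s = 60, seed = 4))
  cfg <- run_config()
  idx <- acceleration_index(rec$trace, cfg)
  manual <- moving_average(vector_norm(bandpass_filter(rec$trace, cfg)),
                           cfg$index_window_s)
  expect_equal(idx$values, manual$values)
  expect_identical(idx$kind, "acceleration_index")
  expect_true(all(idx$values >= 0))
  expect_lte(max(idx$values),
             max(vector_norm(bandpass_filter(rec$trace, cfg))$values))
})

test_that("a gravity-only trace yields a near-zero acceleration index", {
  tr <- accel_trace(cbind(0, 0, rep(1, 60 * 200)), 200)
  idx <- acceleration_index(tr)
  expect_lt(max(idx$values), 0.02)
})

test_that("a steady 0.9-G rally tracks its target index level", {
  mc <- synth_match_config(duration_s = 60, rally_min_s = 60,
                           rally_meanlog = log(60),
                           truth = mixture_truth(0.9, 1e-3, 0.9, 1e-3, 1),
                           noise_density_g_per_rthz = 1e-9,
                           rest_amp_g = 1e-6, seed = 5)
  rec <- simulate_match(mc)
  idx <- acceleration_index(rec$trace)
  central <- mean(idx$values[3000:9000])
  expect_lt(abs(central - 0.9) / 0.9, 0.10)
})

test_that("the index is stable across sampling rates", {
  cfg <- run_config()
  idx200 <- acceleration_index(simulate_match(
    synth_match_config(sample_rate_hz = 200, duration_s = 120,
                       seed = 12))$trace, cfg)
  idx1000 <- acceleration_index(simulate_match(
    synth_match_config(sample_rate_hz = 1000, duration_s = 120,
                       seed = 12))$trace, cfg)
  # align by taking every 5th sample of the 1 kHz rendering
  a <- idx200$values
  b <- idx1000$values[seq(1, length(idx1000$values), by = 5)]
  stopifnot(length(a) == length(b))
  core <- 1000:(length(a) - 1000)
  rms_diff <- sqrt(mean((a[core] - b[core])^2)) / sqrt(mean(a[core]^2))
  expect_lt(rms_diff, 0.02)
})
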