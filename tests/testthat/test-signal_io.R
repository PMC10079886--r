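test_that("read_trace infers the rate from a regular time column", {
  path <- withr::local_tempfile(fileext = ".csv")
  n <- 50
  t <- (0:(n - 1)) * 0.005
  writeLines(c("t,ax,ay,az",
               sprintf("%.6f,%.3f,%.3f,%.3f", t, sin(t), cos(t), rep(1, n))),
             path)
  tr <- read_trace(path)
  expect_s3_class(tr, "accel_trace")
  expect_equal(tr$sample_rate_hz, 200, tolerance = 1e-3)
  expect_equal(n_samples(tr), n)
  expect_equal(tr$samples[, "az"], rep(1, n))
})

test_that("read_trace preserves 3-column files verbatim at a given rate", {
  path <- withr::local_tempfile(fileext = ".csv")
  m <- matrix(round(rnorm(30), 6), ncol = 3)
  writeLines(apply(m, 1, paste, collapse = ","), path)  # no header
  tr <- read_trace(path, sample_rate_hz = 1000)
  expect_equal(unname(tr$samples), m)
  expect_equal(tr$sample_rate_hz, 1000)
  # m/s^2 conversion divides by standard gravity
  tr2 <- read_trace(path, sample_rate_hz = 1000, input_unit = "ms2")
  expect_equal(unname(tr2$samples), m / 9.80665)
})

test_that("read_trace rejects bad files with informative errors", {
  # irregular timestamps
  p1 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("t,ax,ay,az", "0,0,0,1", "0.005,0,0,1", "0.505,0,0,1",
               "0.510,0,0,1"), p1)
  expect_error(read_trace(p1), class = "accelmix_sampling_error")
  # non-numeric row, named by line
  p2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("ax,ay,az", "0,0,1", "0,oops,1"), p2)
  expect_error(read_trace(p2, sample_rate_hz = 100), "line 3",
               class = "accelmix_parse_error")
  # empty file
  p3 <- withr::local_tempfile(fileext = ".csv")
  writeLines(character(0), p3)
  expect_error(read_trace(p3, sample_rate_hz = 100),
               class = "accelmix_input_error")
  # user rate conflicting with the time column
  p4 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("t,ax,ay,az", sprintf("%.4f,0,0,1", (0:49) / 100)), p4)
  expect_error(read_trace(p4, sample_rate_hz = 200),
               class = "accelmix_sampling_error")
  # missing rate for a 3-column file
  p5 <- withr::local_tempfile(fileext = ".csv")
  writeLines("0,0,1", p5)
  expect_error(read_trace(p5), class = "accelmix_input_error")
})

test_that("traces round-trip through write_trace/read_trace", {
  rec <- simulate_match(synth_match_config(sample_rate_hz = 50,
                                           duration_s = 30, seed = 8))
  path <- withr::local_tempfile(fileext = ".csv")
  write_trace(rec$trace, path)
  back <- read_trace(path)
  expect_equal(back$sample_rate_hz, rec$trace$sample_rate_hz,
               tolerance = 1e-3)
  expect_equal(back$samples, rec$trace$samples, tolerance = 1e-7)
})

test_that("interval sets round-trip losslessly, including empty sets", {
  iv <- interval_set(c("in_play", "rest", "in_play"),
                     c(0L, 1000L, 2500L), c(1000L, 2500L, 4000L),
                     4000L, 200, "m01")
  path <- withr::local_tempfile(fileext = ".csv")
  write_intervals(iv, path)
  back <- read_intervals(path)
  expect_identical(back$label, iv$label)
  expect_identical(back$start_index, iv$start_index)
  expect_identical(back$end_index, iv$end_index)
  expect_equal(back$start_s, iv$start_s)
  expect_equal(attr(back, "n_samples"), attr(iv, "n_samples"))

  empty <- interval_set(character(0), integer(0), integer(0), 0L, 200)
  write_intervals(empty, path)
  expect_identical(readLines(path),
                   "recording_id,label,start_index,end_index,start_s,end_s")
  expect_equal(nrow(read_intervals(path)), 0L)
})

test_that("single in-play interval writes one labeled row", {
  iv <- interval_set("in_play", 0L, 1000L, 1000L, 200, "m01")
  path <- withr::local_tempfile(fileext = ".csv")
  write_intervals(iv, path)
  rows <- readLines(path)
  expect_length(rows, 2L)
  expect_match(rows[2], "^m01,in_play,0,1000,")
})

test_that("feature tables round-trip bit-exactly", {
  tab <- make_feature_table(3)
  path <- withr::local_tempfile(fileext = ".csv")
  write_features(tab, path)
  back <- read_features(path)
  for (col in names(tab)) expect_identical(back[[col]], tab[[col]])
})

test_that("interval sets reject malformed structure", {
  expect_error(interval_set(c("in_play", "in_play"), c(0L, 10L),
                            c(10L, 20L), 20L, 100),
               class = "accelmix_input_error")   # same adjacent labels
  expect_error(interval_set(c("in_play", "rest"), c(0L, 12L),
                            c(10L, 20L), 20L, 100),
               class = "accelmix_input_error")   # gap
  expect_error(interval_set("rest", 0L, 0L, 0L, 100),
               class = "accelmix_input_error")   # empty interval
})

test_that("run configurations load from YAML and reject unknown keys", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("band_low_hz: 1.0", "rest_threshold_g: 0.25",
               "em_n_init: 3"), path)
  cfg <- read_run_config(path)
  expect_equal(cfg$band_low_hz, 1.0)
  expect_equal(cfg$rest_threshold_g, 0.25)
  expect_equal(cfg$em_n_init, 3L)
  expect_equal(cfg$band_high_hz, 20)   # untouched default

  writeLines("rest_treshold_g: 0.25", path)    # typo
  expect_error(read_run_config(path), class = "accelmix_config_error")
  expect_error(run_config(band_low_hz = 30, band_high_hz = 20),
               class = "accelmix_config_error")
})
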