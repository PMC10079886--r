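# Analytic magnitude response of the zero-phase (forward-backward)
# Butterworth band-pass, evaluated through the bilinear transform with
# prewarped band edges: for a digital frequency f at sampling rate fs the
# equivalent analog frequency is tan(pi * f / fs), and the band-pass built
# from an order-n low-pass prototype has
#   |H(jW)|^2 = 1 / (1 + ((W^2 - Wl*Wh) / (W * (Wh - Wl)))^(2n)).
# Forward-backward application squares the magnitude, so the net gain is
# |H|^2 itself.
butter_fb_gain <- function(f_hz, fs_hz, low_hz = 0.5, high_hz = 20,
                           order = 2) {
  W <- tan(pi * f_hz / fs_hz)
  Wl <- tan(pi * low_hz / fs_hz)
  Wh <- tan(pi * high_hz / fs_hz)
  u <- (W^2 - Wl * Wh) / (W * (Wh - Wl))
  1 / (1 + u^(2 * order))
}

# Brute-force centered moving mean with shrunken edge windows (loop form,
# independent of the cumulative-sum implementation under test).
naive_moving_average <- function(x, w) {
  h <- (w - 1) %/% 2
  n <- length(x)
  vapply(seq_len(n), function(i) {
    mean(x[max(1, i - h):min(n, i + h)])
  }, numeric(1))
}

# Brute-force rest labeling: scan runs of sub-threshold detector values and
# keep those at least min_len samples long.
naive_rest_labels <- function(detector, threshold, min_len) {
  below <- detector < threshold
  lab <- rep("in_play", length(below))
  r <- rle(below)
  stops <- cumsum(r$lengths)
  starts <- stops - r$lengths + 1
  for (k in seq_along(r$lengths)) {
    if (r$values[k] && r$lengths[k] >= min_len)
      lab[starts[k]:stops[k]] <- "rest"
  }
  lab
}

# Expand an interval_set into one label per sample.
labels_per_sample <- function(iv) {
  rep(iv$label, iv$end_index - iv$start_index)
}

# Sine-wave trace on a single axis.
tone_trace <- function(f_hz, fs_hz, dur_s, amp = 1) {
  t <- (seq_len(round(fs_hz * dur_s)) - 1) / fs_hz
  accel_trace(cbind(amp * sin(2 * pi * f_hz * t), 0, 0), fs_hz)
}

# Small valid feature table for io/feature tests.
make_feature_table <- function(n_per_group = 3, seed = 42) {
  withr_seed <- function(code) { set.seed(seed); code }
  withr_seed({
    k <- 2 * n_per_group
    feature_table(data.frame(
      recording_id = sprintf("rec%02d", seq_len(k)),
      group = rep(c("A", "B"), each = n_per_group),
      mu_low = runif(k, 0.2, 0.3), sigma_low = runif(k, 0.03, 0.08),
      mu_high = runif(k, 0.6, 1.0), sigma_high = runif(k, 0.1, 0.4),
      w_high = runif(k, 0.4, 0.8), mu_total = runif(k, 1.0, 1.4),
      stringsAsFactors = FALSE))
  })
}
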