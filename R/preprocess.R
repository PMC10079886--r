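#' Construct a single-channel time series
#'
#' @param values Numeric vector (G).
#' @param sample_rate_hz Sampling rate in Hz.
#' @param kind One of `"norm"`, `"acceleration_index"`, `"detector_signal"`.
#' @param recording_id Label inherited from the source trace.
#' @return A `scalar_series` object.
#' @export
scalar_series <- function(values, sample_rate_hz,
                          kind = c("norm", "acceleration_index",
                                   "detector_signal"),
                          recording_id = "recording") {
  kind <- match.arg(kind)
  values <- as.numeric(values)
  if (length(values) < 1L || !all(is.finite(values)))
    abort("series values must be a non-empty finite numeric vector",
          "accelmix_input_error")
  if (kind %in% c("norm", "acceleration_index") && any(values < 0))
    abort(sprintf("a '%s' series must be non-negative", kind),
          "accelmix_input_error")
  if (!is_scalar_num(sample_rate_hz) || sample_rate_hz <= 0)
    abort("sample_rate_hz must be a positive number", "accelmix_input_error")
  structure(list(values = values,
                 sample_rate_hz = as.numeric(sample_rate_hz),
                 kind = kind,
                 recording_id = as.character(recording_id)),
            class = "scalar_series")
}

#' @export
print.scalar_series <- function(x, ...) {
  cat(sprintf("<scalar_series:%s> '%s': %d samples @ %g Hz\n",
              x$kind, x$recording_id, length(x$values), x$sample_rate_hz))
  invisible(x)
}

# Steady-state initial filter state for a unit-amplitude step input
# (transposed direct-form II), so zero-phase filtering has no start-up
# transient on signals with a non-zero baseline.
lfilter_zi <- function(b, a) {
  n <- max(length(a), length(b))
  b <- c(b, rep(0, n - length(b)))
  a <- c(a, rep(0, n - length(a)))
  b <- b / a[1]
  a <- a / a[1]
  comp <- matrix(0, n - 1L, n - 1L)
  comp[1L, ] <- -a[-1L]
  if (n > 2L) comp[cbind(2:(n - 1L), 1:(n - 2L))] <- 1
  solve(diag(n - 1L) - t(comp), b[-1L] - a[-1L] * b[1L])
}

# Forward-backward IIR filtering with odd-reflection padding and matched
# initial conditions (the Gustafsson-free scheme used by MATLAB/SciPy
# filtfilt). Exactly zero phase; squared magnitude response.
zero_phase_filter <- function(b, a, x) {
  n <- length(x)
  nfilt <- max(length(a), length(b))
  pad <- 3L * (nfilt - 1L)
  if (n <= pad + 1L)
    abort("signal too short for zero-phase filtering", "accelmix_input_error")
  ext <- c(2 * x[1] - x[(pad + 1L):2L], x, 2 * x[n] - x[(n - 1L):(n - pad)])
  zi <- lfilter_zi(b, a)
  y <- lfilter_cpp(b, a, ext, zi * ext[1])
  y <- rev(lfilter_cpp(b, a, rev(y), zi * y[length(y)]))
  y[(pad + 1L):(pad + n)]
}

#' Band-pass filter a trace (zero phase)
#'
#' Applies a Butterworth band-pass (order `cfg$filter_order` per edge,
#' default corners 0.5--20 Hz) independently to each axis, forward and
#' backward so the net phase is zero and interval boundaries are not
#' shifted. The pass rejects DC, so the static gravity component is
#' attenuated to (numerically) zero.
#'
#' @param trace An `accel_trace`.
#' @param cfg A [run_config()].
#' @return A filtered `accel_trace` of identical length.
#' @export
bandpass_filter <- function(trace, cfg = run_config()) {
  stopifnot(inherits(trace, "accel_trace"))
  validate_run_config(cfg)
  nyq <- trace$sample_rate_hz / 2
  if (cfg$band_high_hz >= nyq)
    abort(sprintf("band_high_hz (%g) must be below the Nyquist frequency (%g)",
                  cfg$band_high_hz, nyq), "accelmix_config_error")
  n <- nrow(trace$samples)
  # warm-up guard: the slowest pole has time constant ~ 1/(2*pi*band_low)
  min_n <- ceiling(3 * trace$sample_rate_hz / (2 * pi * cfg$band_low_hz))
  if (n < min_n)
    abort(sprintf("trace too short to filter: %d samples < %d (3x the %g-Hz corner time constant)",
                  n, min_n, cfg$band_low_hz), "accelmix_input_error")
  bf <- signal::butter(cfg$filter_order,
                       c(cfg$band_low_hz, cfg$band_high_hz) / nyq,
                       type = "pass")
  filt <- vapply(1:3, function(j) zero_phase_filter(bf$b, bf$a, trace$samples[, j]),
                 numeric(n))
  if (n == 1L) filt <- matrix(filt, nrow = 1L)
  accel_trace(filt, trace$sample_rate_hz, trace$recording_id)
}

#' Euclidean norm of a tri-axial trace
#'
#' @param trace An `accel_trace` (raw or filtered).
#' @return A `scalar_series` of kind `"norm"` with
#'   `sqrt(ax^2 + ay^2 + az^2)` per sample.
#' @examples
#' vector_norm(accel_trace(cbind(3, 4, 0), 200))$values  # 5
#' @export
vector_norm <- function(trace) {
  stopifnot(inherits(trace, "accel_trace"))
  scalar_series(sqrt(rowSums(trace$samples^2)), trace$sample_rate_hz,
                kind = "norm", recording_id = trace$recording_id)
}

#' Centered moving average with shrunken edge windows
#'
#' The window length is `round(window_s * sample_rate_hz)` samples, forced
#' odd so the window is symmetric about each sample. Near the edges the mean
#' is taken over the available samples only (no padding, no fabricated
#' values), so the output has the same length as the input.
#'
#' @param series A `scalar_series`.
#' @param window_s Window length in seconds.
#' @param kind Kind of the returned series; defaults to the input kind.
#' @return A `scalar_series` of the same length.
#' @export
moving_average <- function(series, window_s, kind = NULL) {
  stopifnot(inherits(series, "scalar_series"))
  if (!is_scalar_num(window_s) || window_s <= 0)
    abort("window_s must be a positive number", "accelmix_config_error")
  n <- length(series$values)
  w <- round(window_s * series$sample_rate_hz)
  if (w < 1) w <- 1L
  if (w %% 2 == 0) w <- w + 1L   # nearest odd, for a symmetric window
  if (w > n)
    abort(sprintf("window (%d samples) exceeds series length (%d)", w, n),
          "accelmix_input_error")
  h <- (w - 1L) %/% 2L
  cs <- c(0, cumsum(series$values))
  i <- seq_len(n)
  lo <- pmax(i - h, 1L)
  hi <- pmin(i + h, n)
  out <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  # cumsum round-off can push an all-positive series epsilon-negative
  if (series$kind %in% c("norm", "acceleration_index")) out <- pmax(out, 0)
  scalar_series(out, series$sample_rate_hz,
                kind = if (is.null(kind)) series$kind else kind,
                recording_id = series$recording_id)
}

#' Acceleration index of a raw trace
#'
#' The acceleration index is the 1-s centered moving average of the vector
#' norm of the band-pass-filtered trace: the pipeline's main signal, in G.
#'
#' @param trace An `accel_trace` of raw acceleration.
#' @param cfg A [run_config()].
#' @return A `scalar_series` of kind `"acceleration_index"`.
#' @export
acceleration_index <- function(trace, cfg = run_config()) {
  filtered <- bandpass_filter(trace, cfg)
  moving_average(vector_norm(filtered), cfg$index_window_s,
                 kind = "acceleration_index")
}
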