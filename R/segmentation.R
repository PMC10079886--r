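#' Construct a labeled interval set
#'
#' Intervals are 0-based, half-open `[start_index, end_index)` sample-index
#' ranges that must tile `[0, n_samples)` with alternating labels.
#'
#' @param labels Character vector of `"in_play"` / `"rest"` labels.
#' @param starts,ends Integer vectors of interval bounds (half-open).
#' @param n_samples Total sample count the set must tile.
#' @param sample_rate_hz Sampling rate, used to express bounds in seconds.
#' @param recording_id Label of the source recording.
#' @return An `interval_set`: a data frame with columns `recording_id`,
#'   `label`, `start_index`, `end_index`, `start_s`, `end_s`.
#' @export
interval_set <- function(labels, starts, ends, n_samples, sample_rate_hz,
                         recording_id = "recording") {
  k <- length(labels)
  if (length(starts) != k || length(ends) != k)
    abort("labels, starts and ends must have equal length",
          "accelmix_input_error")
  if (k > 0) {
    if (!all(labels %in% c("in_play", "rest")))
      abort("interval labels must be 'in_play' or 'rest'",
            "accelmix_input_error")
    if (any(ends <= starts))
      abort("intervals must be non-empty (end > start)",
            "accelmix_input_error")
    if (starts[1] != 0 || ends[k] != n_samples ||
        (k > 1 && any(starts[-1] != ends[-k])))
      abort("intervals must tile [0, n_samples) without gaps or overlaps",
            "accelmix_input_error")
    if (k > 1 && any(labels[-1] == labels[-k]))
      abort("adjacent intervals must have different labels",
            "accelmix_input_error")
  }
  df <- data.frame(recording_id = rep(as.character(recording_id), k),
                   label = as.character(labels),
                   start_index = as.integer(starts),
                   end_index = as.integer(ends),
                   start_s = starts / sample_rate_hz,
                   end_s = ends / sample_rate_hz,
                   stringsAsFactors = FALSE)
  structure(df, n_samples = as.integer(n_samples),
            sample_rate_hz = as.numeric(sample_rate_hz),
            class = c("interval_set", "data.frame"))
}

#' Segment a recording into rest and in-play intervals
#'
#' The detector signal is a second, 5-s (by default) centered moving average
#' of the acceleration index. Maximal runs where the detector is strictly
#' below `rest_threshold_g` and that last at least `rest_min_dur_s` become
#' rest intervals; every remaining sample is in-play. Sub-threshold dips
#' shorter than the minimum duration therefore merge into the surrounding
#' in-play bout, reflecting the assumption that genuinely low-intensity
#' movement within a rally is brief.
#'
#' @param index A `scalar_series` of kind `"acceleration_index"`.
#' @param cfg A [run_config()].
#' @return An [interval_set()] tiling the recording.
#' @export
detect_intervals <- function(index, cfg = run_config()) {
  stopifnot(inherits(index, "scalar_series"))
  if (index$kind != "acceleration_index")
    abort("detect_intervals expects an acceleration_index series",
          "accelmix_input_error")
  validate_run_config(cfg)
  detector <- moving_average(index, cfg$detector_window_s,
                             kind = "detector_signal")
  n <- length(index$values)
  below <- detector$values < cfg$rest_threshold_g   # strict: ties are in-play
  min_len <- cfg$rest_min_dur_s * index$sample_rate_hz
  r <- rle(below)
  is_rest <- r$values & (r$lengths >= min_len)
  lab <- rep(ifelse(is_rest, "rest", "in_play"), r$lengths)
  rr <- rle(lab)
  ends <- cumsum(rr$lengths)
  starts <- ends - rr$lengths
  interval_set(rr$values, starts, ends, n, index$sample_rate_hz,
               index$recording_id)
}

#' Pool the in-play acceleration-index samples
#'
#' @param index A `scalar_series` of kind `"acceleration_index"`.
#' @param intervals An [interval_set()] tiling the series.
#' @return Numeric vector: the index values inside in-play intervals, in
#'   temporal order.
#' @export
pool_in_play <- function(index, intervals) {
  stopifnot(inherits(index, "scalar_series"), inherits(intervals, "interval_set"))
  n <- length(index$values)
  if (attr(intervals, "n_samples") != n)
    abort(sprintf("interval set covers %d samples but the series has %d",
                  attr(intervals, "n_samples"), n), "accelmix_input_error")
  keep <- intervals$label == "in_play"
  idx <- unlist(mapply(function(s, e) seq.int(s + 1L, e),
                       intervals$start_index[keep], intervals$end_index[keep],
                       SIMPLIFY = FALSE), use.names = FALSE)
  index$values[idx]
}

in_play_indices <- function(intervals) {
  keep <- intervals$label == "in_play"
  unlist(mapply(function(s, e) seq.int(s + 1L, e),
                intervals$start_index[keep], intervals$end_index[keep],
                SIMPLIFY = FALSE), use.names = FALSE)
}

#' Write / read interval annotations
#'
#' CSV columns: `recording_id, label, start_index, end_index, start_s,
#' end_s`. Numeric fields are written with 17 significant digits so the pair
#' round-trips losslessly.
#'
#' @param intervals An [interval_set()].
#' @param path Output (or input) CSV path.
#' @return `write_intervals`: `path`, invisibly. `read_intervals`: an
#'   `interval_set`.
#' @export
write_intervals <- function(intervals, path) {
  stopifnot(inherits(intervals, "interval_set"))
  header <- "recording_id,label,start_index,end_index,start_s,end_s"
  rows <- character(0)
  if (nrow(intervals) > 0)
    rows <- sprintf("%s,%s,%d,%d,%.17g,%.17g",
                    intervals$recording_id, intervals$label,
                    intervals$start_index, intervals$end_index,
                    intervals$start_s, intervals$end_s)
  ok <- tryCatch({ writeLines(c(header, rows), path); TRUE },
                 error = function(e) FALSE)
  if (!ok) abort(sprintf("cannot write %s", path), "accelmix_io_error")
  invisible(path)
}

#' @rdname write_intervals
#' @export
read_intervals <- function(path) {
  if (!file.exists(path))
    abort(sprintf("interval file not found: %s", path), "accelmix_io_error")
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("recording_id", "label", "start_index", "end_index",
            "start_s", "end_s")
  if (!all(need %in% names(df)))
    abort("interval file is missing required columns", "accelmix_parse_error")
  if (nrow(df) == 0)
    return(interval_set(character(0), integer(0), integer(0), 0L, 1,
                        "recording"))
  rate <- df$end_index[nrow(df)] / df$end_s[nrow(df)]
  interval_set(df$label, df$start_index, df$end_index,
               df$end_index[nrow(df)], rate, df$recording_id[1])
}
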