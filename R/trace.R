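#' Construct a tri-axial acceleration trace
#'
#' @param samples Numeric matrix (or 3-column data frame) of per-sample
#'   accelerations in G, columns `ax`, `ay`, `az`.
#' @param sample_rate_hz Sampling rate in Hz (positive).
#' @param recording_id Label carried through the pipeline outputs.
#' @return An `accel_trace`: a list with `samples` (n x 3 matrix),
#'   `sample_rate_hz` and `recording_id`.
#' @examples
#' tr <- accel_trace(cbind(0, 0, rep(1, 100)), 200)
#' n_samples(tr)
#' @export
accel_trace <- function(samples, sample_rate_hz, recording_id = "recording") {
  samples <- as.matrix(samples)
  if (ncol(samples) != 3L)
    abort("trace samples must have exactly 3 columns (ax, ay, az)",
          "accelmix_input_error")
  storage.mode(samples) <- "double"
  if (nrow(samples) < 1L)
    abort("trace must contain at least one sample", "accelmix_input_error")
  if (!all(is.finite(samples)))
    abort("trace contains non-finite sample values", "accelmix_input_error")
  if (!is_scalar_num(sample_rate_hz) || sample_rate_hz <= 0)
    abort("sample_rate_hz must be a positive number", "accelmix_input_error")
  colnames(samples) <- c("ax", "ay", "az")
  structure(
    list(samples = samples,
         sample_rate_hz = as.numeric(sample_rate_hz),
         recording_id = as.character(recording_id)),
    class = "accel_trace"
  )
}

#' @export
print.accel_trace <- function(x, ...) {
  cat(sprintf("<accel_trace> '%s': %d samples @ %g Hz (%.1f s)\n",
              x$recording_id, nrow(x$samples), x$sample_rate_hz,
              nrow(x$samples) / x$sample_rate_hz))
  invisible(x)
}

#' Number of samples in a trace or series
#' @param x An `accel_trace` or `scalar_series`.
#' @return Integer sample count.
#' @export
n_samples <- function(x) {
  if (inherits(x, "accel_trace")) nrow(x$samples)
  else if (inherits(x, "scalar_series")) length(x$values)
  else abort("n_samples: unsupported object", "accelmix_input_error")
}

STANDARD_GRAVITY <- 9.80665  # m/s^2 per G

#' Read a tri-axial trace from delimited text
#'
#' Accepts 3 numeric columns (`ax, ay, az`) or 4 (`t, ax, ay, az`); a header
#' row is detected automatically. When a time column is present the sample
#' rate is inferred from the median inter-sample spacing; irregular spacing
#' (any gap deviating more than 5% from the median) is an error, as is a
#' user-supplied rate disagreeing with the inferred one by more than 1%.
#' The duration-based rest rule makes a silently wrong rate corrosive, so
#' mismatches are never downgraded to warnings.
#'
#' @param path Path to a comma/whitespace-delimited text file.
#' @param sample_rate_hz Sampling rate in Hz; required when the file has no
#'   time column, optional (cross-checked) otherwise.
#' @param recording_id Label for the trace; defaults to the file name.
#' @param input_unit `"g"` or `"ms2"`; `"ms2"` values are divided by 9.80665.
#' @return An `accel_trace`.
#' @export
read_trace <- function(path, sample_rate_hz = NULL,
                       recording_id = NULL,
                       input_unit = c("g", "ms2")) {
  input_unit <- match.arg(input_unit)
  if (!file.exists(path))
    abort(sprintf("trace file not found: %s", path), "accelmix_io_error")
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L)
    abort(sprintf("trace file is empty: %s", path), "accelmix_input_error")

  split_row <- function(s) strsplit(trimws(s), "[,;\t ]+")[[1]]
  first <- split_row(lines[[1]])
  has_header <- anyNA(suppressWarnings(as.numeric(first)))
  data_lines <- if (has_header) lines[-1] else lines
  line_offset <- if (has_header) 1L else 0L
  if (length(data_lines) == 0L)
    abort(sprintf("trace file has a header but no data rows: %s", path),
          "accelmix_input_error")

  fields <- lapply(data_lines, split_row)
  ncols <- lengths(fields)
  if (any(ncols != ncols[1]))
    abort(sprintf("ragged rows in %s (line %d)", path,
                  which(ncols != ncols[1])[1] + line_offset),
          "accelmix_parse_error")
  if (!ncols[1] %in% c(3L, 4L))
    abort(sprintf("expected 3 (ax,ay,az) or 4 (t,ax,ay,az) columns, got %d",
                  ncols[1]), "accelmix_input_error")

  mat <- suppressWarnings(
    matrix(as.numeric(unlist(fields)), ncol = ncols[1], byrow = TRUE))
  if (anyNA(mat)) {
    bad <- which(rowSums(is.na(mat)) > 0)[1]
    abort(sprintf("non-numeric value in %s at line %d", path,
                  bad + line_offset), "accelmix_parse_error")
  }

  if (ncols[1] == 4L) {
    t <- mat[, 1]
    if (length(t) < 2L)
      abort("cannot infer a sample rate from a single timestamp",
            "accelmix_sampling_error")
    dt <- diff(t)
    med <- median(dt)
    if (med <= 0 || any(abs(dt - med) > 0.05 * med))
      abort(sprintf("irregular timestamp spacing in %s (max deviation %.3g%% of median)",
                    path, 100 * max(abs(dt - med)) / med),
            "accelmix_sampling_error")
    inferred <- 1 / med
    if (!is.null(sample_rate_hz) &&
        abs(inferred - sample_rate_hz) > 0.01 * sample_rate_hz)
      abort(sprintf("time column implies %.4g Hz but %.4g Hz was specified",
                    inferred, sample_rate_hz), "accelmix_sampling_error")
    sample_rate_hz <- inferred
    acc <- mat[, 2:4, drop = FALSE]
  } else {
    if (is.null(sample_rate_hz))
      abort("sample_rate_hz is required for files without a time column",
            "accelmix_input_error")
    acc <- mat
  }
  if (input_unit == "ms2") acc <- acc / STANDARD_GRAVITY
  if (is.null(recording_id))
    recording_id <- tools::file_path_sans_ext(basename(path))
  accel_trace(acc, sample_rate_hz, recording_id)
}

#' Write a trace as delimited text
#'
#' Writes a CSV with columns `t, ax, ay, az` (or without `t`); the time
#' column is generated from the sample rate so the file round-trips through
#' [read_trace()].
#'
#' @param trace An `accel_trace`.
#' @param path Output path.
#' @param include_time Write the time column (default TRUE).
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path, include_time = TRUE) {
  stopifnot(inherits(trace, "accel_trace"))
  n <- nrow(trace$samples)
  acc <- apply(trace$samples, 2, function(col) sprintf("%.9g", col))
  if (n == 1L) acc <- matrix(acc, nrow = 1)
  if (include_time) {
    t <- sprintf("%.10g", (seq_len(n) - 1) / trace$sample_rate_hz)
    body <- cbind(t, acc)
    header <- "t,ax,ay,az"
  } else {
    body <- acc
    header <- "ax,ay,az"
  }
  ok <- tryCatch({
    writeLines(c(header, apply(body, 1, paste, collapse = ",")), path)
    TRUE
  }, error = function(e) FALSE)
  if (!ok) abort(sprintf("cannot write %s", path), "accelmix_io_error")
  invisible(path)
}
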