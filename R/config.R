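#' Run configuration for the load-profiling pipeline
#'
#' Bundles every tunable constant of the analysis chain. The defaults encode
#' the published processing choices: a second-order Butterworth band-pass at
#' 0.5--20 Hz, a 1-s smoothing window for the acceleration index, a 5-s
#' smoothing window for the rest detector, and the rest rule "below 0.3 G for
#' at least 5 s".
#'
#' @param band_low_hz,band_high_hz Band-pass corner frequencies in Hz.
#' @param filter_order Butterworth prototype order (2 = the standard
#'   "second-order band-pass", an order-4 recursion after transformation).
#' @param index_window_s Moving-average window, in seconds, applied to the
#'   filtered norm to form the acceleration index.
#' @param detector_window_s Second moving-average window, in seconds, applied
#'   to the acceleration index to form the rest detector signal.
#' @param rest_threshold_g Rest threshold in G; samples whose detector value
#'   is strictly below it are candidate rest.
#' @param rest_min_dur_s Minimum duration, in seconds, a sub-threshold run
#'   must last to count as a rest interval.
#' @param em_tol EM convergence tolerance on the change in mean per-sample
#'   log-likelihood between iterations.
#' @param em_max_iter Maximum EM iterations per initialization.
#' @param em_n_init Number of EM initializations; the fit with the highest
#'   final log-likelihood is kept.
#' @param em_seed Integer seed driving the random EM initializations.
#' @param em_min_samples Minimum pooled sample count required for a fit.
#' @param var_floor Variance floor (G^2) guarding against singular
#'   components.
#' @param input_unit Unit of raw trace files: `"g"` (default) or `"ms2"`
#'   (converted to G by dividing by 9.80665 on read).
#' @param mu_total_scope Window for the conventional raw-norm mean:
#'   `"in_play"` (default; same exposure window as the mixture features) or
#'   `"recording"` (whole recording).
#'
#' @return An object of class `run_config` (a validated list).
#' @examples
#' cfg <- run_config()
#' cfg$rest_threshold_g
#' @export
run_config <- function(band_low_hz = 0.5,
                       band_high_hz = 20,
                       filter_order = 2L,
                       index_window_s = 1,
                       detector_window_s = 5,
                       rest_threshold_g = 0.3,
                       rest_min_dur_s = 5,
                       em_tol = 1e-8,
                       em_max_iter = 500L,
                       em_n_init = 10L,
                       em_seed = 1L,
                       em_min_samples = 100L,
                       var_floor = 1e-6,
                       input_unit = c("g", "ms2"),
                       mu_total_scope = c("in_play", "recording")) {
  input_unit <- match.arg(input_unit)
  mu_total_scope <- match.arg(mu_total_scope)
  cfg <- list(
    band_low_hz = as.numeric(band_low_hz),
    band_high_hz = as.numeric(band_high_hz),
    filter_order = as.integer(filter_order),
    index_window_s = as.numeric(index_window_s),
    detector_window_s = as.numeric(detector_window_s),
    rest_threshold_g = as.numeric(rest_threshold_g),
    rest_min_dur_s = as.numeric(rest_min_dur_s),
    em_tol = as.numeric(em_tol),
    em_max_iter = as.integer(em_max_iter),
    em_n_init = as.integer(em_n_init),
    em_seed = as.integer(em_seed),
    em_min_samples = as.integer(em_min_samples),
    var_floor = as.numeric(var_floor),
    input_unit = input_unit,
    mu_total_scope = mu_total_scope
  )
  validate_run_config(cfg)
  structure(cfg, class = "run_config")
}

validate_run_config <- function(cfg) {
  with(cfg, {
    if (!is_scalar_num(band_low_hz) || !is_scalar_num(band_high_hz) ||
        band_low_hz <= 0 || band_low_hz >= band_high_hz)
      abort("need 0 < band_low_hz < band_high_hz", "accelmix_config_error")
    if (filter_order < 1L)
      abort("filter_order must be >= 1", "accelmix_config_error")
    for (nm in c("index_window_s", "detector_window_s", "rest_threshold_g",
                 "rest_min_dur_s", "em_tol", "var_floor")) {
      v <- get(nm)
      if (!is_scalar_num(v) || v <= 0)
        abort(sprintf("%s must be a positive number", nm),
              "accelmix_config_error")
    }
    if (em_max_iter < 1L || em_n_init < 1L || em_min_samples < 2L)
      abort("EM iteration/initialization counts must be positive",
            "accelmix_config_error")
  })
  invisible(cfg)
}

#' Read a run configuration from a YAML file
#'
#' Unknown keys are rejected so a typo cannot silently fall back to a
#' default.
#'
#' @param path Path to a YAML file whose keys mirror [run_config()]
#'   arguments.
#' @return A `run_config` object.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path))
    abort(sprintf("config file not found: %s", path), "accelmix_io_error")
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  known <- names(formals(run_config))
  bad <- setdiff(names(vals), known)
  if (length(bad) > 0)
    abort(sprintf("unknown config field(s): %s", paste(bad, collapse = ", ")),
          "accelmix_config_error")
  do.call(run_config, vals)
}

#' @export
print.run_config <- function(x, ...) {
  cat("<run_config>\n")
  cat(sprintf("  band-pass: %g-%g Hz (Butterworth order %d, zero phase)\n",
              x$band_low_hz, x$band_high_hz, x$filter_order))
  cat(sprintf("  index window: %g s; detector window: %g s\n",
              x$index_window_s, x$detector_window_s))
  cat(sprintf("  rest rule: detector < %g G for >= %g s\n",
              x$rest_threshold_g, x$rest_min_dur_s))
  cat(sprintf("  EM: %d init(s), tol %g, max %d iter, seed %d\n",
              x$em_n_init, x$em_tol, x$em_max_iter, x$em_seed))
  invisible(x)
}
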