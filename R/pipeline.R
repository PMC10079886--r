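#' Run the full load-profiling pipeline on one recording
#'
#' Chains the stages: acceleration index, rest/in-play segmentation,
#' in-play pooling, mixture fit and conventional mean.
#'
#' @param trace A raw `accel_trace`.
#' @param cfg A [run_config()].
#' @param group Optional group label attached to the feature row.
#' @return A list: `index` (`scalar_series`), `intervals`
#'   ([interval_set()]), `pool` (numeric vector), `fit` (`mixture_fit`),
#'   `mu_total`, and `features` (a one-row [feature_table()]).
#' @examples
#' rec <- simulate_match(synth_match_config(duration_s = 120, seed = 3))
#' res <- process_recording(rec$trace)
#' res$features
#' @export
process_recording <- function(trace, cfg = run_config(), group = "ungrouped") {
  index <- acceleration_index(trace, cfg)
  intervals <- detect_intervals(index, cfg)
  pool <- pool_in_play(index, intervals)
  if (length(pool) < cfg$em_min_samples)
    abort(sprintf("recording '%s': only %d in-play samples (need %d)",
                  trace$recording_id, length(pool), cfg$em_min_samples),
          "accelmix_insufficient_data_error")
  fit <- fit_gmm_em(pool, cfg)
  mu_total <- conventional_mean(trace, intervals, cfg)
  features <- feature_table(data.frame(
    recording_id = trace$recording_id, group = group,
    mu_low = fit$mu_low, sigma_low = fit$sigma_low,
    mu_high = fit$mu_high, sigma_high = fit$sigma_high,
    w_high = fit$w_high, mu_total = mu_total,
    stringsAsFactors = FALSE))
  list(index = index, intervals = intervals, pool = pool, fit = fit,
       mu_total = mu_total, features = features)
}
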