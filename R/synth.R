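#' True mixture parameters for synthetic data
#'
#' Defaults place the low-intensity peak at 0.25 G and the high-intensity
#' peak at 0.9 G with 60% high-side mass -- the intensity structure typical
#' of competitive racket-sport play, where the low mode corresponds to
#' walking-level movement and the high mode to ball-chasing and strokes.
#'
#' @param mu_low,sigma_low Low-component mean and SD (G).
#' @param mu_high,sigma_high High-component mean and SD (G).
#' @param w_high High-component mixing weight in `[0, 1]`.
#' @return A `mixture_truth` list.
#' @export
mixture_truth <- function(mu_low = 0.25, sigma_low = 0.05,
                          mu_high = 0.90, sigma_high = 0.30,
                          w_high = 0.6) {
  if (sigma_low <= 0 || sigma_high <= 0)
    abort("component standard deviations must be positive",
          "accelmix_domain_error")
  if (w_high < 0 || w_high > 1)
    abort("w_high must lie in [0, 1]", "accelmix_domain_error")
  if (mu_low > mu_high)
    abort("mu_low must not exceed mu_high", "accelmix_domain_error")
  structure(list(mu_low = mu_low, sigma_low = sigma_low,
                 mu_high = mu_high, sigma_high = sigma_high,
                 w_high = w_high),
            class = "mixture_truth")
}

# Draw n values from the truth mixture, truncated at 0 by redrawing.
draw_mixture <- function(truth, n, force_high = FALSE) {
  if (n == 0) return(numeric(0))
  comp_high <- if (force_high) rep(TRUE, n) else runif(n) < truth$w_high
  x <- rnorm(n,
             mean = ifelse(comp_high, truth$mu_high, truth$mu_low),
             sd = ifelse(comp_high, truth$sigma_high, truth$sigma_low))
  while (any(neg <- x < 0)) {
    x[neg] <- rnorm(sum(neg),
                    mean = ifelse(comp_high[neg], truth$mu_high, truth$mu_low),
                    sd = ifelse(comp_high[neg], truth$sigma_high,
                                truth$sigma_low))
  }
  x
}

#' Draw an annotated sample pool from a mixture
#'
#' Each draw picks the high component with probability `w_high`, then draws
#' from the selected normal; negative draws are replaced (truncation at 0,
#' since the acceleration index is non-negative).
#'
#' @param truth A [mixture_truth()].
#' @param n Number of draws.
#' @param seed Optional integer seed (the caller's RNG state is preserved).
#' @return A list with `samples` (numeric vector) and `truth`.
#' @export
sample_mixture_pool <- function(truth, n, seed = NULL) {
  stopifnot(inherits(truth, "mixture_truth"))
  if (!is_scalar_num(n) || n < 1)
    abort("n must be a positive integer", "accelmix_input_error")
  samples <- with_seed(seed, draw_mixture(truth, as.integer(n)))
  list(samples = samples, truth = truth)
}

# Amplitude-modulated |sin| averaged over a window is amplitude * 2/pi;
# the generator scales carrier amplitudes by its inverse so a target
# intensity level maps one-to-one onto the acceleration index.
#' Carrier-amplitude-to-index calibration constant
#'
#' The 1-s moving average of the rectified norm of a sinusoidal carrier of
#' amplitude `A` is `A * 2 / pi`; [simulate_match()] therefore renders a
#' target index level `L` with carrier amplitude `L * pi / 2`. Exposed so
#' tests can verify the calibration analytically.
#' @return `2 / pi`.
#' @export
carrier_index_gain <- function() 2 / pi

#' Configuration of a synthetic match recording
#'
#' Emulates the bout structure of a competitive match: rallies (in-play)
#' alternating with rest periods. Within a rally a two-state component
#' process (low/high intensity, exponential dwells of mean `dwell_mean_s`)
#' selects which mixture component the target level tracks, and within a
#' component the level follows an Ornstein-Uhlenbeck fluctuation (time
#' constant `level_tau_s`, micro-grid `micro_dt_s`) whose stationary
#' marginal is exactly that component's normal -- so the time-marginal of
#' the in-play intensity is the truth mixture. The level is rendered as an
#' amplitude-modulated carrier inside the analysis passband. Rally and rest
#' durations are log-normal with floors; the defaults (median 35 s each)
#' represent game-scale alternation. Consecutive low-component time is
#' capped (`low_dwell_cap_s`) and the first/last `boundary_high_s` seconds
#' of a rally are forced to the high component, encoding the assumption
#' that rallies open and close with a stroke and that genuinely
#' low-intensity in-play movement is brief.
#'
#' @param sample_rate_hz Rendering rate in Hz.
#' @param duration_s Recording length in seconds.
#' @param truth A [mixture_truth()]: the in-play intensity mixture.
#' @param rally_meanlog,rally_sdlog,rally_min_s Log-normal rally-duration
#'   parameters and floor (s).
#' @param rest_meanlog,rest_sdlog,rest_min_s Log-normal rest-duration
#'   parameters and floor (s); the floor keeps quiet gaps recoverable by the
#'   5-s rest rule.
#' @param dwell_mean_s Mean of the exponential dwell time of the low/high
#'   component process within a rally (s).
#' @param level_tau_s Correlation time of the within-component
#'   Ornstein-Uhlenbeck level fluctuation (s).
#' @param micro_dt_s Micro-grid step for rendering the level process (s);
#'   continuous-time, so independent of the sampling rate.
#' @param low_dwell_cap_s Maximum consecutive in-play time in the low
#'   component before a high-component dwell is forced (s).
#' @param boundary_high_s Rally head/tail length forced to the high
#'   component (s).
#' @param carrier_band_hz Length-2 range the per-rally carrier frequency is
#'   drawn from (Hz); must sit inside the analysis passband.
#' @param rest_amp_g Target index level during rest (G); must stay below
#'   `rest_threshold_g` or ground truth becomes unrecoverable (a warning is
#'   raised).
#' @param noise_density_g_per_rthz White sensor-noise amplitude spectral
#'   density (G per sqrt(Hz)); the per-sample SD is
#'   `noise_density * sqrt(rate / 2)`, so in-band noise power does not
#'   depend on the sampling rate.
#' @param gravity_g Length-3 static gravity offset added to the axes (G).
#' @param bias_g Length-3 static sensor offset (G) added to the axes, e.g.
#'   accelerometer bias or posture-dependent baseline; removed by the
#'   band-pass filter but inherited by the raw-norm conventional mean.
#' @param rest_threshold_g Rest threshold the generator assumes when capping
#'   low dwells and checking `rest_amp_g` consistency.
#' @param seed Integer seed; the same seed reproduces the match exactly, and
#'   the same seed at a different `sample_rate_hz` renders the same
#'   underlying motion.
#' @return A `synth_match_config` list.
#' @export
synth_match_config <- function(sample_rate_hz = 200,
                               duration_s = 600,
                               truth = mixture_truth(),
                               rally_meanlog = log(35), rally_sdlog = 0.35,
                               rally_min_s = 10,
                               rest_meanlog = log(35), rest_sdlog = 0.30,
                               rest_min_s = 8,
                               dwell_mean_s = 4,
                               level_tau_s = 1.5,
                               micro_dt_s = 0.25,
                               low_dwell_cap_s = 2.5,
                               boundary_high_s = 3,
                               carrier_band_hz = c(3, 6),
                               rest_amp_g = 0.05,
                               noise_density_g_per_rthz = 0.002,
                               gravity_g = c(0, 0, 1),
                               bias_g = c(0, 0, 0),
                               rest_threshold_g = 0.3,
                               seed = 1L) {
  cfg <- list(sample_rate_hz = sample_rate_hz, duration_s = duration_s,
              truth = truth,
              rally_meanlog = rally_meanlog, rally_sdlog = rally_sdlog,
              rally_min_s = rally_min_s,
              rest_meanlog = rest_meanlog, rest_sdlog = rest_sdlog,
              rest_min_s = rest_min_s,
              dwell_mean_s = dwell_mean_s,
              level_tau_s = level_tau_s,
              micro_dt_s = micro_dt_s,
              low_dwell_cap_s = low_dwell_cap_s,
              boundary_high_s = boundary_high_s,
              carrier_band_hz = as.numeric(carrier_band_hz),
              rest_amp_g = rest_amp_g,
              noise_density_g_per_rthz = noise_density_g_per_rthz,
              gravity_g = as.numeric(gravity_g),
              bias_g = as.numeric(bias_g),
              rest_threshold_g = rest_threshold_g,
              seed = as.integer(seed))
  if (!inherits(truth, "mixture_truth"))
    abort("truth must be a mixture_truth object", "accelmix_config_error")
  for (nm in c("sample_rate_hz", "duration_s", "rally_min_s", "rest_min_s",
               "dwell_mean_s", "level_tau_s", "micro_dt_s",
               "low_dwell_cap_s", "rest_amp_g", "rest_threshold_g"))
    if (!is_scalar_num(cfg[[nm]]) || cfg[[nm]] <= 0)
      abort(sprintf("%s must be a positive number", nm),
            "accelmix_config_error")
  if (length(cfg$carrier_band_hz) != 2 || any(cfg$carrier_band_hz <= 0) ||
      diff(cfg$carrier_band_hz) < 0)
    abort("carrier_band_hz must be an increasing positive pair",
          "accelmix_config_error")
  if (length(cfg$gravity_g) != 3 || length(cfg$bias_g) != 3)
    abort("gravity_g and bias_g must have length 3", "accelmix_config_error")
  if (cfg$rest_amp_g >= cfg$rest_threshold_g)
    warning("rest_amp_g >= rest_threshold_g: ground-truth rest intervals ",
            "will not be recoverable", call. = FALSE)
  structure(cfg, class = "synth_match_config")
}

# Alternating bout schedule (continuous time). The tail shorter than 5 s is
# absorbed into the final drawn bout so truth intervals never end in a
# sliver that the duration-based rest rule could not recover.
draw_bouts <- function(cfg) {
  t <- 0
  labels <- character(0)
  durs <- numeric(0)
  label <- "in_play"
  while (t < cfg$duration_s) {
    d <- if (label == "in_play")
      max(rlnorm(1, cfg$rally_meanlog, cfg$rally_sdlog), cfg$rally_min_s)
    else
      max(rlnorm(1, cfg$rest_meanlog, cfg$rest_sdlog), cfg$rest_min_s)
    if (t + d > cfg$duration_s - 5) d <- cfg$duration_s - t
    labels <- c(labels, label)
    durs <- c(durs, d)
    t <- t + d
    label <- if (label == "in_play") "rest" else "in_play"
  }
  data.frame(label = labels, start = cumsum(c(0, durs[-length(durs)])),
             end = cumsum(durs))
}

# Intensity schedule for one rally (continuous time). A two-state
# component process (low/high, exponential dwells) selects which normal the
# target level tracks; within a component the level follows a discretised
# Ornstein-Uhlenbeck chain on a fixed micro-grid, whose stationary marginal
# is exactly the component's normal. So the time-marginal of the rendered
# level is the truth mixture, while the signal fluctuates continuously the
# way genuine play does. Consecutive low-component time is capped and the
# rally head/tail are forced high (rallies open and close with a stroke).
draw_rally_levels <- function(start, end, cfg) {
  dt <- cfg$micro_dt_s
  phi <- exp(-dt / cfg$level_tau_s)
  innov_sd <- sqrt(1 - phi^2)
  t <- start
  low_run <- 0
  state <- NA_real_           # standardised OU state, N(0,1) stationary
  comp_high <- TRUE
  seg_start <- numeric(0); seg_end <- numeric(0); seg_level <- numeric(0)
  first <- TRUE
  while (t < end) {
    force_high <- first || (end - t <= cfg$boundary_high_s) ||
      (t - start < cfg$boundary_high_s) ||
      (low_run >= cfg$low_dwell_cap_s)
    new_high <- if (force_high) TRUE else runif(1) < cfg$truth$w_high
    if (is.na(state) || new_high != comp_high) state <- rnorm(1)
    comp_high <- new_high
    d <- rexp(1, rate = 1 / cfg$dwell_mean_s)
    if (!comp_high) {
      d <- min(d, cfg$low_dwell_cap_s - low_run)
      low_run <- low_run + d
    } else {
      low_run <- 0
    }
    d <- min(max(d, dt), end - t)
    mu <- if (comp_high) cfg$truth$mu_high else cfg$truth$mu_low
    sg <- if (comp_high) cfg$truth$sigma_high else cfg$truth$sigma_low
    n_micro <- max(1L, ceiling(d / dt - 1e-9))
    for (k in seq_len(n_micro)) {
      s0 <- t + (k - 1) * dt
      s1 <- min(t + k * dt, end)
      if (s1 <= s0) break
      seg_start <- c(seg_start, s0)
      seg_end <- c(seg_end, s1)
      seg_level <- c(seg_level, max(mu + sg * state, 0))
      state <- phi * state + innov_sd * rnorm(1)
    }
    t <- t + n_micro * dt
    first <- FALSE
  }
  data.frame(start = seg_start, end = pmin(seg_end, end), level = seg_level)
}

#' Simulate a synthetic match recording with ground truth
#'
#' Renders the bout/intensity structure described in
#' [synth_match_config()] as a raw tri-axial trace: within rallies the
#' target intensity is an amplitude-modulated sinusoidal carrier on the x
#' axis (amplitude `level * pi / 2`, so the pipeline's acceleration index
#' tracks the level; see [carrier_index_gain()]); rest bouts carry a small
#' residual sway; all axes receive white sensor noise and a static gravity
#' offset. All structural randomness (bouts, dwell times, levels, carrier
#' phases) is drawn before any per-sample noise, so the same seed rendered
#' at two sampling rates yields the same underlying motion.
#'
#' @param config A [synth_match_config()].
#' @param recording_id Label for the generated trace.
#' @return A list: `trace` (raw `accel_trace`), `intervals` (ground-truth
#'   [interval_set()]), `truth` (the [mixture_truth()]), `bouts`
#'   (continuous-time bout table).
#' @export
simulate_match <- function(config, recording_id = "synthetic_match") {
  stopifnot(inherits(config, "synth_match_config"))
  with_seed(config$seed, {
    bouts <- draw_bouts(config)
    # per-bout carriers and per-rally intensity schedules (rate-independent)
    bouts$carrier_hz <- runif(nrow(bouts), config$carrier_band_hz[1],
                              config$carrier_band_hz[2])
    bouts$phase <- runif(nrow(bouts), 0, 2 * pi)
    schedules <- lapply(seq_len(nrow(bouts)), function(i) {
      if (bouts$label[i] == "in_play")
        draw_rally_levels(bouts$start[i], bouts$end[i], config)
      else
        data.frame(start = bouts$start[i], end = bouts$end[i],
                   level = config$rest_amp_g)
    })

    fs <- config$sample_rate_hz
    n <- round(config$duration_s * fs)
    tt <- (seq_len(n) - 1) / fs
    env <- numeric(n)
    carrier <- numeric(n)
    bnd_idx <- round(bouts$end * fs)
    bnd_idx[length(bnd_idx)] <- n
    starts_idx <- c(0L, bnd_idx[-length(bnd_idx)])
    for (i in seq_len(nrow(bouts))) {
      sel <- if (starts_idx[i] < bnd_idx[i])
        (starts_idx[i] + 1L):bnd_idx[i] else integer(0)
      if (length(sel) == 0) next
      carrier[sel] <- sin(2 * pi * bouts$carrier_hz[i] *
                            (tt[sel] - bouts$start[i]) + bouts$phase[i])
      sch <- schedules[[i]]
      for (k in seq_len(nrow(sch))) {
        a <- max(starts_idx[i], round(sch$start[k] * fs))
        b <- min(bnd_idx[i], if (k == nrow(sch)) bnd_idx[i]
                 else round(sch$end[k] * fs))
        if (b > a) env[(a + 1L):b] <- sch$level[k] * pi / 2
      }
    }
    noise_sd <- config$noise_density_g_per_rthz * sqrt(fs / 2)
    samples <- cbind(env * carrier + rnorm(n, 0, noise_sd),
                     rnorm(n, 0, noise_sd),
                     rnorm(n, 0, noise_sd))
    samples <- sweep(samples, 2, config$gravity_g + config$bias_g, `+`)
    trace <- accel_trace(samples, fs, recording_id)
    intervals <- interval_set(bouts$label, starts_idx, bnd_idx, n, fs,
                              recording_id)
    list(trace = trace, intervals = intervals, truth = config$truth,
         bouts = bouts)
  })
}

#' Configuration of a two-group synthetic cohort
#'
#' Each group is described by a template [synth_match_config()]; every
#' recording gets its own ground-truth mixture drawn around the template's
#' truth with the between-recording standard deviations in `between`,
#' emulating player-to-player variability. By default the two groups share
#' identical low-side behaviour and mixing-weight variability and differ
#' only in the high-intensity component (group A: 0.90/0.30 G, group B:
#' 0.70/0.20 G), mirroring populations whose low-intensity movement is
#' alike while high-intensity play separates them.
#'
#' @param template_a,template_b Per-group [synth_match_config()] templates.
#' @param n_per_group Recordings per group (>= 2).
#' @param group_labels Character pair naming the groups.
#' @param between Named list of between-recording SDs: truth jitter
#'   (`mu_low`, `sigma_low`, `mu_high`, `sigma_high`, `w_high`) plus
#'   `bias`, the per-axis SD of a per-recording static sensor offset.
#' @param seed Integer seed for the whole cohort.
#' @return A `synth_cohort_config` list.
#' @export
synth_cohort_config <- function(template_a = synth_match_config(
                                  sample_rate_hz = 50, duration_s = 150,
                                  truth = mixture_truth(0.25, 0.05, 0.90,
                                                        0.30, 0.6)),
                                template_b = synth_match_config(
                                  sample_rate_hz = 50, duration_s = 150,
                                  truth = mixture_truth(0.25, 0.05, 0.70,
                                                        0.20, 0.6)),
                                n_per_group = 20,
                                group_labels = c("A", "B"),
                                between = list(mu_low = 0.03,
                                               sigma_low = 0.008,
                                               mu_high = 0.06,
                                               sigma_high = 0.04,
                                               w_high = 0.12,
                                               bias = 0.07),
                                seed = 1L) {
  if (!inherits(template_a, "synth_match_config") ||
      !inherits(template_b, "synth_match_config"))
    abort("templates must be synth_match_config objects",
          "accelmix_config_error")
  if (!is_scalar_num(n_per_group) || n_per_group < 2)
    abort("n_per_group must be at least 2", "accelmix_config_error")
  if (length(group_labels) != 2 || group_labels[1] == group_labels[2])
    abort("group_labels must be two distinct labels", "accelmix_config_error")
  structure(list(templates = list(template_a, template_b),
                 n_per_group = as.integer(n_per_group),
                 group_labels = as.character(group_labels),
                 between = between,
                 seed = as.integer(seed)),
            class = "synth_cohort_config")
}

# Per-recording truth: template truth jittered by between-recording SDs,
# with truncations keeping parameters physical and the labeling convention
# (mu_low <= mu_high) intact.
jitter_truth <- function(truth, between) {
  mu_low <- max(rnorm(1, truth$mu_low, between$mu_low), 0.05)
  sigma_low <- max(rnorm(1, truth$sigma_low, between$sigma_low), 0.01)
  mu_high <- max(rnorm(1, truth$mu_high, between$mu_high), mu_low + 0.1)
  sigma_high <- max(rnorm(1, truth$sigma_high, between$sigma_high), 0.05)
  w_high <- min(max(rnorm(1, truth$w_high, between$w_high), 0.1), 0.9)
  mixture_truth(mu_low, sigma_low, mu_high, sigma_high, w_high)
}

#' Simulate a two-group cohort of synthetic matches
#'
#' @param config A [synth_cohort_config()].
#' @return A list: `recordings` (list of [simulate_match()] results, with
#'   `$group` added), `truth_features` (a [feature_table()] of per-recording
#'   ground-truth mixture parameters; `mu_total` is `NA`-free only for the
#'   mixture columns' purposes and is set to the truth mixture mean as a
#'   placeholder), and `config`.
#' @export
simulate_cohort <- function(config = synth_cohort_config()) {
  stopifnot(inherits(config, "synth_cohort_config"))
  n <- config$n_per_group
  with_seed(config$seed, {
    rec_seeds <- sample.int(.Machine$integer.max, 2L * n)
    truths <- list()
    rows <- list()
    recs <- list()
    idx <- 0L
    for (g in 1:2) {
      tmpl <- config$templates[[g]]
      for (i in seq_len(n)) {
        idx <- idx + 1L
        truth_i <- jitter_truth(tmpl$truth, config$between)
        cfg_i <- tmpl
        cfg_i$truth <- truth_i
        cfg_i$bias_g <- rnorm(3, 0, config$between$bias)
        cfg_i$seed <- rec_seeds[idx]
        id <- sprintf("%s_%02d", config$group_labels[g], i)
        rec <- simulate_match(cfg_i, recording_id = id)
        rec$group <- config$group_labels[g]
        recs[[idx]] <- rec
        rows[[idx]] <- data.frame(
          recording_id = id, group = config$group_labels[g],
          mu_low = truth_i$mu_low, sigma_low = truth_i$sigma_low,
          mu_high = truth_i$mu_high, sigma_high = truth_i$sigma_high,
          w_high = truth_i$w_high,
          mu_total = (1 - truth_i$w_high) * truth_i$mu_low +
            truth_i$w_high * truth_i$mu_high,
          stringsAsFactors = FALSE)
      }
    }
    list(recordings = recs,
         truth_features = feature_table(do.call(rbind, rows)),
         config = config)
  })
}
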