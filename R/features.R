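GMM_FEATURES <- c("mu_low", "sigma_low", "mu_high", "sigma_high", "w_high")
ALL_FEATURES <- c(GMM_FEATURES, "mu_total")

#' Construct a per-recording feature table
#'
#' @param df Data frame with columns `recording_id`, `group`, the five
#'   mixture features (`mu_low`, `sigma_low`, `mu_high`, `sigma_high`,
#'   `w_high`) and the conventional mean `mu_total`.
#' @param standardized Whether the columns are already z-scored.
#' @param column_means,column_sds Per-feature centering/scaling constants
#'   (stored when `standardized` is TRUE so the transform is invertible).
#' @return A `feature_table` (data frame subclass).
#' @export
feature_table <- function(df, standardized = FALSE,
                          column_means = NULL, column_sds = NULL) {
  need <- c("recording_id", "group", ALL_FEATURES)
  if (!all(need %in% names(df)))
    abort(sprintf("feature table is missing column(s): %s",
                  paste(setdiff(need, names(df)), collapse = ", ")),
          "accelmix_input_error")
  df <- as.data.frame(df)[need]
  df$recording_id <- as.character(df$recording_id)
  df$group <- as.character(df$group)
  for (f in ALL_FEATURES) {
    df[[f]] <- as.numeric(df[[f]])
    if (anyNA(df[[f]]))
      abort(sprintf("feature column '%s' contains missing values", f),
            "accelmix_input_error")
  }
  structure(df, standardized = isTRUE(standardized),
            column_means = column_means, column_sds = column_sds,
            class = c("feature_table", "data.frame"))
}

#' Conventional raw-norm mean
#'
#' The baseline external-load feature: the mean of the *unfiltered*
#' acceleration norm, by default restricted to in-play samples so the
#' conventional and mixture features see the same exposure window. Set
#' `cfg$mu_total_scope = "recording"` for a whole-recording mean.
#'
#' @param trace The raw `accel_trace`.
#' @param intervals The [interval_set()] for the recording.
#' @param cfg A [run_config()].
#' @return `mu_total` in G.
#' @export
conventional_mean <- function(trace, intervals, cfg = run_config()) {
  stopifnot(inherits(trace, "accel_trace"), inherits(intervals, "interval_set"))
  nrm <- vector_norm(trace)$values
  if (cfg$mu_total_scope == "recording") return(mean(nrm))
  idx <- in_play_indices(intervals)
  if (length(idx) == 0)
    abort("no in-play samples: cannot compute the conventional mean",
          "accelmix_insufficient_data_error")
  mean(nrm[idx])
}

#' Standardize feature columns (z-score)
#'
#' Each feature column is centered and scaled to mean 0, standard deviation
#' 1 over all rows (both groups pooled), using the n-1 (sample) standard
#' deviation. The centering and scaling constants are stored so
#' [unstandardize()] inverts the transform exactly.
#'
#' @param table A [feature_table()] with at least 2 rows.
#' @return The standardized `feature_table`.
#' @export
standardize <- function(table) {
  stopifnot(inherits(table, "feature_table"))
  if (nrow(table) < 2)
    abort("standardization needs at least 2 rows", "accelmix_input_error")
  mus <- vapply(ALL_FEATURES, function(f) mean(table[[f]]), numeric(1))
  sds <- vapply(ALL_FEATURES, function(f) sd(table[[f]]), numeric(1))
  if (any(sds == 0))
    abort(sprintf("constant feature column(s): %s",
                  paste(ALL_FEATURES[sds == 0], collapse = ", ")),
          "accelmix_degenerate_feature_error")
  out <- table
  for (f in ALL_FEATURES) out[[f]] <- (table[[f]] - mus[f]) / sds[f]
  feature_table(out, standardized = TRUE,
                column_means = mus, column_sds = sds)
}

#' Invert a standardization
#'
#' @param table A standardized [feature_table()].
#' @return The table on its original scale.
#' @export
unstandardize <- function(table) {
  stopifnot(inherits(table, "feature_table"))
  if (!attr(table, "standardized"))
    abort("table is not standardized", "accelmix_input_error")
  mus <- attr(table, "column_means")
  sds <- attr(table, "column_sds")
  out <- table
  for (f in ALL_FEATURES) out[[f]] <- table[[f]] * sds[f] + mus[f]
  feature_table(out, standardized = FALSE)
}

check_two_groups <- function(table) {
  gs <- sort(unique(table$group))
  if (length(gs) != 2)
    abort(sprintf("exactly two groups are required, found %d", length(gs)),
          "accelmix_usage_error")
  gs
}

#' Euclidean distance between group means
#'
#' Distance between the two group-mean vectors, restricted to the selected
#' (standardized) features.
#'
#' @param table A standardized [feature_table()] with exactly two groups.
#' @param features Character vector of 1--6 feature names.
#' @return The Euclidean distance (dimensionless, standardized units).
#' @export
group_distance <- function(table, features) {
  stopifnot(inherits(table, "feature_table"))
  if (!attr(table, "standardized"))
    abort("group_distance requires a standardized table",
          "accelmix_input_error")
  if (length(features) < 1)
    abort("at least one feature must be selected", "accelmix_config_error")
  bad <- setdiff(features, ALL_FEATURES)
  if (length(bad) > 0)
    abort(sprintf("unknown feature name(s): %s", paste(bad, collapse = ", ")),
          "accelmix_config_error")
  gs <- check_two_groups(table)
  m1 <- vapply(features, function(f) mean(table[[f]][table$group == gs[1]]),
               numeric(1))
  m2 <- vapply(features, function(f) mean(table[[f]][table$group == gs[2]]),
               numeric(1))
  sqrt(sum((m1 - m2)^2))
}

#' Group distances for all singletons and pairs of mixture features
#'
#' Computes [group_distance()] for each of the five mixture features alone
#' and for every unordered pair, and reports the pair with the greatest
#' distance.
#'
#' @param table A standardized [feature_table()] with exactly two groups.
#' @return A list with `distances` (data frame: `feature_1`, `feature_2`
#'   (`NA` for singletons), `distance`) and `best_pair` (character vector of
#'   length 2).
#' @export
distance_matrix <- function(table) {
  singles <- data.frame(feature_1 = GMM_FEATURES, feature_2 = NA_character_,
                        stringsAsFactors = FALSE)
  prs <- t(utils::combn(GMM_FEATURES, 2))
  pairs <- data.frame(feature_1 = prs[, 1], feature_2 = prs[, 2],
                      stringsAsFactors = FALSE)
  all <- rbind(singles, pairs)
  all$distance <- vapply(seq_len(nrow(all)), function(i) {
    f <- c(all$feature_1[i], all$feature_2[i])
    group_distance(table, f[!is.na(f)])
  }, numeric(1))
  is_pair <- !is.na(all$feature_2)
  best <- which(is_pair)[which.max(all$distance[is_pair])]
  list(distances = all,
       best_pair = c(all$feature_1[best], all$feature_2[best]))
}

#' Two-class linear discriminant analysis on selected features
#'
#' Fisher/pooled-covariance LDA with equal priors, fitted with
#' [MASS::lda()]. Reports the discriminant weight vector, the intercept of
#' the linear decision rule, resubstitution accuracy and confusion counts;
#' optionally a k-fold cross-validated accuracy.
#'
#' @param table A standardized [feature_table()] with exactly two groups of
#'   at least 2 rows each.
#' @param features Character vector of feature names.
#' @param cv_folds Optional integer: also compute k-fold cross-validated
#'   accuracy (deterministic interleaved folds).
#' @return An `lda_model`: `weights`, `intercept`, `classes`, `accuracy`,
#'   `confusion` (2x2), `features`, optionally `cv_accuracy`.
#' @export
fit_lda <- function(table, features, cv_folds = NULL) {
  stopifnot(inherits(table, "feature_table"))
  if (!attr(table, "standardized"))
    abort("fit_lda requires a standardized table", "accelmix_input_error")
  if (length(features) < 1)
    abort("at least one feature must be selected", "accelmix_config_error")
  bad <- setdiff(features, ALL_FEATURES)
  if (length(bad) > 0)
    abort(sprintf("unknown feature name(s): %s", paste(bad, collapse = ", ")),
          "accelmix_config_error")
  gs <- check_two_groups(table)
  if (any(table(table$group) < 2))
    abort("each group needs at least 2 rows", "accelmix_usage_error")
  X <- as.matrix(as.data.frame(table)[features])
  grp <- factor(table$group, levels = gs)
  model <- tryCatch(
    MASS::lda(X, grouping = grp, prior = c(0.5, 0.5)),
    error = function(e)
      abort(sprintf("LDA failed (singular within-group covariance?): %s; try a smaller feature subset",
                    conditionMessage(e)), "accelmix_degenerate_design_error"))
  w <- model$scaling[, 1]
  mid <- colMeans(model$means)            # midpoint of the two class means
  pred <- stats::predict(model, X)$class
  conf <- table(truth = grp, predicted = pred)
  acc <- mean(pred == grp)
  out <- list(weights = w,
              intercept = -sum(w * mid),
              classes = gs,
              accuracy = acc,
              confusion = unclass(conf),
              features = features,
              model = model)
  if (!is.null(cv_folds)) {
    k <- as.integer(cv_folds)
    fold <- rep_len(seq_len(k), nrow(X))[order(order(as.integer(grp)))]
    hits <- vapply(seq_len(k), function(f) {
      tr <- fold != f
      m <- MASS::lda(X[tr, , drop = FALSE], grouping = grp[tr],
                     prior = c(0.5, 0.5))
      sum(stats::predict(m, X[!tr, , drop = FALSE])$class == grp[!tr])
    }, numeric(1))
    out$cv_accuracy <- sum(hits) / nrow(X)
  }
  structure(out, class = "lda_model")
}

#' @export
print.lda_model <- function(x, ...) {
  cat(sprintf("<lda_model> %s vs %s on {%s}\n", x$classes[1], x$classes[2],
              paste(x$features, collapse = ", ")))
  cat(sprintf("  resubstitution accuracy: %.1f%%\n", 100 * x$accuracy))
  if (!is.null(x$cv_accuracy))
    cat(sprintf("  cross-validated accuracy: %.1f%%\n", 100 * x$cv_accuracy))
  invisible(x)
}

#' Compare the mixture-based and conventional load features
#'
#' Bundles the group separation achieved by the proposed feature set
#' `{mu_high, sigma_high}` against the conventional `{mu_total}`: the
#' Euclidean distance between standardized group means and the two-class
#' LDA accuracy for each.
#'
#' @param table A standardized [feature_table()] with exactly two groups.
#' @param cv_folds Optional; passed to [fit_lda()].
#' @return A `method_comparison` list with elements `proposed` and
#'   `conventional`, each carrying `features`, `distance`, `accuracy` and
#'   `confusion`.
#' @export
compare_methods <- function(table, cv_folds = NULL) {
  sets <- list(proposed = c("mu_high", "sigma_high"),
               conventional = "mu_total")
  out <- lapply(sets, function(fs) {
    m <- fit_lda(table, fs, cv_folds = cv_folds)
    r <- list(features = fs,
              distance = group_distance(table, fs),
              accuracy = m$accuracy,
              confusion = m$confusion)
    if (!is.null(m$cv_accuracy)) r$cv_accuracy <- m$cv_accuracy
    r
  })
  structure(out, class = "method_comparison")
}

#' @export
print.method_comparison <- function(x, ...) {
  for (nm in names(x))
    cat(sprintf("%-12s {%s}: distance %.3f, LDA accuracy %.1f%%\n", nm,
                paste(x[[nm]]$features, collapse = ", "),
                x[[nm]]$distance, 100 * x[[nm]]$accuracy))
  invisible(x)
}

#' Write / read feature tables
#'
#' CSV columns: `recording_id, group, mu_low, sigma_low, mu_high,
#' sigma_high, w_high, mu_total`. Values are written with 17 significant
#' digits, so the pair round-trips bit-exactly.
#'
#' @param table A [feature_table()].
#' @param path Output (or input) CSV path.
#' @return `write_features`: `path`, invisibly. `read_features`: a
#'   `feature_table` (marked unstandardized; standardize after reading).
#' @export
write_features <- function(table, path) {
  stopifnot(inherits(table, "feature_table"))
  header <- paste(c("recording_id", "group", ALL_FEATURES), collapse = ",")
  rows <- character(0)
  if (nrow(table) > 0) {
    vals <- vapply(ALL_FEATURES,
                   function(f) sprintf("%.17g", table[[f]]), character(nrow(table)))
    if (nrow(table) == 1L) vals <- matrix(vals, nrow = 1)
    rows <- paste(table$recording_id, table$group,
                  apply(vals, 1, paste, collapse = ","), sep = ",")
  }
  ok <- tryCatch({ writeLines(c(header, rows), path); TRUE },
                 error = function(e) FALSE)
  if (!ok) abort(sprintf("cannot write %s", path), "accelmix_io_error")
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  if (!file.exists(path))
    abort(sprintf("feature file not found: %s", path), "accelmix_io_error")
  df <- read.csv(path, stringsAsFactors = FALSE,
                 colClasses = c(recording_id = "character",
                                group = "character"))
  feature_table(df)
}
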