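test_that("conventional mean averages the raw norm over in-play samples", {
  tr <- accel_trace(cbind(0, 0, rep(0.6, 1000)), 100)
  iv <- interval_set("in_play", 0L, 1000L, 1000L, 100)
  expect_equal(conventional_mean(tr, iv), 0.6)

  # half at norm 0.4, half at 0.8 -> 0.6
  tr2 <- accel_trace(cbind(0, 0, c(rep(0.4, 500), rep(0.8, 500))), 100)
  expect_equal(conventional_mean(tr2, iv), 0.6)

  # brute-force oracle on a synthetic match
  rec <- simulate_match(synth_match_config(sample_rate_hz = 50,
                                           duration_s = 120, seed = 21))
  nrm <- sqrt(rowSums(rec$trace$samples^2))
  keep <- unlist(mapply(seq, rec$intervals$start_index + 1,
                        rec$intervals$end_index,
                        SIMPLIFY = FALSE)[rec$intervals$label == "in_play"])
  expect_equal(conventional_mean(rec$trace, rec$intervals), mean(nrm[keep]))

  # all-rest recording has no exposure window
  iv_rest <- interval_set("rest", 0L, 1000L, 1000L, 100)
  expect_error(conventional_mean(tr, iv_rest),
               class = "accelmix_insufficient_data_error")
  # whole-recording scope works regardless
  expect_equal(conventional_mean(tr, iv_rest,
                                 run_config(mu_total_scope = "recording")),
               0.6)
})

test_that("standardization matches the n-1 convention and is invertible", {
  tab <- make_feature_table(1)          # 2 rows
  tab$mu_low <- c(1, 3)
  std <- standardize(tab)
  expect_equal(std$mu_low, c(-1, 1) / sqrt(2), tolerance = 1e-12)

  tab6 <- make_feature_table(3)
  std6 <- standardize(tab6)
  for (f in c("mu_low", "sigma_low", "mu_high", "sigma_high", "w_high",
              "mu_total")) {
    expect_lt(abs(mean(std6[[f]])), 1e-9)
    expect_lt(abs(sd(std6[[f]]) - 1), 1e-9)
  }
  # idempotence and exact inversion
  std_again <- standardize(std6)
  for (f in names(std6)[-(1:2)])
    expect_equal(std_again[[f]], std6[[f]], tolerance = 1e-12)
  back <- unstandardize(std6)
  for (f in names(tab6)[-(1:2)])
    expect_equal(back[[f]], tab6[[f]], tolerance = 1e-12)

  # constant columns are named in the failure
  tabc <- make_feature_table(2)
  tabc$w_high <- 0.5
  expect_error(standardize(tabc), "w_high",
               class = "accelmix_degenerate_feature_error")
})

test_that("group distance reduces to Euclidean geometry", {
  tab <- make_feature_table(2)
  std <- standardize(tab)
  # identical group means -> 0: make group B a copy of group A
  sym <- tab
  sym[5:8, -(1:2)] <- sym[1:4, -(1:2)]
  sym$group <- rep(c("A", "B"), each = 4)
  sym$recording_id <- sprintf("r%d", 1:8)
  std_sym <- standardize(feature_table(sym))
  expect_equal(group_distance(std_sym, c("mu_high", "sigma_high")), 0)

  # engineered standardized coordinates: means (0,0) vs (3,4) -> 5
  eng <- make_feature_table(4)
  eng$mu_high <- c(-1, 1, -1, 1, 2, 4, 2, 4)       # means 0 and 3
  eng$sigma_high <- c(-2, 2, -2, 2, 2, 6, 2, 6)    # means 0 and 4
  eng <- feature_table(eng, standardized = TRUE)   # bypass re-scaling
  expect_equal(group_distance(eng, c("mu_high", "sigma_high")), 5)
  # 1-D distance is the absolute mean difference
  expect_equal(group_distance(eng, "mu_high"), 3)

  expect_error(group_distance(std, "nope"), class = "accelmix_config_error")
  expect_error(group_distance(std, character(0)),
               class = "accelmix_config_error")
  expect_error(group_distance(tab, "mu_high"),
               class = "accelmix_input_error")   # not standardized
})

test_that("distance matrix covers singletons and pairs and finds the best pair", {
  co <- simulate_cohort(synth_cohort_config(n_per_group = 10, seed = 14))
  std <- standardize(co$truth_features)
  dm <- distance_matrix(std)
  expect_equal(nrow(dm$distances), 5 + 10)
  expect_true(all(dm$distances$distance >= 0))
  # cohort truths differ only in the high-intensity component
  expect_setequal(dm$best_pair, c("mu_high", "sigma_high"))
  # squared distances add over features
  d2 <- function(f) group_distance(std, f)^2
  expect_equal(d2(c("mu_high", "sigma_high")),
               d2("mu_high") + d2("sigma_high"))

  # invariant to row permutation
  set.seed(1)
  perm <- feature_table(as.data.frame(std)[sample(nrow(std)), ],
                        standardized = TRUE)
  dm2 <- distance_matrix(perm)
  expect_equal(dm2$distances$distance, dm$distances$distance)
})

test_that("LDA separates well-separated clusters perfectly", {
  set.seed(61)
  n <- 50
  tab <- make_feature_table(n / 2)[rep(1:6, length.out = 2 * n), ]
  tab$recording_id <- sprintf("r%03d", 1:(2 * n))
  tab$group <- rep(c("A", "B"), each = n)
  tab$mu_high <- c(rnorm(n, 0, 1), rnorm(n, 4, 1))
  tab$sigma_high <- c(rnorm(n, 0, 1), rnorm(n, 4, 1))
  tab <- feature_table(tab)
  std <- standardize(tab)
  m <- fit_lda(std, c("mu_high", "sigma_high"))
  expect_equal(m$accuracy, 1.0)
  expect_equal(sum(m$confusion), 2 * n)

  # brute-force check: the pooled-covariance discriminant classifies
  # every row the same way as the reported confusion counts
  X <- as.matrix(as.data.frame(std)[c("mu_high", "sigma_high")])
  g <- std$group
  m1 <- colMeans(X[g == "A", ]); m2 <- colMeans(X[g == "B", ])
  S <- ((sum(g == "A") - 1) * cov(X[g == "A", ]) +
        (sum(g == "B") - 1) * cov(X[g == "B", ])) / (2 * n - 2)
  w <- solve(S, m2 - m1)
  score <- X %*% w - sum(w * (m1 + m2)) / 2
  pred <- ifelse(score > 0, "B", "A")
  expect_equal(mean(pred == g), m$accuracy)
})

test_that("LDA is symmetric under label swap and near chance for identical groups", {
  set.seed(62)
  n <- 50
  tab <- make_feature_table(3)[rep(1:6, length.out = 2 * n), ]
  tab$recording_id <- sprintf("r%03d", 1:(2 * n))
  tab$group <- rep(c("A", "B"), each = n)
  tab$mu_high <- rnorm(2 * n)          # identical distributions
  tab$sigma_high <- rnorm(2 * n)
  std <- standardize(feature_table(tab))
  m <- fit_lda(std, c("mu_high", "sigma_high"))
  expect_gte(m$accuracy, 0.35)
  expect_lte(m$accuracy, 0.65)

  swapped <- std
  swapped$group <- ifelse(std$group == "A", "B", "A")
  swapped <- feature_table(swapped, standardized = TRUE)
  m2 <- fit_lda(swapped, c("mu_high", "sigma_high"))
  expect_equal(m2$accuracy, m$accuracy)
  # discriminant direction flips (anti-parallel)
  cosang <- sum(m$weights * m2$weights) /
    sqrt(sum(m$weights^2) * sum(m2$weights^2))
  expect_equal(cosang, -1, tolerance = 1e-8)
})

test_that("LDA accuracy is invariant to common affine rescaling of features", {
  co <- simulate_cohort(synth_cohort_config(n_per_group = 10, seed = 8))
  tab <- co$truth_features
  m1 <- fit_lda(standardize(tab), c("mu_high", "sigma_high"))
  resc <- tab
  resc$mu_high <- 100 * resc$mu_high - 7
  resc$sigma_high <- 100 * resc$sigma_high - 7
  m2 <- fit_lda(standardize(feature_table(resc)), c("mu_high", "sigma_high"))
  expect_equal(m2$accuracy, m1$accuracy)
})

test_that("method comparison contrasts proposed and conventional features", {
  co <- simulate_cohort(synth_cohort_config(n_per_group = 15, seed = 9))
  std <- standardize(co$truth_features)
  cmp <- compare_methods(std)
  expect_named(cmp, c("proposed", "conventional"))
  expect_equal(cmp$proposed$features, c("mu_high", "sigma_high"))
  expect_equal(cmp$conventional$features, "mu_total")
  expect_true(cmp$proposed$accuracy >= 0 && cmp$proposed$accuracy <= 1)
  expect_equal(sum(cmp$proposed$confusion), nrow(std))
  expect_error(fit_lda(std, character(0)), class = "accelmix_config_error")
})
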