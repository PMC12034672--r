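# Protocol mechanics, ablations, Wilcoxon comparisons, leakage audit.

test_that("subject-dependent splits are stratified 3:1 per subject", {
  st <- tiny_study()
  res <- run_subject_dependent(st, tiny_spec(), features = tiny_features())
  expect_length(res$per_subject_accuracy, 3)
  expect_true(all(res$per_subject_accuracy >= 0 &
                    res$per_subject_accuracy <= 1))
  for (f in res$folds) {
    expect_length(f$train, 6)
    expect_length(f$test, 2)
    expect_length(intersect(f$train, f$test), 0)
  }
  expect_equal(res$mean, mean(res$per_subject_accuracy), tolerance = 1e-12)
  expect_equal(res$sd, sd(res$per_subject_accuracy), tolerance = 1e-12)

  # single-subject study: a single accuracy comes back
  one <- list(st$subjects[[1]])
  f_one <- study_feature_matrix(one, window_s = 3)
  r1 <- run_subject_dependent(one, tiny_spec(), features = f_one)
  expect_length(r1$per_subject_accuracy, 1)
})

test_that("leave-one-subject-out holds each subject's trials out in turn", {
  st <- tiny_study()
  sf <- tiny_features()
  res <- run_loso(st, tiny_spec("subject_independent"), features = sf)
  expect_length(res$per_subject_accuracy, 3)
  for (i in seq_along(res$folds)) {
    f <- res$folds[[i]]
    expect_equal(sort(unique(sf$meta$subject[f$test])), i)
    expect_false(i %in% sf$meta$subject[f$train])
    expect_length(f$test, 8)  # every trial of the held-out subject
  }
  expect_error(run_loso(list(st$subjects[[1]]),
                        tiny_spec("subject_independent"),
                        features = study_feature_matrix(
                          list(st$subjects[[1]]), 3)),
               "at least 2 subjects")
})

test_that("subject-and-trial protocol keeps trial indices disjoint", {
  st <- tiny_study()
  sf <- tiny_features()
  spec <- tiny_spec("subject_trial_independent")
  res <- run_subject_trial_independent(st, spec, features = sf)
  for (f in res$folds) {
    expect_length(intersect(f$test_trials, f$train_trials), 0)
    expect_length(f$test_trials, 4)  # half of 8
    # training rows come from other subjects and complementary trials only
    expect_false(f$subject %in% sf$meta$subject[f$train])
    expect_true(all(sf$meta$trial[f$train] %in% f$train_trials))
    expect_true(all(sf$meta$trial[f$test] %in% f$test_trials))
  }
  # identical seed => identical partition
  res2 <- run_subject_trial_independent(st, spec, features = sf)
  expect_identical(lapply(res$folds, `[[`, "test_trials"),
                   lapply(res2$folds, `[[`, "test_trials"))
})

test_that("no protocol stage touches test rows (leakage audit)", {
  st <- tiny_study()
  sf <- tiny_features()
  for (mode in c("subject_dependent", "subject_independent",
                 "subject_trial_independent")) {
    res <- run_protocol(st, tiny_spec(mode), features = sf,
                        record_access = TRUE)
    expect_true(isTRUE(leakage_audit(res)))
    stages <- unlist(lapply(res$access_log,
                            function(a) vapply(a$stages, `[[`, "", "stage")))
    expect_setequal(unique(stages), c("mrmr", "standardize", "grid_search"))
  }
})

test_that("region restriction shrinks feature blocks accordingly", {
  st <- tiny_study()
  map <- list(L = c("Ch01", "Ch02", "Ch03"), R = c("Ch04", "Ch05", "Ch06"))
  sf <- study_feature_matrix(list(st$subjects[[1]]), window_s = 3,
                             region = "L", region_map = map)
  # 12 signals x 4 windows x (1 + 2*3) features
  expect_equal(ncol(sf$X), 12 * 4 * 7)
  expect_error(study_feature_matrix(list(st$subjects[[1]]), window_s = 3,
                                    region = "solo",
                                    region_map = list(solo = "Ch01")),
               "fewer than 2 channels")
  spec <- tiny_spec()
  spec$region_map <- map
  out <- region_ablation(st, spec, regions = c("L", "R"))
  expect_named(out, c("L", "R"))
  expect_true(all(vapply(out, function(r) r$mean, 1) >= 0))
})

test_that("band-pair restriction keeps that pair's two signals", {
  st <- tiny_study()
  sf <- study_feature_matrix(list(st$subjects[[1]]), window_s = 3,
                             band_pairs = "gamma_beta")
  # 2 signals (amp + phase) x 4 windows x 13 features
  expect_equal(ncol(sf$X), 2 * 4 * 13)
  expect_error(study_feature_matrix(list(st$subjects[[1]]), window_s = 3,
                                    band_pairs = "alpha_gamma"),
               "unknown band pair")
})

test_that("paired Wilcoxon comparison follows the discard-zeros policy", {
  a <- c(0.8, 0.7, 0.9, 0.6)
  expect_true(wilcoxon_compare(a, a)$degenerate)
  set.seed(71)
  b <- runif(32, 0.5, 0.9)
  res <- wilcoxon_compare(b + 0.1, b)  # uniform improvement across subjects
  expect_lt(res$p_value, 0.05)
  expect_false(res$degenerate)
  expect_error(wilcoxon_compare(1:3, 1:4), "paired")
})

test_that("the Wilcoxon test keeps its nominal size under the null", {
  # signed-rank p-values are discrete at small n, so check the rejection
  # rate at alpha = 0.05 rather than continuous uniformity
  set.seed(73)
  p <- replicate(500, {
    a <- runif(16)
    b <- runif(16)
    wilcoxon_compare(a, b)$p_value
  })
  rej <- sum(p < 0.05)
  band <- qbinom(c(0.0005, 0.9995), 500, 0.05)  # 99.9% binomial band
  expect_gte(rej, band[1])
  expect_lte(rej, band[2])
  expect_gt(mean(p), 0.4)
  expect_lt(mean(p), 0.6)
})
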