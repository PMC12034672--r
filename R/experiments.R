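# The three evaluation protocols, ablations, Wilcoxon comparisons and the
# leakage-audit instrumentation.

# --- leakage audit -----------------------------------------------------------
# Training-only stages (selection, scaling, grid search) log the global row
# ids of the matrices they are handed; the audit then checks that no logged
# row belongs to the fold's test set.

new_recorder <- function() {
  e <- new.env(parent = emptyenv())
  e$log <- list()
  e
}

log_access <- function(recorder, stage, rows) {
  if (is.null(recorder)) return(invisible(NULL))
  recorder$log[[length(recorder$log) + 1L]] <-
    list(stage = stage, rows = rows)
  invisible(NULL)
}

#' Audit an experiment result for train/test leakage
#'
#' Experiments run with `record_access = TRUE` log, per fold, the global row
#' ids read by feature selection, standardization and grid search. The audit
#' verifies that every logged row belongs to the fold's training set and none
#' to its test set.
#'
#' @param result an `experiment_result` produced with `record_access = TRUE`.
#' @return `TRUE` if clean; otherwise a character vector describing the
#'   violations.
#' @export
leakage_audit <- function(result) {
  if (is.null(result$access_log))
    stop("result carries no access log; run with record_access = TRUE")
  bad <- character(0)
  for (f in seq_along(result$access_log)) {
    al <- result$access_log[[f]]
    for (entry in al$stages) {
      if (length(intersect(entry$rows, al$test)))
        bad <- c(bad, sprintf("fold %d: stage '%s' read test rows", f,
                              entry$stage))
      if (length(setdiff(entry$rows, al$train)))
        bad <- c(bad, sprintf("fold %d: stage '%s' read non-training rows", f,
                              entry$stage))
    }
  }
  if (length(bad)) bad else TRUE
}

# --- protocol specification --------------------------------------------------

#' Specify an evaluation protocol
#'
#' @param mode `"subject_dependent"` (per-subject stratified 3:1 split),
#'   `"subject_independent"` (leave-one-subject-out) or
#'   `"subject_trial_independent"` (held-out subject tested on a random half
#'   of the trial indices, training restricted to the complementary trial
#'   indices of the other subjects).
#' @param dimension `"valence"`, `"arousal"` or `"four_class"`.
#' @param window_s sliding-window length in seconds (60 = static).
#' @param threshold_q positional threshold fraction.
#' @param region region id (`"ALL"`, `"F"`, `"LT"`, `"RT"`, `"C"`, `"PO"`).
#' @param band_pairs `"ALL"` or band-pair names.
#' @param n_bins MI histogram bins.
#' @param k number of mRMR-selected features.
#' @param classifier a [classifier_config()].
#' @param region_map named list resolving region ids to channel names
#'   (default [deap_regions()]).
#' @param seed protocol seed (splits, fold draws).
#' @return list of class `protocol_spec`.
#' @export
protocol_spec <- function(mode = c("subject_dependent", "subject_independent",
                                   "subject_trial_independent"),
                          dimension = c("valence", "arousal", "four_class"),
                          window_s = 1, threshold_q = 0.3, region = "ALL",
                          band_pairs = "ALL", n_bins = 8, k = 64,
                          classifier = classifier_config(),
                          region_map = deap_regions(), seed = 1) {
  structure(list(mode = match.arg(mode), dimension = match.arg(dimension),
                 window_s = window_s, threshold_q = threshold_q,
                 region = region, band_pairs = band_pairs, n_bins = n_bins,
                 k = k, classifier = classifier, region_map = region_map,
                 seed = seed),
            class = "protocol_spec")
}

protocol_labels <- function(meta, dimension) {
  switch(dimension,
         valence = factor(meta$valence_bin, levels = c(0, 1)),
         arousal = factor(meta$arousal_bin, levels = c(0, 1)),
         four_class = meta$four_class)
}

experiment_result <- function(per_subject, spec, access_log = NULL,
                              folds = NULL) {
  structure(list(per_subject_accuracy = per_subject,
                 mean = mean(per_subject),
                 sd = stats::sd(per_subject),
                 spec = spec, access_log = access_log, folds = folds),
            class = "experiment_result")
}

#' @export
print.experiment_result <- function(x, ...) {
  cat(sprintf("<experiment_result> %s / %s, t = %g s: %.2f%% +- %.2f%% (n = %d)\n",
              x$spec$mode, x$spec$dimension, x$spec$window_s,
              100 * x$mean, 100 * (x$sd %||% NA), length(x$per_subject_accuracy)))
  invisible(x)
}

# stratified 3:1 split of one subject's trial rows; retries (bounded) until
# every class appears in the training part
stratified_split <- function(y, ratio = 0.75, seed = 1, max_retries = 20) {
  for (attempt in seq_len(max_retries)) {
    train <- integer(0)
    with_seed(derive_seed(seed, 31, attempt), {
      for (cl in unique(y)) {
        idx <- which(y == cl)
        n_tr <- round(ratio * length(idx))
        train <- c(train, idx[sample.int(length(idx))][seq_len(n_tr)])
      }
    })
    test <- setdiff(seq_along(y), train)
    if (length(test) > 0 &&
        all(unique(y) %in% y[train]))
      return(list(train = sort(train), test = sort(test)))
  }
  stop("could not produce a split with all classes in training after ",
       max_retries, " attempts")
}

run_fold <- function(X, y, train, test, spec, recorder) {
  sel <- mrmr_select(X[train, , drop = FALSE], y[train], k = min(spec$k, ncol(X)),
                     recorder = recorder, row_ids = train)
  cols <- sel$indices
  cfg <- spec$classifier
  cfg$seed <- derive_seed(spec$seed, 47, min(test))
  fp <- fit_and_predict(X[train, cols, drop = FALSE], y[train],
                        X[test, cols, drop = FALSE], cfg,
                        recorder = recorder, row_ids = train)
  mean(fp$labels == droplevels(as.factor(y))[test])
}

#' Run an evaluation protocol
#'
#' Computes (or reuses) the study's feature matrix and evaluates the
#' classification protocol named by `spec$mode`, returning per-subject
#' accuracies. Feature selection, standardization and grid search are fit on
#' training rows only in every fold.
#'
#' @param study a `synthetic_study` or list of [subject_dataset()] objects.
#' @param spec a [protocol_spec()].
#' @param features optional precomputed [study_feature_matrix()] for the
#'   spec's window/region/band-pair settings (reused across protocol runs).
#' @param record_access record the leakage-audit log (see [leakage_audit()]).
#' @return an `experiment_result`.
#' @export
run_protocol <- function(study, spec, features = NULL, record_access = FALSE) {
  sf <- features %||% study_feature_matrix(
    study, spec$window_s, region = spec$region, band_pairs = spec$band_pairs,
    n_bins = spec$n_bins, q = spec$threshold_q,
    region_map = spec$region_map %||% deap_regions())
  X <- sf$X
  y <- protocol_labels(sf$meta, spec$dimension)
  subj <- sf$meta$subject
  subjects <- sort(unique(subj))

  folds <- switch(
    spec$mode,
    subject_dependent = lapply(subjects, function(s) {
      rows <- which(subj == s)
      sp <- stratified_split(y[rows], 0.75, derive_seed(spec$seed, 53, s))
      list(subject = s, train = rows[sp$train], test = rows[sp$test])
    }),
    subject_independent = lapply(subjects, function(s) {
      list(subject = s, train = which(subj != s), test = which(subj == s))
    }),
    subject_trial_independent = lapply(subjects, function(s) {
      trials <- sort(unique(sf$meta$trial))
      n_half <- floor(length(trials) / 2)
      test_trials <- with_seed(derive_seed(spec$seed, 59, s),
                               sort(sample(trials, n_half)))
      train_trials <- setdiff(trials, test_trials)
      list(subject = s,
           train = which(subj != s & sf$meta$trial %in% train_trials),
           test = which(subj == s & sf$meta$trial %in% test_trials),
           test_trials = test_trials, train_trials = train_trials)
    }))
  if (spec$mode != "subject_dependent" && length(subjects) < 2)
    stop("cross-subject protocols need at least 2 subjects")

  acc <- numeric(length(folds))
  access_log <- if (record_access) vector("list", length(folds)) else NULL
  for (f in seq_along(folds)) {
    rec <- if (record_access) new_recorder() else NULL
    acc[f] <- run_fold(X, y, folds[[f]]$train, folds[[f]]$test, spec, rec)
    if (record_access)
      access_log[[f]] <- list(train = folds[[f]]$train,
                              test = folds[[f]]$test, stages = rec$log)
  }
  experiment_result(acc, spec, access_log = access_log, folds = folds)
}

#' @rdname run_protocol
#' @export
run_subject_dependent <- function(study, spec, features = NULL,
                                  record_access = FALSE) {
  spec$mode <- "subject_dependent"
  run_protocol(study, spec, features, record_access)
}

#' @rdname run_protocol
#' @export
run_loso <- function(study, spec, features = NULL, record_access = FALSE) {
  spec$mode <- "subject_independent"
  run_protocol(study, spec, features, record_access)
}

#' @rdname run_protocol
#' @export
run_subject_trial_independent <- function(study, spec, features = NULL,
                                          record_access = FALSE) {
  spec$mode <- "subject_trial_independent"
  run_protocol(study, spec, features, record_access)
}

#' Region ablation
#'
#' Re-runs the protocol once per scalp region, restricting the pipeline to
#' that region's channels (feature blocks shrink to `1 + 2 |region|` values
#' per network).
#'
#' @param study study object.
#' @param spec a [protocol_spec()]; its `region` field is overridden.
#' @param regions region ids (default the five scalp regions).
#' @return named list of `experiment_result`, one per region.
#' @export
region_ablation <- function(study, spec,
                            regions = c("F", "LT", "RT", "C", "PO")) {
  out <- list()
  for (r in regions) {
    sp <- spec
    sp$region <- r
    out[[r]] <- run_protocol(study, sp)
  }
  out
}

#' Band-pair ablation
#'
#' Re-runs the protocol restricted to single band pairs (each pair contributes
#' its amplitude and phase difference signals, so the per-trial feature count
#' is `2 * (duration / t) * (1 + 2 n)`).
#'
#' @param study study object.
#' @param spec a [protocol_spec()]; its `band_pairs` field is overridden.
#' @param pairs band-pair names (default all six).
#' @return named list of `experiment_result`, one per pair.
#' @export
band_pair_ablation <- function(study, spec, pairs = band_pair_names()) {
  out <- list()
  for (p in pairs) {
    sp <- spec
    sp$band_pairs <- p
    out[[p]] <- run_protocol(study, sp)
  }
  out
}

#' Paired Wilcoxon signed-rank comparison of accuracies
#'
#' Two-sided signed-rank test on paired per-subject accuracies. Zero
#' differences are dropped before testing (the discard-zeros policy); if all
#' differences are zero the result is flagged degenerate with `p = 1`.
#'
#' @param a,b equal-length numeric vectors of per-subject accuracies, paired
#'   by subject.
#' @return list with `statistic`, `p_value`, `n_nonzero`, `degenerate`.
#' @export
wilcoxon_compare <- function(a, b) {
  if (length(a) != length(b)) stop("a and b must be paired (equal length)")
  d <- a - b
  nz <- d[d != 0]
  if (length(nz) == 0)
    return(list(statistic = NA_real_, p_value = 1, n_nonzero = 0L,
                degenerate = TRUE))
  wt <- suppressWarnings(stats::wilcox.test(nz, alternative = "two.sided",
                                            exact = length(nz) < 50))
  list(statistic = unname(wt$statistic), p_value = wt$p.value,
       n_nonzero = length(nz), degenerate = FALSE)
}
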