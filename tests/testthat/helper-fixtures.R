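# Shared fixtures, cached per test session (the reference study's feature
# matrices are expensive and reused across test files).

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixture_cache[[key]]))
    assign(key, expr, envir = .fixture_cache)
  .fixture_cache[[key]]
}

reference_study <- function() cached("study", fixture_study(seed = 1))

reference_features <- function(window_s) {
  cached(paste0("feat_w", window_s),
         study_feature_matrix(reference_study(), window_s))
}

# a small, fast study for protocol-mechanics tests: 3 subjects x 8 trials,
# 6 channels, 12 s trials
tiny_study <- function(n_subjects = 3, n_trials = 8, seed = 7) {
  cached(sprintf("tiny_%d_%d_%d", n_subjects, n_trials, seed), {
    nch <- 6
    specs <- list(
      LV = coupling_spec(nch, matrix(c(1, 2), ncol = 2),
                         coupling_strength = 0.8, noise_sd = 0.3),
      HV = coupling_spec(nch, rbind(c(1, 2), c(3, 4), c(5, 6), c(2, 3)),
                         coupling_strength = 0.8, noise_sd = 0.3))
    ratings <- list(LV = list(valence = c(2, 4), arousal = c(2, 8)),
                    HV = list(valence = c(6, 8), arousal = c(2, 8)))
    generate_study(n_subjects, n_trials, specs, ratings, seed = seed,
                   duration_s = 12)
  })
}

tiny_spec <- function(mode = "subject_dependent", ...) {
  protocol_spec(mode = mode, dimension = "valence", window_s = 3, k = 8,
                classifier = classifier_config(n_repeats = 2, n_folds = 3,
                                               c_grid = c(0.1, 1),
                                               seed = 5),
                seed = 5, ...)
}

tiny_features <- function() {
  cached("tiny_features", study_feature_matrix(tiny_study(), window_s = 3))
}
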