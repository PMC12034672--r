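# End-to-end feature construction: trial -> rhythms -> difference signals ->
# windows -> MI networks -> graph-attribute feature vectors.

select_difference_signals <- function(diffs, band_pairs) {
  if (identical(band_pairs, "ALL")) return(diffs)
  valid <- band_pair_names()
  unknown <- setdiff(band_pairs, valid)
  if (length(unknown))
    stop("unknown band pair(s): ", paste(unknown, collapse = ", "),
         " (valid: ", paste(valid, collapse = ", "), ")")
  keep <- unlist(lapply(c("amp", "phase"), function(m)
    paste(m, band_pairs, sep = "_")))
  diffs[names(diffs) %in% keep]
}

#' Full feature vector of one trial
#'
#' Runs the whole per-trial pipeline: Morlet decomposition into the four
#' rhythms, the 12 inter-band amplitude/phase difference signals (or the
#' subset belonging to `band_pairs`), non-overlapping windows of `window_s`
#' seconds, an MI connectivity matrix and positional-threshold binarization
#' per window, and the `1 + 2 n` graph-attribute block per network. Blocks are
#' concatenated signal-major, window-minor.
#'
#' @param tr a preprocessed [trial_recording()].
#' @param window_s window length in seconds (60 gives the static analysis).
#' @param n_bins histogram bins for the MI estimator (default 8).
#' @param q positional threshold fraction (default 0.3).
#' @param band_pairs `"ALL"` or a character vector of pair names such as
#'   `"alpha_theta"` (each pair contributes its amplitude and phase signals).
#' @param wrap wrap phase differences to (-pi, pi].
#' @return a `trial_features` vector (see [assemble_trial_features()]).
#' @export
trial_feature_vector <- function(tr, window_s, n_bins = 8, q = 0.3,
                                 band_pairs = "ALL", wrap = TRUE) {
  bd <- band_definitions()
  analytics <- lapply(seq_len(nrow(bd)), function(i)
    morlet_decompose(tr, as.list(bd[i, ])))
  names(analytics) <- bd$name
  diffs <- select_difference_signals(band_differences(analytics, wrap = wrap),
                                     band_pairs)
  duration_s <- ncol(tr$data) / tr$fs
  networks <- list()
  for (nm in names(diffs)) {
    wins <- segment_windows(diffs[[nm]], window_s, fs = tr$fs)
    for (w in seq_along(wins)) {
      adj <- positional_threshold(connectivity_matrix(wins[[w]], n_bins), q)
      networks[[sprintf("%s_w%02d", nm, w)]] <- adj
    }
  }
  assemble_trial_features(networks, window_s, duration_s = duration_s,
                          n_signals = length(diffs))
}

#' Feature matrix of a whole study
#'
#' Applies [trial_feature_vector()] to every trial of every subject and stacks
#' the results into a trials x features matrix with per-row metadata (subject,
#' trial, ratings and binarized labels).
#'
#' @param study a `synthetic_study` or list of [subject_dataset()] objects.
#' @param window_s window length in seconds.
#' @param region region id or [region_mask()] applied before decomposition
#'   (`"ALL"` keeps every channel).
#' @param band_pairs see [trial_feature_vector()].
#' @param n_bins,q MI estimator bins and positional threshold fraction.
#' @param region_map region map used to resolve region ids.
#' @param progress print one dot per trial to stderr.
#' @return object of class `study_features`: list with `X` (matrix), `meta`
#'   (data frame: `subject`, `trial`, `valence`, `arousal`, `valence_bin`,
#'   `arousal_bin`, `four_class`), `params`.
#' @export
study_feature_matrix <- function(study, window_s, region = "ALL",
                                 band_pairs = "ALL", n_bins = 8, q = 0.3,
                                 region_map = deap_regions(),
                                 progress = FALSE) {
  subjects <- if (inherits(study, "synthetic_study")) study$subjects else study
  rows <- list()
  meta <- list()
  for (s in seq_along(subjects)) {
    sd_ <- subjects[[s]]
    labs <- binarize_labels(sd_$ratings)
    for (tr in seq_along(sd_$trials)) {
      rec <- sd_$trials[[tr]]
      if (!identical(region, "ALL")) {
        mask <- if (inherits(region, "region_mask")) region
                else region_mask(region, channels = rec$channel_names,
                                 region_map = region_map)
        if (length(mask$channels) < 2)
          stop("region '", mask$region_id, "' has fewer than 2 channels")
        rec <- select_region(rec, mask)
      }
      fv <- trial_feature_vector(rec, window_s, n_bins = n_bins, q = q,
                                 band_pairs = band_pairs)
      rows[[length(rows) + 1L]] <- as.numeric(fv)
      meta[[length(meta) + 1L]] <- data.frame(
        subject = s, trial = tr,
        valence = sd_$ratings$valence[tr], arousal = sd_$ratings$arousal[tr],
        valence_bin = labs$valence_bin[tr], arousal_bin = labs$arousal_bin[tr],
        four_class = labs$four_class[tr])
      if (progress) cat(".", file = stderr())
    }
  }
  if (progress) cat("\n", file = stderr())
  X <- do.call(rbind, rows)
  structure(list(X = X, meta = do.call(rbind, meta),
                 params = list(window_s = window_s, region = region,
                               band_pairs = band_pairs, n_bins = n_bins,
                               q = q)),
            class = "study_features")
}

#' Write a study feature matrix to CSV
#'
#' Rows are trials (with subject/trial/label metadata columns first), columns
#' the layout-named features.
#'
#' @param sf a `study_features` object.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_features_csv <- function(sf, path) {
  stopifnot(inherits(sf, "study_features"))
  utils::write.csv(cbind(sf$meta, as.data.frame(sf$X)), path,
                   row.names = FALSE)
  invisible(path)
}
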