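# Data model, DEAP-format reading, preprocessing, labels, channel regions.

#' Construct a trial recording
#'
#' A `trial_recording` holds one trial's channels-by-samples matrix together
#' with its sampling rate and channel names.
#'
#' @param data numeric matrix, channels x samples.
#' @param fs sampling rate in Hz.
#' @param channel_names character vector of unique channel labels, one per row
#'   of `data`. Defaults to `Ch01 ...` placeholders.
#' @return an object of class `trial_recording` with fields `data`, `fs`,
#'   `channel_names`.
#' @export
trial_recording <- function(data, fs, channel_names = NULL) {
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  if (is.null(channel_names))
    channel_names <- sprintf("Ch%02d", seq_len(nrow(data)))
  if (length(channel_names) != nrow(data))
    stop("channel_names length (", length(channel_names),
         ") does not match channel count (", nrow(data), ")")
  if (anyDuplicated(channel_names))
    stop("channel_names must be unique")
  rownames(data) <- channel_names
  structure(list(data = data, fs = fs, channel_names = channel_names),
            class = "trial_recording")
}

#' @export
print.trial_recording <- function(x, ...) {
  cat(sprintf("<trial_recording> %d channels x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs))
  invisible(x)
}

#' Construct a subject dataset
#'
#' @param trials list of [trial_recording()] objects, one per trial.
#' @param ratings data frame with one row per trial and at least columns
#'   `valence` and `arousal` on the continuous 1-9 self-assessment scale.
#' @return an object of class `subject_dataset`.
#' @export
subject_dataset <- function(trials, ratings) {
  ratings <- as.data.frame(ratings)
  if (!all(c("valence", "arousal") %in% names(ratings)))
    stop("ratings must have 'valence' and 'arousal' columns")
  if (length(trials) != nrow(ratings))
    stop("number of trials (", length(trials),
         ") does not match rating rows (", nrow(ratings), ")")
  rng <- range(c(ratings$valence, ratings$arousal))
  if (rng[1] < 1 || rng[2] > 9)
    stop("ratings must lie in [1, 9]; observed range [",
         rng[1], ", ", rng[2], "]")
  structure(list(trials = trials, ratings = ratings),
            class = "subject_dataset")
}

#' @export
print.subject_dataset <- function(x, ...) {
  cat(sprintf("<subject_dataset> %d trials, %d channels\n",
              length(x$trials),
              if (length(x$trials)) nrow(x$trials[[1]]$data) else 0))
  invisible(x)
}

#' DEAP channel order
#'
#' The 32 EEG channel labels of the preprocessed DEAP release, in recording
#' order (Geneva order), optionally followed by the 8 peripheral channels.
#'
#' @param peripheral if `TRUE`, append the 8 non-EEG channel labels
#'   (positions 33-40).
#' @return character vector of length 32 or 40.
#' @export
deap_channel_names <- function(peripheral = FALSE) {
  eeg <- c("Fp1", "AF3", "F3", "F7", "FC5", "FC1", "C3", "T7",
           "CP5", "CP1", "P3", "P7", "PO3", "O1", "Oz", "Pz",
           "Fp2", "AF4", "Fz", "F4", "F8", "FC6", "FC2", "Cz",
           "C4", "T8", "CP6", "CP2", "P4", "P8", "PO4", "O2")
  if (!peripheral) return(eeg)
  c(eeg, c("hEOG", "vEOG", "zEMG", "tEMG", "GSR", "Resp", "Plet", "Temp"))
}

#' Scalp region map
#'
#' Partition of the 32 DEAP channels into five scalp regions: frontal (F),
#' left temporal (LT), right temporal (RT), central (C) and parieto-occipital
#' (PO). The assignment follows the standard 10-20 positions: parietal and
#' occipital electrodes are merged into one posterior region and the temporal
#' strip is split left/right. This map is a documented convention of this
#' package and can be replaced by any named list of channel vectors (or a
#' JSON/YAML file read into one).
#'
#' @return named list of character vectors partitioning the 32 channels.
#' @export
deap_regions <- function() {
  list(
    F  = c("Fp1", "Fp2", "AF3", "AF4", "F7", "F3", "Fz", "F4", "F8"),
    LT = c("FC5", "T7", "CP5"),
    RT = c("FC6", "T8", "CP6"),
    C  = c("FC1", "FC2", "C3", "Cz", "C4", "CP1", "CP2"),
    PO = c("P7", "P3", "Pz", "P4", "P8", "PO3", "PO4", "O1", "Oz", "O2")
  )
}

#' Build a region mask
#'
#' @param region_id one of `"F"`, `"LT"`, `"RT"`, `"C"`, `"PO"`, `"ALL"`.
#' @param channels channel universe for `"ALL"` (defaults to the 32 DEAP
#'   channels).
#' @param region_map named list mapping region ids to channel vectors;
#'   defaults to [deap_regions()].
#' @return object of class `region_mask` with fields `region_id`, `channels`.
#' @export
region_mask <- function(region_id, channels = deap_channel_names(),
                        region_map = deap_regions()) {
  if (identical(region_id, "ALL")) {
    ch <- channels
  } else {
    if (!region_id %in% names(region_map))
      stop("unknown region id: ", region_id)
    ch <- region_map[[region_id]]
  }
  structure(list(region_id = region_id, channels = ch),
            class = "region_mask")
}

#' Subset a recording to a scalp region
#'
#' Keeps only the channels named by the mask, preserving the recording's
#' original channel order.
#'
#' @param tr a [trial_recording()].
#' @param mask a [region_mask()] (or character vector of channel names).
#' @return a `trial_recording` with the selected channels.
#' @export
select_region <- function(tr, mask) {
  ch <- if (inherits(mask, "region_mask")) mask$channels else mask
  missing_ch <- setdiff(ch, tr$channel_names)
  if (length(missing_ch))
    stop("channels not present in recording: ",
         paste(missing_ch, collapse = ", "))
  keep <- tr$channel_names[tr$channel_names %in% ch]
  trial_recording(tr$data[keep, , drop = FALSE], tr$fs, keep)
}

#' Baseline-subtract and trim a raw trial
#'
#' Subtracts each channel's mean over the leading baseline segment from the
#' final `keep_s` seconds and discards the baseline. For 40-channel DEAP input
#' the 8 peripheral (non-EEG) channels at positions 33-40 are dropped, giving
#' the canonical 32 x 7680 matrix at 128 Hz.
#'
#' @param raw a [trial_recording()] with at least `baseline_s + keep_s`
#'   seconds of signal.
#' @param baseline_s baseline duration in seconds (default 3).
#' @param keep_s retained duration in seconds (default 60).
#' @param keep_channels indices of channels to retain; by default `1:32` for
#'   40-channel input and all channels otherwise.
#' @return preprocessed `trial_recording`.
#' @export
preprocess_trial <- function(raw, baseline_s = 3, keep_s = 60,
                             keep_channels = NULL) {
  fs <- raw$fs
  n_base <- as.integer(round(baseline_s * fs))
  n_keep <- as.integer(round(keep_s * fs))
  if (ncol(raw$data) < n_base + n_keep)
    stop("trial too short: need at least ", baseline_s + keep_s,
         " s (", n_base + n_keep, " samples), got ", ncol(raw$data))
  if (is.null(keep_channels))
    keep_channels <- if (nrow(raw$data) == 40) 1:32 else seq_len(nrow(raw$data))
  x <- raw$data[keep_channels, , drop = FALSE]
  n <- ncol(x)
  base_mean <- rowMeans(x[, seq_len(n_base), drop = FALSE])
  out <- x[, (n - n_keep + 1):n, drop = FALSE] - base_mean
  trial_recording(out, fs, raw$channel_names[keep_channels])
}

#' Binarize self-assessment ratings
#'
#' Ratings of 5 or above are classified high (1), below 5 low (0), for both
#' the valence and arousal dimensions. The four-class label is the pairing of
#' the two binary labels, encoded LVLA = 0, LVHA = 1, HVLA = 2, HVHA = 3.
#'
#' @param ratings data frame (or matrix) with `valence` and `arousal` columns
#'   on the 1-9 scale.
#' @param threshold the high/low cut point (default 5; scores equal to the
#'   threshold are high).
#' @return object of class `label_set`: a data frame with columns
#'   `valence_bin`, `arousal_bin` (0/1 integers) and `four_class` (factor with
#'   levels `LVLA`, `LVHA`, `HVLA`, `HVHA`).
#' @export
binarize_labels <- function(ratings, threshold = 5) {
  ratings <- as.data.frame(ratings)
  v <- ratings$valence
  a <- ratings$arousal
  if (is.null(v) || is.null(a))
    stop("ratings must have 'valence' and 'arousal' columns")
  if (any(v < 1 | v > 9 | a < 1 | a > 9))
    stop("ratings out of range [1, 9]")
  vb <- as.integer(v >= threshold)
  ab <- as.integer(a >= threshold)
  lv <- c("LVLA", "LVHA", "HVLA", "HVHA")
  fc <- factor(lv[2L * vb + ab + 1L], levels = lv)
  structure(data.frame(valence_bin = vb, arousal_bin = ab, four_class = fc),
            class = c("label_set", "data.frame"))
}

#' Read one subject's recordings from disk
#'
#' Reads a per-subject file in either of the two DEAP release dialects: a
#' MATLAB `.mat` file or a pickled-Python file, each holding a
#' trials x channels x samples array named `data` and a trials x 4 array named
#' `labels` (valence, arousal, dominance, liking). The trials are returned raw
#' (no baseline subtraction); feed them to [preprocess_trial()].
#'
#' @param path path to the file.
#' @param dialect `"matlab"` or `"python"` (pickled). Guessed from the file
#'   extension by default (`.mat` is MATLAB, anything else pickled).
#' @param fs sampling rate of the stored data (128 Hz for the preprocessed
#'   DEAP release).
#' @param channel_names optional channel labels; DEAP labels are used for
#'   32- or 40-channel data, placeholders otherwise.
#' @return a [subject_dataset()].
#' @export
load_subject <- function(path, dialect = c("auto", "matlab", "python"),
                         fs = 128, channel_names = NULL) {
  dialect <- match.arg(dialect)
  if (dialect == "auto")
    dialect <- if (grepl("\\.mat$", path, ignore.case = TRUE)) "matlab"
               else "python"
  vars <- switch(dialect,
                 matlab = read_mat5(path),
                 python = read_pickle_arrays(path))
  if (is.null(vars$data)) stop("file has no 'data' array: ", path)
  if (is.null(vars$labels)) stop("file has no 'labels' array: ", path)
  d <- vars$data
  lab <- vars$labels
  if (length(dim(d)) != 3)
    stop("'data' must be 3-dimensional (trials x channels x samples), got ",
         length(dim(d)), " dimensions")
  if (length(dim(lab)) != 2 || dim(lab)[2] < 2)
    stop("'labels' must be trials x >=2 (valence, arousal, ...), got dims ",
         paste(dim(lab), collapse = " x "))
  if (dim(d)[1] != dim(lab)[1])
    stop("trial count mismatch: data has ", dim(d)[1],
         " trials but labels has ", dim(lab)[1], " rows")
  n_ch <- dim(d)[2]
  if (is.null(channel_names)) {
    channel_names <- if (n_ch == 32) deap_channel_names()
                     else if (n_ch == 40) deap_channel_names(peripheral = TRUE)
                     else sprintf("Ch%02d", seq_len(n_ch))
  }
  trials <- lapply(seq_len(dim(d)[1]), function(i) {
    trial_recording(d[i, , ], fs, channel_names)
  })
  ratings <- data.frame(valence = lab[, 1], arousal = lab[, 2])
  if (ncol(lab) >= 3) ratings$dominance <- lab[, 3]
  if (ncol(lab) >= 4) ratings$liking <- lab[, 4]
  subject_dataset(trials, ratings)
}

#' Write one subject's recordings to disk
#'
#' Inverse of [load_subject()]; used by the synthetic-data writer so the
#' readers are exercised end to end.
#'
#' @param sd a [subject_dataset()].
#' @param path output path.
#' @param dialect `"matlab"` or `"python"`.
#' @return `path`, invisibly.
#' @export
write_subject <- function(sd, path, dialect = c("matlab", "python")) {
  dialect <- match.arg(dialect)
  n_tr <- length(sd$trials)
  n_ch <- nrow(sd$trials[[1]]$data)
  n_s <- ncol(sd$trials[[1]]$data)
  d <- array(0, dim = c(n_tr, n_ch, n_s))
  for (i in seq_len(n_tr)) d[i, , ] <- sd$trials[[i]]$data
  lab <- cbind(sd$ratings$valence, sd$ratings$arousal,
               sd$ratings$dominance %||% rep(5, n_tr),
               sd$ratings$liking %||% rep(5, n_tr))
  vars <- list(data = d, labels = lab)
  switch(dialect,
         matlab = write_mat5(path, vars),
         python = write_pickle_arrays(path, vars))
  invisible(path)
}
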