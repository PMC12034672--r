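# Synthetic multichannel EEG with planted, class-dependent cross-channel
# coupling, so connectivity recovery, feature extraction and the three
# evaluation protocols are testable without any external dataset.

#' Specify a planted coupling structure
#'
#' Each channel carries an intrinsic band-limited oscillation. The planted
#' edges are grouped into connected components, and every component gets one
#' shared band-limited latent source that is mixed into each of its channels
#' (`channel_i += w * s` for every channel `i` of the component) — a
#' synchronized community, the simplest mechanism mutual information provably
#' detects. Two channels joined by a planted edge therefore always share a
#' source; channels of the same component are mutually coupled even without a
#' direct planted edge. Broadband Gaussian noise is added on top.
#'
#' @param n_channels number of channels.
#' @param planted_edges 2-column matrix of channel index pairs (may have zero
#'   rows).
#' @param coupling_strength shared-source mixing weight in `[0, 1]`; 0 makes
#'   all channels mutually independent.
#' @param band rhythm carrying both the intrinsic oscillations and the shared
#'   sources: `"theta"`, `"alpha"`, `"beta"` or `"gamma"`.
#' @param noise_sd standard deviation of the additive broadband noise.
#' @param osc_sd standard deviation of each channel's intrinsic band-limited
#'   oscillation (default 1). The ratio `coupling_strength / osc_sd` sets how
#'   strongly a planted edge's shared envelope dominates the channel's own
#'   independent envelope fluctuations.
#' @param gate_block_s if non-`NULL`, each component's shared source is
#'   gated by an on/off square wave with blocks of this length in seconds,
#'   emulating second-scale nonstationarity of the coupling — the temporal
#'   structure that distinguishes dynamic from static network analyses.
#'   `NULL` keeps the coupling on throughout the trial.
#' @param gate_duty probability that a block is on under the `"random"` gate
#'   mode (default 0.5).
#' @param gate_mode `"random"` (each block on independently with probability
#'   `gate_duty`) or `"alternating"` (a deterministic on/off alternation with
#'   50% duty, emulating stimulus-locked coupling dynamics; combine with
#'   `gate_offset_blocks` to put two classes in anti-phase).
#' @param gate_offset_blocks integer phase offset, in blocks, of the
#'   alternating gate.
#' @return object of class `coupling_spec`.
#' @export
coupling_spec <- function(n_channels, planted_edges = NULL,
                          coupling_strength = 0.8, band = "alpha",
                          noise_sd = 0.3, osc_sd = 1,
                          gate_block_s = NULL, gate_duty = 0.5,
                          gate_mode = c("random", "alternating"),
                          gate_offset_blocks = 0) {
  gate_mode <- match.arg(gate_mode)
  if (is.null(planted_edges))
    planted_edges <- matrix(integer(0), ncol = 2)
  planted_edges <- matrix(as.integer(planted_edges), ncol = 2)
  if (nrow(planted_edges) > 0) {
    if (any(planted_edges < 1 | planted_edges > n_channels))
      stop("planted edge endpoints must be channel indices in 1..",
           n_channels)
    if (any(planted_edges[, 1] == planted_edges[, 2]))
      stop("self-loops are not allowed in planted_edges")
  }
  if (coupling_strength < 0 || coupling_strength > 1)
    stop("coupling_strength must be in [0, 1]")
  bd <- band_definitions()
  if (!band %in% bd$name) stop("unknown band: ", band)
  if (osc_sd < 0) stop("osc_sd must be non-negative")
  if (!is.null(gate_block_s) && gate_block_s <= 0)
    stop("gate_block_s must be positive")
  if (gate_duty < 0 || gate_duty > 1) stop("gate_duty must be in [0, 1]")
  structure(list(n_channels = n_channels, planted_edges = planted_edges,
                 coupling_strength = coupling_strength, band = band,
                 noise_sd = noise_sd, osc_sd = osc_sd,
                 gate_block_s = gate_block_s, gate_duty = gate_duty,
                 gate_mode = gate_mode,
                 gate_offset_blocks = gate_offset_blocks),
            class = "coupling_spec")
}

# band-limited Gaussian noise: white noise filtered with the same Gaussian
# spectral response as the Morlet kernel, rescaled to unit variance
bandlimited_noise <- function(n, fs, low, high) {
  f0 <- (low + high) / 2
  sf <- (high - low) / 4
  w <- stats::rnorm(n)
  f <- (seq_len(n) - 1L) / n * fs
  f[f > fs / 2] <- f[f > fs / 2] - fs
  h <- exp(-(abs(f) - f0)^2 / (2 * sf^2))
  x <- Re(stats::fft(stats::fft(w) * h, inverse = TRUE)) / n
  s <- stats::sd(x)
  if (s > 0) x / s else x
}

#' Generate one synthetic trial
#'
#' @param spec a [coupling_spec()].
#' @param duration_s trial duration in seconds (default 60).
#' @param fs sampling rate in Hz (default 128); must satisfy Nyquist for the
#'   spec's band.
#' @param seed integer seed; the output is bit-identical for identical seeds.
#' @param channel_names optional channel labels.
#' @return a [trial_recording()].
#' @export
generate_trial <- function(spec, duration_s = 60, fs = 128, seed = 1,
                           channel_names = NULL) {
  stopifnot(inherits(spec, "coupling_spec"))
  bd <- band_definitions()
  b <- bd[bd$name == spec$band, ]
  if (b$high >= fs / 2)
    stop("fs = ", fs, " Hz is too low for the ", spec$band,
         " band (needs > ", 2 * b$high, " Hz)")
  n <- duration_s * fs
  if (abs(n - round(n)) > 1e-9)
    stop("duration_s * fs must be an integer")
  n <- as.integer(round(n))
  nc <- spec$n_channels
  with_seed(seed, {
    x <- matrix(0, nc, n)
    for (i in seq_len(nc))
      x[i, ] <- spec$osc_sd * bandlimited_noise(n, fs, b$low, b$high)
    if (nrow(spec$planted_edges) > 0 && spec$coupling_strength > 0) {
      comps <- edge_components(spec$planted_edges, nc)
      for (comp in comps) {
        s <- bandlimited_noise(n, fs, b$low, b$high)
        if (!is.null(spec$gate_block_s)) {
          blk <- as.integer(round(spec$gate_block_s * fs))
          n_blk <- ceiling(n / blk)
          bits <- if (identical(spec$gate_mode, "alternating")) {
            rep_len(c(1, 0), n_blk + spec$gate_offset_blocks)[
              (spec$gate_offset_blocks + 1):(spec$gate_offset_blocks + n_blk)]
          } else {
            stats::rbinom(n_blk, 1, spec$gate_duty)
          }
          s <- s * rep(bits, each = blk)[seq_len(n)]
        }
        for (i in comp)
          x[i, ] <- x[i, ] + spec$coupling_strength * s
      }
    }
    x <- x + matrix(stats::rnorm(nc * n, sd = spec$noise_sd), nc, n)
    trial_recording(x, fs, channel_names)
  })
}

# connected components (as channel-index vectors) of a planted edge set;
# only channels touched by at least one edge are returned
edge_components <- function(edges, n_channels) {
  label <- seq_len(n_channels)
  repeat {
    changed <- FALSE
    for (e in seq_len(nrow(edges))) {
      a <- edges[e, 1]
      b <- edges[e, 2]
      m <- min(label[a], label[b])
      if (label[a] != m || label[b] != m) {
        label[label == label[a] | label == label[b]] <- m
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  touched <- unique(as.vector(edges))
  split(touched, label[touched])
}

# deterministic planted graph with n_edges distinct edges on n_channels nodes
random_edge_set <- function(n_channels, n_edges, seed) {
  all_pairs <- t(utils::combn(n_channels, 2L))
  if (n_edges > nrow(all_pairs))
    stop("more edges requested than pairs available")
  with_seed(seed, all_pairs[sample(nrow(all_pairs), n_edges), , drop = FALSE])
}

#' Generate a multi-subject synthetic study
#'
#' Builds a study in the shape the reader/preprocessor expects: per subject, a
#' balanced sequence of trials whose class determines which coupling spec
#' generated the signals and from which rating range the self-assessment
#' scores are drawn (so [binarize_labels()] recovers the intended class).
#' Per-subject log-normal gain and noise-floor multipliers emulate
#' inter-subject variability, which is what separates the subject-dependent
#' from the subject-independent protocols.
#'
#' @param n_subjects number of subjects.
#' @param n_trials trials per subject (balanced across classes within +-1).
#' @param class_specs named list of [coupling_spec()], one per class; all must
#'   share `n_channels`.
#' @param rating_map named list (same names) of lists with `valence` and
#'   `arousal` ranges `c(lo, hi)` on the 1-9 scale.
#' @param seed integer master seed; all randomness derives from it.
#' @param duration_s,fs trial geometry (default 60 s at 128 Hz).
#' @param deap_shape if `TRUE`, prepend a 3-second baseline segment and append
#'   8 noise-only peripheral channels so each trial matches the raw DEAP
#'   40-channel x 63-second layout (requires 32-channel specs).
#' @param subject_gain_sd,subject_noise_sd log-scale standard deviations of
#'   the per-subject gain and noise multipliers.
#' @return object of class `synthetic_study`: list with `subjects` (list of
#'   [subject_dataset()]), `classes` (subjects x trials character matrix of
#'   true classes), `truth` (the class specs), `seed`.
#' @export
generate_study <- function(n_subjects, n_trials, class_specs, rating_map,
                           seed = 1, duration_s = 60, fs = 128,
                           deap_shape = FALSE,
                           subject_gain_sd = 0.2, subject_noise_sd = 0.2) {
  cls <- names(class_specs)
  if (is.null(cls) || !all(cls %in% names(rating_map)))
    stop("class_specs and rating_map must be named consistently")
  nch <- unique(vapply(class_specs, function(s) s$n_channels, numeric(1)))
  if (length(nch) != 1)
    stop("all class specs must have the same channel count")
  if (deap_shape && nch != 32)
    stop("deap_shape requires 32-channel specs")
  base_s <- if (deap_shape) 3 else 0
  channel_names <- if (nch == 32) deap_channel_names()
                   else sprintf("Ch%02d", seq_len(nch))

  subjects <- vector("list", n_subjects)
  class_mat <- matrix(NA_character_, n_subjects, n_trials)
  for (s in seq_len(n_subjects)) {
    s_seed <- derive_seed(seed, 101, s)
    per <- with_seed(s_seed, {
      gain <- stats::rlnorm(1, 0, subject_gain_sd)
      noise_mult <- stats::rlnorm(1, 0, subject_noise_sd)
      order_cls <- sample(rep(cls, length.out = n_trials))
      list(gain = gain, noise_mult = noise_mult, order = order_cls)
    })
    trials <- vector("list", n_trials)
    val <- aro <- numeric(n_trials)
    for (tr in seq_len(n_trials)) {
      cl <- per$order[tr]
      sp <- class_specs[[cl]]
      sp$noise_sd <- sp$noise_sd * per$noise_mult
      t_seed <- derive_seed(seed, 211, s, tr)
      rec <- generate_trial(sp, duration_s + base_s, fs, t_seed,
                            channel_names = channel_names)
      rec$data <- rec$data * per$gain
      if (deap_shape) {
        extra <- with_seed(derive_seed(seed, 223, s, tr),
                           matrix(stats::rnorm(8 * ncol(rec$data)), 8))
        rec <- trial_recording(rbind(rec$data, extra), fs,
                               deap_channel_names(peripheral = TRUE))
      }
      trials[[tr]] <- rec
      r <- with_seed(derive_seed(seed, 227, s, tr), {
        rm_ <- rating_map[[cl]]
        c(stats::runif(1, rm_$valence[1], rm_$valence[2]),
          stats::runif(1, rm_$arousal[1], rm_$arousal[2]))
      })
      val[tr] <- r[1]
      aro[tr] <- r[2]
      class_mat[s, tr] <- cl
    }
    subjects[[s]] <- subject_dataset(trials,
                                     data.frame(valence = val, arousal = aro))
  }
  structure(list(subjects = subjects, classes = class_mat,
                 truth = class_specs, seed = seed),
            class = "synthetic_study")
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat(sprintf("<synthetic_study> %d subjects x %d trials, %d channels, seed %d\n",
              length(x$subjects), ncol(x$classes),
              x$truth[[1]]$n_channels, x$seed))
  invisible(x)
}

#' The package's reference synthetic study
#'
#' A 6-subject x 20-trial, 16-channel, 60-second study whose two classes
#' differ only in the density of their planted alpha-band coupling graphs:
#' the low-valence class has 4 planted edges (a 4-channel community), the
#' high-valence class 16 (a dense 7-channel community), both at coupling
#' strength 1 with broadband noise sd 0.2 and intrinsic oscillation sd 0.2
#' (so the shared community envelope dominates each channel's independent
#' envelope fluctuations). Coupling alternates on/off in
#' 2-second blocks (50% duty), with the two classes in anti-phase —
#' stimulus-locked second-scale coupling dynamics that short sliding windows
#' resolve and a whole-trial static network averages away. The truth
#' graphs are fixed design constants; `seed` varies only the signals,
#' subject effects and ratings. The planted graphs
#' are fixed design constants (drawn once from an internal constant seed);
#' `seed` varies only the signals, subject effects and ratings. Ratings are
#' drawn from 2-4 (low valence) and 6-8 (high valence), so label binarization
#' recovers the generating class exactly.
#'
#' @param seed integer seed for signals/ratings.
#' @param n_subjects,n_trials study size (defaults 6 x 20).
#' @return a `synthetic_study`.
#' @export
fixture_study <- function(seed = 1, n_subjects = 6, n_trials = 20) {
  nch <- 16
  # fixed truth graphs: a small community (4 edges on a 4-cycle) for the
  # low-valence class and a dense community (16 edges on 7 channels) for the
  # high-valence class
  lv_edges <- rbind(c(1, 5), c(5, 9), c(9, 13), c(13, 1))
  hv_nodes <- c(2, 4, 6, 8, 10, 12, 14)
  hv_all <- t(utils::combn(hv_nodes, 2))
  hv_edges <- hv_all[1:16, ]
  specs <- list(
    LV = coupling_spec(nch, lv_edges,
                       coupling_strength = 1, band = "alpha",
                       noise_sd = 0.2, osc_sd = 0.2, gate_block_s = 2,
                       gate_mode = "alternating", gate_offset_blocks = 0),
    HV = coupling_spec(nch, hv_edges,
                       coupling_strength = 1, band = "alpha",
                       noise_sd = 0.2, osc_sd = 0.2, gate_block_s = 2,
                       gate_mode = "alternating", gate_offset_blocks = 1))
  ratings <- list(
    LV = list(valence = c(2, 4), arousal = c(2, 8)),
    HV = list(valence = c(6, 8), arousal = c(2, 8)))
  generate_study(n_subjects, n_trials, specs, ratings, seed = seed)
}

#' Write a synthetic study to disk in a DEAP-style layout
#'
#' One file per subject (`s01.mat`, `s02.mat`, ... or `s01.dat` for the
#' pickled dialect), each holding `data` (trials x channels x samples) and
#' `labels` (trials x 4) arrays, i.e. exactly what [load_subject()] reads.
#'
#' @param study a `synthetic_study`.
#' @param dir output directory (created if needed).
#' @param dialect `"matlab"` or `"python"`.
#' @return character vector of file paths, invisibly.
#' @export
write_study <- function(study, dir, dialect = c("matlab", "python")) {
  dialect <- match.arg(dialect)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ext <- if (dialect == "matlab") "mat" else "dat"
  paths <- character(length(study$subjects))
  for (s in seq_along(study$subjects)) {
    paths[s] <- file.path(dir, sprintf("s%02d.%s", s, ext))
    write_subject(study$subjects[[s]], paths[s], dialect)
  }
  invisible(paths)
}
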