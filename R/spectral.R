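# Complex Morlet decomposition into the four rhythms, amplitude/phase
# extraction, inter-band difference signals and sliding-window segmentation.

#' Default rhythm definitions
#'
#' Theta 4-8 Hz, alpha 8-12 Hz, beta 12-32 Hz, gamma 32-42 Hz.
#'
#' @return data frame with columns `name`, `low`, `high` (Hz).
#' @export
band_definitions <- function() {
  data.frame(name = c("theta", "alpha", "beta", "gamma"),
             low  = c(4, 8, 12, 32),
             high = c(8, 12, 32, 42))
}

#' Wrap angles to (-pi, pi]
#'
#' @param x numeric angles in radians.
#' @return wrapped angles in (-pi, pi].
#' @export
wrap_phase <- function(x) {
  y <- x %% (2 * pi)          # [0, 2*pi)
  y[y > pi] <- y[y > pi] - 2 * pi
  y
}

#' Complex Morlet decomposition of one rhythm
#'
#' Convolves each channel with a complex Morlet wavelet centred at the band
#' midpoint. One wavelet is used per band; its Gaussian spectral standard
#' deviation defaults to `(high - low) / 4`, placing about 95% of the
#' wavelet's energy inside the band. The convolution is carried out in the
#' frequency domain (multiplication by the wavelet's Gaussian spectrum on
#' positive frequencies only), which also yields the analytic signal, after
#' reflect-padding each channel by one wavelet length (6 temporal standard
#' deviations) to control edge effects. Amplitude is the modulus of the
#' analytic signal and phase its argument (0 where the amplitude is exactly
#' zero).
#'
#' @param tr a [trial_recording()] (or plain channels x samples matrix with an
#'   `fs` attribute supplied via the `fs` argument).
#' @param band one row of [band_definitions()] (list/data frame with `name`,
#'   `low`, `high`), or a band name.
#' @param cycles optional number of wavelet cycles; overrides the default
#'   bandwidth (`cycles = f0 / sigma_f`, so larger values narrow the filter).
#' @param fs sampling rate, only needed when `tr` is a bare matrix.
#' @return object of class `band_analytic` with fields `amplitude` and
#'   `phase` (channels x samples), plus `band`.
#' @export
morlet_decompose <- function(tr, band, cycles = NULL, fs = NULL) {
  if (inherits(tr, "trial_recording")) {
    x <- tr$data
    fs <- tr$fs
  } else {
    x <- as.matrix(tr)
    if (is.null(fs)) stop("fs must be given for matrix input")
  }
  if (is.character(band)) {
    bd <- band_definitions()
    band <- as.list(bd[match(band, bd$name), ])
    if (is.na(band$low)) stop("unknown band name")
  }
  band <- as.list(band)
  if (band$high >= fs / 2)
    stop("band '", band$name, "' upper edge ", band$high,
         " Hz is at or above Nyquist (", fs / 2, " Hz)")
  f0 <- (band$low + band$high) / 2
  sigma_f <- if (is.null(cycles)) (band$high - band$low) / 4 else f0 / cycles
  sigma_t <- 1 / (2 * pi * sigma_f)
  npad <- min(ncol(x) - 1L, as.integer(ceiling(6 * sigma_t * fs)))

  n <- ncol(x)
  idx <- c(seq(npad + 1L, 2L, by = -1L), seq_len(n),
           seq(n - 1L, n - npad, by = -1L))
  xp <- x[, idx, drop = FALSE]
  # zero-extend to an FFT-friendly composite length; the extension sits
  # beyond the reflect pad, outside the retained region
  np <- stats::nextn(ncol(xp), c(2, 3, 5))
  if (np > ncol(xp))
    xp <- cbind(xp, matrix(0, nrow(xp), np - ncol(xp)))
  f <- (seq_len(np) - 1L) / np * fs
  f[f > fs / 2] <- f[f > fs / 2] - fs
  h <- exp(-(f - f0)^2 / (2 * sigma_f^2))
  h[f > 0] <- 2 * h[f > 0]
  h[f < 0] <- 0

  ft <- stats::mvfft(t(xp))
  an <- t(stats::mvfft(ft * h, inverse = TRUE)) / np
  an <- an[, (npad + 1L):(npad + n), drop = FALSE]

  amp <- Mod(an)
  ph <- Arg(an)
  ph[amp == 0] <- 0
  dimnames(amp) <- dimnames(ph) <- dimnames(x)
  structure(list(amplitude = amp, phase = ph, band = band$name),
            class = "band_analytic")
}

# fixed ordering of the six band pairs, higher band first (alpha_theta, ...)
band_pair_names <- function() {
  b <- band_definitions()$name
  out <- character(0)
  for (hi in 2:4) for (lo in seq_len(hi - 1L))
    out <- c(out, paste(b[hi], b[lo], sep = "_"))
  out
}

#' Inter-band amplitude and phase difference signals
#'
#' For each of the 6 unordered band pairs, forms the amplitude difference
#' (higher band minus lower band) and the phase difference (wrapped to
#' (-pi, pi]), giving 12 difference signals per trial. Signal ids follow the
#' `mode_higher_lower` convention, e.g. `amp_alpha_theta`,
#' `phase_gamma_beta`; the 6 amplitude signals come first.
#'
#' @param analytics named list of the four `band_analytic` objects (names
#'   `theta`, `alpha`, `beta`, `gamma`).
#' @param wrap if `FALSE`, phase differences are raw subtractions instead of
#'   being wrapped to (-pi, pi].
#' @return named list of 12 `difference_signal` objects, each with fields
#'   `values` (channels x samples), `pair`, `mode`.
#' @export
band_differences <- function(analytics, wrap = TRUE) {
  bands <- band_definitions()$name
  if (!all(bands %in% names(analytics)))
    stop("analytics must contain all four bands: ",
         paste(bands, collapse = ", "))
  shp <- dim(analytics[[bands[1]]]$amplitude)
  for (b in bands)
    if (!identical(dim(analytics[[b]]$amplitude), shp))
      stop("band analytics have mismatched shapes")
  mk <- function(values, pair, mode) {
    structure(list(values = values, pair = pair, mode = mode),
              class = "difference_signal")
  }
  out <- list()
  for (mode in c("amp", "phase")) {
    for (hi in 2:4) for (lo in seq_len(hi - 1L)) {
      pair <- paste(bands[hi], bands[lo], sep = "_")
      v <- if (mode == "amp") {
        analytics[[bands[hi]]]$amplitude - analytics[[bands[lo]]]$amplitude
      } else {
        d <- analytics[[bands[hi]]]$phase - analytics[[bands[lo]]]$phase
        if (wrap) wrap_phase(d) else d
      }
      out[[paste(mode, pair, sep = "_")]] <- mk(v, pair, mode)
    }
  }
  out
}

#' Segment a signal into non-overlapping windows
#'
#' Splits the channels x samples matrix into `duration / window_s` contiguous
#' non-overlapping windows. Partial windows are not allowed: the duration must
#' be divisible by the window length.
#'
#' @param sig a `difference_signal`, `trial_recording`, or channels x samples
#'   matrix.
#' @param window_s window length in seconds.
#' @param fs sampling rate (required for bare matrices).
#' @return list of channels x (window_s * fs) matrices, in temporal order.
#' @export
segment_windows <- function(sig, window_s, fs = NULL) {
  x <- if (inherits(sig, "difference_signal")) sig$values
       else if (inherits(sig, "trial_recording")) { fs <- sig$fs; sig$data }
       else as.matrix(sig)
  if (is.null(fs)) stop("fs must be given for matrix input")
  wlen <- window_s * fs
  if (abs(wlen - round(wlen)) > 1e-9)
    stop("window_s * fs must be an integer number of samples")
  wlen <- as.integer(round(wlen))
  n <- ncol(x)
  if (n %% wlen != 0)
    stop("signal length (", n, " samples) is not divisible by the window (",
         wlen, " samples); partial windows are not allowed")
  k <- n %/% wlen
  lapply(seq_len(k), function(i)
    x[, ((i - 1L) * wlen + 1L):(i * wlen), drop = FALSE])
}
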