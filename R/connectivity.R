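# Histogram mutual information between channel pairs and positional-threshold
# binarization into simple graphs.

# equal-width binning over [min(x), max(x)]; a constant vector falls in bin 1
discretize_uniform <- function(x, n_bins) {
  lo <- min(x)
  hi <- max(x)
  if (hi <= lo) return(rep(1L, length(x)))
  b <- as.integer(floor((x - lo) / (hi - lo) * n_bins)) + 1L
  b[b > n_bins] <- n_bins
  b
}

entropy_from_counts <- function(cnt) {
  n <- sum(cnt)
  p <- cnt[cnt > 0] / n
  -sum(p * log(p))
}

#' Histogram entropy of a sample
#'
#' Shannon entropy (in nats) of the equal-width histogram of `x` over
#' `[min(x), max(x)]`, with the convention `0 * log(0) = 0`. A constant vector
#' has zero entropy.
#'
#' @param x numeric sample vector.
#' @param n_bins number of histogram bins (>= 2).
#' @return entropy in nats.
#' @export
marginal_entropy <- function(x, n_bins = 8) {
  if (length(x) == 0) stop("empty input")
  if (n_bins < 2) stop("n_bins must be >= 2")
  entropy_from_counts(tabulate(discretize_uniform(x, n_bins), n_bins))
}

#' Histogram mutual information between two samples
#'
#' MI(x, y) = H(x) + H(y) - H(x, y) in nats, with all entropies estimated from
#' equal-width histograms (`n_bins` per axis; the joint uses the
#' `n_bins` x `n_bins` product grid). The estimate is clamped at zero, where
#' tiny negative values can otherwise arise from floating-point cancellation.
#'
#' @param x,y numeric vectors of equal length.
#' @param n_bins histogram bins per variable.
#' @return mutual information in nats (>= 0).
#' @export
mutual_information <- function(x, y, n_bins = 8) {
  if (length(x) != length(y))
    stop("x and y must have the same length (", length(x),
         " vs ", length(y), ")")
  dx <- discretize_uniform(x, n_bins)
  dy <- discretize_uniform(y, n_bins)
  hx <- entropy_from_counts(tabulate(dx, n_bins))
  hy <- entropy_from_counts(tabulate(dy, n_bins))
  hxy <- entropy_from_counts(tabulate((dx - 1L) * n_bins + dy, n_bins * n_bins))
  max(0, hx + hy - hxy)
}

#' Mutual-information connectivity matrix for one window
#'
#' Computes the symmetric channels x channels MI matrix for one time window.
#' Off-diagonal entries are pairwise histogram MI; the diagonal holds each
#' channel's marginal entropy (the self-MI).
#'
#' @param window channels x samples numeric matrix (>= 2 channels, >= 2
#'   samples).
#' @param n_bins histogram bins per variable (default 8; short windows make
#'   finer binning unstable).
#' @return object of class `connectivity_matrix` with fields `values`
#'   (symmetric matrix, nats) and `n_bins`.
#' @export
connectivity_matrix <- function(window, n_bins = 8) {
  x <- as.matrix(window)
  n_ch <- nrow(x)
  ns <- ncol(x)
  if (n_ch < 2) stop("need at least 2 channels")
  if (ns < 2) stop("need at least 2 samples per window")

  D <- matrix(0L, n_ch, ns)
  for (i in seq_len(n_ch)) D[i, ] <- discretize_uniform(x[i, ], n_bins)

  # marginal entropies, one tabulate over channel-offset codes
  mh <- entropy_rows(D, n_bins)

  pairs <- utils::combn(n_ch, 2L)
  i1 <- pairs[1L, ]
  i2 <- pairs[2L, ]
  codes <- (D[i1, , drop = FALSE] - 1L) * n_bins + D[i2, , drop = FALSE]
  hj <- entropy_rows(codes, n_bins * n_bins)

  mi <- pmax(0, mh[i1] + mh[i2] - hj)
  M <- matrix(0, n_ch, n_ch, dimnames = list(rownames(x), rownames(x)))
  M[cbind(i1, i2)] <- mi
  M[cbind(i2, i1)] <- mi
  diag(M) <- mh
  structure(list(values = M, n_bins = n_bins), class = "connectivity_matrix")
}

# entropy of each row of an integer-coded matrix (values in 1..n_codes),
# via a single tabulate over row-offset codes
entropy_rows <- function(D, n_codes) {
  nr <- nrow(D)
  ns <- ncol(D)
  off <- (seq_len(nr) - 1L) * n_codes
  cnt <- tabulate(D + off, nbins = nr * n_codes)
  cm <- matrix(cnt, nrow = n_codes)
  p <- cm / ns
  plp <- p * log(p)
  plp[cm == 0L] <- 0
  -colSums(plp)
}

#' Binarize a connectivity matrix at a positional threshold
#'
#' All `n^2` entries of the matrix (diagonal included) are sorted ascending
#' and the value at 1-based position `floor(q * n^2)` (clamped to at least 1)
#' becomes the threshold: entries strictly greater than it become edges,
#' everything else (including ties with the threshold) is discarded. For a
#' 32-channel matrix at `q = 0.3` the threshold sits at position 307 of the
#' 1024 sorted values. The diagonal of the result is forced to zero so the
#' graph is simple. Thresholding is per matrix, which makes the edge density
#' comparable across subjects despite inter-individual MI scale differences.
#'
#' @param cm a `connectivity_matrix` or plain symmetric numeric matrix.
#' @param q positional threshold fraction in (0, 1); default 0.3.
#' @return object of class `adjacency_matrix` with fields `values` (binary
#'   matrix), `q`, `threshold_index`, `threshold_value`.
#' @export
positional_threshold <- function(cm, q = 0.3) {
  if (q <= 0 || q >= 1) stop("q must be in (0, 1)")
  M <- if (inherits(cm, "connectivity_matrix")) cm$values else as.matrix(cm)
  n <- nrow(M)
  v <- sort(as.vector(M))
  idx <- max(1L, as.integer(floor(q * n * n)))
  thr <- v[idx]
  A <- (M > thr) * 1
  diag(A) <- 0
  structure(list(values = A, q = q, threshold_index = idx,
                 threshold_value = thr),
            class = "adjacency_matrix")
}

#' Export a binary network as an edge list
#'
#' Writes (or returns) the upper-triangle edges of a binary adjacency matrix
#' as a two-column table of channel names, a plain-text interchange format for
#' graph tooling.
#'
#' @param adj `adjacency_matrix` or binary matrix with dimnames.
#' @param path optional file path; if given, a tab-separated file is written.
#' @return data frame with columns `from`, `to` (invisibly when writing).
#' @export
adjacency_edge_list <- function(adj, path = NULL) {
  A <- if (inherits(adj, "adjacency_matrix")) adj$values else as.matrix(adj)
  nm <- rownames(A) %||% sprintf("Ch%02d", seq_len(nrow(A)))
  idx <- which(upper.tri(A) & A > 0, arr.ind = TRUE)
  el <- data.frame(from = nm[idx[, 1]], to = nm[idx[, 2]])
  if (!is.null(path)) {
    utils::write.table(el, path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(el))
  }
  el
}
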