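# mRMR feature selection and the SVM training/prediction protocol.

# equal-frequency discretization of one column into at most n_levels levels;
# rank-based so features with few distinct values (including binary ones)
# keep their levels instead of collapsing
discretize_quantile <- function(x, n_levels = 3) {
  r <- rank(x, ties.method = "average")
  as.integer(cut(r, breaks = n_levels, labels = FALSE))
}

# MI (nats) between every column of an integer-coded matrix D (levels 1..B)
# and a grouping vector g (levels 1..L), fully vectorized over columns
mi_columns <- function(D, g, B, L) {
  n <- nrow(D)
  nf <- ncol(D)
  Y <- matrix(0, n, L)
  Y[cbind(seq_len(n), g)] <- 1
  nl <- colSums(Y)
  mi <- numeric(nf)
  for (b in seq_len(B)) {
    Ib <- (D == b) * 1
    nb <- colSums(Ib)             # per-feature count at level b
    cl <- crossprod(Y, Ib)        # L x nf joint counts
    for (l in seq_len(L)) {
      c_ <- cl[l, ]
      pos <- c_ > 0
      if (any(pos))
        mi[pos] <- mi[pos] +
          c_[pos] / n * log(c_[pos] * n / (nb[pos] * nl[l]))
    }
  }
  pmax(mi, 0)
}

# per-column maximum level after discretization is <= n_bins; recode a single
# selected column as a grouping vector with its own level count
column_levels <- function(v) {
  u <- sort(unique(v))
  list(g = match(v, u), L = length(u))
}

#' Greedy mRMR feature selection
#'
#' Max-relevance min-redundancy selection on quantile-discretized features.
#' The first feature maximizes MI(feature; label); each subsequent feature
#' maximizes relevance minus the mean MI against the already-selected set
#' (MID, the difference criterion) or the relevance/redundancy quotient
#' (MIQ). Ties break to the lowest original column index, so the selection is
#' deterministic and invariant to feature shuffling modulo that index order.
#'
#' @param X trials x features numeric matrix.
#' @param y label vector (factor or coercible; at least 2 classes).
#' @param k number of features to select (`k <= ncol(X)`).
#' @param n_bins quantile-discretization levels for the features (default 3).
#' @param variant `"MID"` (difference, default) or `"MIQ"` (quotient).
#' @param recorder optional environment used by the leakage audit; the row
#'   ids this call reads are logged there.
#' @param row_ids row identities of `X` for the audit log.
#' @return object of class `selection_result`: list with `indices` (ordered,
#'   unique), `scores` (criterion value at each step), `k`.
#' @export
mrmr_select <- function(X, y, k, n_bins = 3, variant = c("MID", "MIQ"),
                        recorder = NULL, row_ids = NULL) {
  variant <- match.arg(variant)
  X <- as.matrix(X)
  y <- as.factor(y)
  if (nlevels(droplevels(y)) < 2) stop("y must contain at least 2 classes")
  if (k > ncol(X)) stop("k (", k, ") exceeds feature count (", ncol(X), ")")
  log_access(recorder, "mrmr", row_ids %||% seq_len(nrow(X)))

  D <- matrix(0L, nrow(X), ncol(X))
  for (j in seq_len(ncol(X))) D[, j] <- discretize_quantile(X[, j], n_bins)

  rel <- mi_columns(D, as.integer(droplevels(y)), n_bins,
                    nlevels(droplevels(y)))
  selected <- integer(k)
  scores <- numeric(k)
  red_sum <- numeric(ncol(X))
  avail <- rep(TRUE, ncol(X))

  selected[1] <- which.max(rel)
  scores[1] <- rel[selected[1]]
  avail[selected[1]] <- FALSE
  if (k > 1) {
    for (s in 2:k) {
      gl <- column_levels(D[, selected[s - 1]])
      red_sum <- red_sum + mi_columns(D, gl$g, n_bins, gl$L)
      crit <- if (variant == "MID") rel - red_sum / (s - 1)
              else rel / (red_sum / (s - 1) + 1e-12)
      crit[!avail] <- -Inf
      selected[s] <- which.max(crit)
      scores[s] <- crit[selected[s]]
      avail[selected[s]] <- FALSE
    }
  }
  structure(list(indices = selected, scores = scores, k = k,
                 variant = variant, n_bins = n_bins),
            class = "selection_result")
}

#' Classifier protocol configuration
#'
#' @param c_grid SVM cost grid (default `2^(-5), 2^(-3), ..., 2^5`).
#' @param kernels kernel set searched (default linear and radial).
#' @param n_folds stratified CV folds for the grid search (default 5).
#' @param n_repeats number of repetitions whose test-class probabilities are
#'   averaged (default 100; each repetition redraws the CV folds).
#' @param standardize z-score features on training statistics before fitting.
#' @param seed base seed; repetition `r` uses a fold seed derived from
#'   `seed + r`.
#' @return list of class `classifier_config`.
#' @export
classifier_config <- function(c_grid = 2^seq(-5, 5, by = 2),
                              kernels = c("linear", "radial"),
                              n_folds = 5, n_repeats = 100,
                              standardize = TRUE, seed = 1) {
  if (n_folds < 2) stop("n_folds must be >= 2")
  if (n_repeats < 1) stop("n_repeats must be >= 1")
  structure(list(c_grid = c_grid, kernels = kernels, n_folds = n_folds,
                 n_repeats = n_repeats, standardize = standardize,
                 seed = seed),
            class = "classifier_config")
}

# stratified fold assignment: within each class, shuffle then deal round-robin
stratified_folds <- function(y, n_folds, seed) {
  fold <- integer(length(y))
  with_seed(seed, {
    for (cl in levels(y)) {
      idx <- which(y == cl)
      idx <- idx[sample.int(length(idx))]
      fold[idx] <- rep_len(seq_len(n_folds), length(idx))
    }
  })
  fold
}

svm_fit <- function(X, y, kernel, cost, gamma, probability = FALSE) {
  e1071::svm(x = X, y = y, kernel = kernel, cost = cost, gamma = gamma,
             probability = probability, scale = FALSE)
}

#' Train the SVM protocol and predict test probabilities
#'
#' Implements the repeated grid-searched protocol: per repetition, a
#' stratified `n_folds`-fold cross-validation on the training set scores every
#' (kernel, cost) cell of the grid by CV accuracy; the winning cell is refit
#' on the full training set and class probabilities are predicted for the test
#' set. The per-repetition probabilities are averaged over `n_repeats`
#' repetitions (each with freshly drawn folds) and the hard label is the
#' arg-max of the averaged probabilities. Features are z-scored on training
#' statistics (constant features get unit scale); the radial kernel width uses
#' the variance-scaled heuristic `1 / (p * var(X_train))`.
#'
#' @param X_train,y_train training matrix and labels (all classes present).
#' @param X_test test matrix with the same columns as `X_train`.
#' @param cfg a [classifier_config()].
#' @param recorder,row_ids leakage-audit hooks: row identities of `X_train`.
#' @return list with `probabilities` (test x classes, rows sum to 1),
#'   `labels` (factor), `chosen` (data frame of per-repetition winning kernel
#'   and cost), `cv_table` (first repetition's per-cell CV accuracies).
#' @export
fit_and_predict <- function(X_train, y_train, X_test, cfg = classifier_config(),
                            recorder = NULL, row_ids = NULL) {
  X_train <- as.matrix(X_train)
  X_test <- as.matrix(X_test)
  if (ncol(X_train) != ncol(X_test))
    stop("train/test feature dimensions differ")
  y <- droplevels(as.factor(y_train))
  if (nlevels(y) < 2) stop("training set must contain at least 2 classes")
  rows <- row_ids %||% seq_len(nrow(X_train))

  if (cfg$standardize) {
    log_access(recorder, "standardize", rows)
    mu <- colMeans(X_train)
    sdv <- apply(X_train, 2, stats::sd)
    sdv[sdv == 0] <- 1
    X_train <- sweep(sweep(X_train, 2, mu), 2, sdv, "/")
    X_test <- sweep(sweep(X_test, 2, mu), 2, sdv, "/")
  }
  v <- stats::var(as.vector(X_train))
  gamma <- if (v > 0) 1 / (ncol(X_train) * v) else 1 / ncol(X_train)

  grid <- expand.grid(kernel = cfg$kernels, cost = cfg$c_grid,
                      stringsAsFactors = FALSE)
  log_access(recorder, "grid_search", rows)

  lev <- levels(y)
  prob_sum <- matrix(0, nrow(X_test), length(lev),
                     dimnames = list(NULL, lev))
  chosen <- data.frame(kernel = character(cfg$n_repeats),
                       cost = numeric(cfg$n_repeats))
  cv_table <- NULL
  for (r in seq_len(cfg$n_repeats)) {
    fold <- stratified_folds(y, cfg$n_folds, derive_seed(cfg$seed, 7, r))
    cv_acc <- numeric(nrow(grid))
    for (g in seq_len(nrow(grid))) {
      correct <- 0L
      for (f in seq_len(cfg$n_folds)) {
        tr <- fold != f
        te <- fold == f
        if (!any(te) || nlevels(droplevels(y[tr])) < 2) next
        m <- svm_fit(X_train[tr, , drop = FALSE], y[tr],
                     grid$kernel[g], grid$cost[g], gamma)
        correct <- correct +
          sum(predict(m, X_train[te, , drop = FALSE]) == y[te])
      }
      cv_acc[g] <- correct / length(y)
    }
    best <- which.max(cv_acc)
    if (r == 1) cv_table <- cbind(grid, cv_accuracy = cv_acc)
    chosen$kernel[r] <- grid$kernel[best]
    chosen$cost[r] <- grid$cost[best]
    m <- svm_fit(X_train, y, grid$kernel[best], grid$cost[best], gamma,
                 probability = TRUE)
    p <- attr(predict(m, X_test, probability = TRUE), "probabilities")
    prob_sum <- prob_sum + p[, lev, drop = FALSE]
  }
  prob <- prob_sum / cfg$n_repeats
  labels <- factor(lev[max.col(prob, ties.method = "first")], levels = lev)
  list(probabilities = prob, labels = labels, chosen = chosen,
       cv_table = cv_table)
}
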