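# Histogram entropy/MI estimation and positional-threshold binarization.

test_that("histogram entropy matches hand-evaluated cases", {
  expect_equal(marginal_entropy(rep(3.7, 50), 8), 0)
  expect_equal(marginal_entropy(rep(c(0, 1), 50), 2), log(2))
  expect_equal(marginal_entropy(rep(c(0.1, 0.35, 0.6, 0.85), 25), 4), log(4))
  expect_error(marginal_entropy(numeric(0)), "empty")
  expect_error(marginal_entropy(1:5, n_bins = 1), "n_bins")
})

test_that("mutual information matches closed forms and is symmetric", {
  x <- rnorm(500)
  expect_equal(mutual_information(x, rep(1, 500), 8), 0)
  u <- rep(c(0, 1), 250)
  expect_equal(mutual_information(u, u, 2), log(2))
  expect_equal(mutual_information(x, x^2, 8), mutual_information(x^2, x, 8))
  expect_error(mutual_information(1:5, 1:6), "same length")
})

test_that("production MI equals the literal triple-loop oracle", {
  set.seed(42)
  for (r in 1:100) {
    n <- sample(50:200, 1)
    B <- sample(c(2, 4, 8), 1)
    x <- rnorm(n)
    y <- 0.5 * x + rnorm(n)
    expect_equal(mutual_information(x, y, B), oracle_mi(x, y, B),
                 tolerance = 1e-12)
  }
})

test_that("independent noise cannot inflate estimated MI", {
  set.seed(7)
  n <- 10000
  x <- rnorm(n)
  y <- x + 0.3 * rnorm(n)
  mi_clean <- mutual_information(x, y, 8)
  mi_noisy <- mutual_information(x, y + rnorm(n), 8)
  expect_lt(mi_noisy, mi_clean + 0.02)  # small margin for estimator noise
})

test_that("connectivity matrices are symmetric with entropies on the diagonal", {
  set.seed(3)
  w <- matrix(rnorm(32 * 256), 32)
  w[2, ] <- w[1, ]  # duplicated channel
  cm <- connectivity_matrix(w, 8)
  expect_equal(dim(cm$values), c(32L, 32L))
  expect_equal(cm$values, t(cm$values))
  expect_true(all(cm$values >= 0))
  for (i in c(1, 5, 32))
    expect_equal(cm$values[i, i], marginal_entropy(w[i, ], 8))
  expect_equal(cm$values[1, 2], marginal_entropy(w[1, ], 8))
  # pairwise entries equal the scalar estimator
  expect_equal(cm$values[3, 7], mutual_information(w[3, ], w[7, ], 8))
  expect_error(connectivity_matrix(w[1, , drop = FALSE]), "2 channels")
})

test_that("a planted edge ranks in the top decile of pairwise MI", {
  # strong shared source relative to the intrinsic oscillation, as in the
  # reference fixture: planted contrast must survive a short window
  sp <- coupling_spec(32, matrix(c(4, 9), ncol = 2),
                      coupling_strength = 0.9, noise_sd = 0.1, osc_sd = 0.3)
  tr <- generate_trial(sp, 2, 128, seed = 77)  # one 2-s window
  M <- connectivity_matrix(tr$data, 8)$values
  off <- M[upper.tri(M)]
  expect_gte(M[4, 9], quantile(off, 0.9))
})

test_that("the positional threshold picks the floor(q n^2) order statistic", {
  set.seed(11)
  M <- matrix(rnorm(1024), 32)
  M <- (M + t(M)) / 2
  adj <- positional_threshold(M, 0.3)
  expect_equal(adj$threshold_index, 307L)
  expect_equal(adj$threshold_value, sort(as.vector(M))[307])
  expect_equal(diag(adj$values), rep(0, 32))
  expect_equal(adj$values, t(adj$values))

  # all-equal matrix: nothing strictly exceeds the threshold
  expect_equal(sum(positional_threshold(matrix(1, 8, 8), 0.3)$values), 0)

  # 4 x 4 toy with 16 distinct entries, brute-force count
  M4 <- matrix(sample(16) / 16, 4, 4)
  thr <- sort(as.vector(M4))[floor(0.3 * 16)]  # 4th smallest
  expect_equal(positional_threshold(M4, 0.3)$threshold_value, thr)
  expect_equal(sum(M4 > thr), 12)
  expect_error(positional_threshold(M4, 1.2), "in \\(0, 1\\)")
})

test_that("edge density tracks 1 - q up to floor and diagonal effects", {
  set.seed(19)
  for (q in c(0.3, 0.5, 0.7)) {
    n <- 20
    M <- matrix(runif(n * n), n)
    M <- (M + t(M)) / 2
    diag(M) <- runif(n, 1, 2)  # diagonal (self-entropy) dominates, as in MI
    adj <- positional_threshold(M, q)
    dens <- sum(adj$values) / (n * (n - 1))
    # n^2 - floor(q n^2) entries exceed the threshold, up to n on the diagonal
    expect_lt(abs(dens - (1 - q)), (n + 2) / (n * (n - 1)))
  }
})

test_that("binary networks export as channel-name edge lists", {
  A <- toy_path3()
  rownames(A) <- colnames(A) <- c("Fz", "Cz", "Pz")
  el <- adjacency_edge_list(A)
  expect_equal(nrow(el), 2)
  expect_setequal(paste(el$from, el$to), c("Fz Cz", "Cz Pz"))
  p <- tempfile()
  adjacency_edge_list(A, p)
  expect_equal(nrow(read.delim(p)), 2)
  unlink(p)
})
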