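# Independent brute-force oracles used to cross-check the production paths.

# literal histogram MI: explicit edge comparison binning and full joint table
oracle_bin <- function(v, B) {
  lo <- min(v)
  hi <- max(v)
  if (hi == lo) return(rep(1L, length(v)))
  edges <- lo + (seq_len(B + 1) - 1) * (hi - lo) / B
  out <- integer(length(v))
  for (s in seq_along(v)) {
    b <- 1L
    for (k in 2:B) if (v[s] >= edges[k]) b <- k
    out[s] <- b
  }
  out
}

oracle_entropy_counts <- function(cnt) {
  n <- sum(cnt)
  h <- 0
  for (c_ in cnt) if (c_ > 0) h <- h - (c_ / n) * log(c_ / n)
  h
}

oracle_mi <- function(x, y, B) {
  bx <- oracle_bin(x, B)
  by <- oracle_bin(y, B)
  n <- length(x)
  J <- matrix(0, B, B)
  for (s in seq_len(n)) J[bx[s], by[s]] <- J[bx[s], by[s]] + 1
  hx <- oracle_entropy_counts(tabulate(bx, B))
  hy <- oracle_entropy_counts(tabulate(by, B))
  hxy <- oracle_entropy_counts(as.vector(J))
  max(0, hx + hy - hxy)
}

# Floyd-Warshall distances and triple-loop graph metrics
oracle_distances <- function(A) {
  n <- nrow(A)
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  D[A > 0] <- 1
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n))
    if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
  D
}

oracle_global_eff <- function(A) {
  n <- nrow(A)
  if (n < 2) return(0)
  D <- oracle_distances(A)
  s <- 0
  for (i in seq_len(n)) for (j in seq_len(n))
    if (i != j && is.finite(D[i, j])) s <- s + 1 / D[i, j]
  s / (n * (n - 1))
}

oracle_local_eff <- function(A) {
  vapply(seq_len(nrow(A)), function(i) {
    nb <- which(A[i, ] > 0)
    if (length(nb) < 2) return(0)
    oracle_global_eff(A[nb, nb, drop = FALSE])
  }, numeric(1))
}

oracle_clustering <- function(A) {
  vapply(seq_len(nrow(A)), function(i) {
    nb <- which(A[i, ] > 0)
    d <- length(nb)
    if (d < 2) return(0)
    e <- 0
    for (a in seq_len(d - 1)) for (b in (a + 1):d)
      if (A[nb[a], nb[b]] > 0) e <- e + 1
    e / (d * (d - 1) / 2)
  }, numeric(1))
}

random_graph <- function(n, p) {
  A <- matrix(0, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    if (stats::runif(1) < p) A[i, j] <- A[j, i] <- 1
  A
}

# small named toy graphs
toy_k4 <- function() matrix(1, 4, 4) - diag(4)
toy_path3 <- function() {
  A <- matrix(0, 3, 3)
  A[1, 2] <- A[2, 1] <- A[2, 3] <- A[3, 2] <- 1
  A
}
toy_star <- function(leaves = 3) {
  A <- matrix(0, leaves + 1, leaves + 1)
  A[1, 2:(leaves + 1)] <- A[2:(leaves + 1), 1] <- 1
  A
}
toy_triangle <- function() matrix(1, 3, 3) - diag(3)
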