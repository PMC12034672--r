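# Graph-attribute metrics, feature blocks, edge-frequency aggregation.

test_that("hop-count distances handle complete, path and disconnected graphs", {
  expect_true(all(shortest_paths(toy_k4())[row(diag(4)) != col(diag(4))] == 1))
  D <- shortest_paths(toy_path3())
  expect_equal(D[1, 3], 2)
  two_dyads <- matrix(0, 4, 4)
  two_dyads[1, 2] <- two_dyads[2, 1] <- two_dyads[3, 4] <- two_dyads[4, 3] <- 1
  expect_equal(shortest_paths(two_dyads)[1, 3], Inf)
})

test_that("characteristic path length flags disconnected graphs", {
  expect_equal(characteristic_path_length(toy_k4()),
               list(value = 1, connected = TRUE))
  expect_equal(characteristic_path_length(toy_path3())$value, 4 / 3)
  edgeless <- matrix(0, 3, 3)
  lp <- characteristic_path_length(edgeless)
  expect_false(lp$connected)
  expect_equal(lp$value, Inf)
})

test_that("global efficiency matches hand-computed values and bounds", {
  expect_equal(global_efficiency(toy_k4()), 1)
  expect_equal(global_efficiency(matrix(0, 5, 5)), 0)
  expect_equal(global_efficiency(toy_path3()), 5 / 6)
  expect_error(global_efficiency(matrix(0, 1, 1)), "2 nodes")
})

test_that("local efficiency is the neighbour-subgraph global efficiency", {
  expect_equal(local_efficiency(toy_triangle(), 1), 1)
  expect_equal(local_efficiency(toy_star(3), 1), 0)     # hub of a star
  k4m <- toy_k4(); k4m[3, 4] <- k4m[4, 3] <- 0
  # node 1 still adjacent to all others; its neighbourhood is a 3-path
  expect_equal(local_efficiency(k4m, 1), 5 / 6)
  # literal variant keeps the node inside its own subgraph
  expect_equal(local_efficiency(toy_triangle(), 1, include_node = TRUE), 1)
  expect_gte(local_efficiency(k4m, 1, include_node = TRUE),
             local_efficiency(k4m, 1))
})

test_that("clustering coefficients count realized neighbour edges", {
  expect_equal(unname(clustering_coefficient(toy_triangle(), 1)), 1)
  expect_equal(unname(clustering_coefficient(toy_star(3), 1)), 0)
  A <- matrix(0, 4, 4)  # node 1 with neighbours 2,3,4; single edge 2-3
  A[1, 2:4] <- A[2:4, 1] <- 1
  A[2, 3] <- A[3, 2] <- 1
  expect_equal(unname(clustering_coefficient(A, 1)), 1 / 3)
})

test_that("production metrics agree with igraph on random graphs", {
  skip_if_not_installed("igraph")
  set.seed(23)
  for (r in 1:30) {
    n <- sample(4:12, 1)
    A <- random_graph(n, runif(1, 0.15, 0.9))
    g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
    expect_equal(global_efficiency(A), igraph::global_efficiency(g),
                 tolerance = 1e-12)
    # (igraph's local_efficiency measures distances in the graph minus the
    # vertex, a different variant; the neighbour-subgraph form is checked
    # against the brute-force oracle instead)
    ci <- igraph::transitivity(g, type = "local", isolates = "zero")
    expect_equal(unname(clustering_coefficient(A)), ci, tolerance = 1e-12)
  }
})

test_that("adding an edge never decreases global efficiency (n <= 5)", {
  for (n in 4:5) {
    n_pairs <- n * (n - 1) / 2
    pairs <- t(combn(n, 2))
    for (code in 0:(2^n_pairs - 1)) {
      bits <- as.integer(intToBits(code))[seq_len(n_pairs)]
      A <- matrix(0, n, n)
      A[pairs[bits == 1, , drop = FALSE]] <- 1
      A <- A + t(A)
      eg <- global_efficiency(A)
      missing_e <- which(bits == 0)
      for (m in missing_e) {
        A2 <- A
        A2[pairs[m, 1], pairs[m, 2]] <- A2[pairs[m, 2], pairs[m, 1]] <- 1
        expect_gte(global_efficiency(A2), eg)
      }
    }
  }
})

test_that("metrics are invariant (equivariant) under node relabelling", {
  set.seed(31)
  A <- random_graph(8, 0.4)
  p <- sample(8)
  Ap <- A[p, p]
  expect_equal(global_efficiency(Ap), global_efficiency(A), tolerance = 1e-12)
  expect_equal(unname(local_efficiency(Ap)), unname(local_efficiency(A))[p],
               tolerance = 1e-12)
  expect_equal(unname(clustering_coefficient(Ap)),
               unname(clustering_coefficient(A))[p], tolerance = 1e-12)
})

test_that("feature blocks have length 1 + 2n and vanish on edgeless graphs", {
  set.seed(5)
  expect_length(network_feature_vector(random_graph(32, 0.3)), 65)
  expect_length(network_feature_vector(random_graph(3, 0.5)), 7)
  expect_equal(unname(network_feature_vector(matrix(0, 6, 6))), rep(0, 13))
})

test_that("trial feature assembly enforces the 12 x (60/t) network count", {
  set.seed(6)
  nets120 <- replicate(120, random_graph(5, 0.4), simplify = FALSE)
  tf <- assemble_trial_features(nets120, window_s = 6)
  expect_length(tf, 120 * 11)
  expect_equal(nrow(attr(tf, "layout")), 120)
  nets12 <- replicate(12, random_graph(5, 0.4), simplify = FALSE)
  expect_length(assemble_trial_features(nets12, 60), 12 * 11)
  expect_error(assemble_trial_features(nets12, 6), "expected 120")
  # at the paper's geometry the trial vector has 12 * 10 * 65 = 7800 values
  nets32 <- replicate(120, random_graph(32, 0.3), simplify = FALSE)
  expect_length(assemble_trial_features(nets32, 6), 7800)
})

test_that("edge-frequency maps aggregate and retain strictly frequent edges", {
  set.seed(8)
  nets <- replicate(12, random_graph(6, 0.5), simplify = FALSE)
  m <- edge_frequency_map(nets)
  expect_equal(m$max_count, 12)
  expect_true(all(m$counts >= 0 & m$counts <= 12))
  expect_equal(m$counts, t(m$counts))
  expect_equal(diag(m$counts), rep(0, 6))
  # an edge present in every network survives any retention level < 1
  always <- matrix(0, 6, 6); always[1, 2] <- always[2, 1] <- 1
  nets_all <- lapply(nets, function(A) { A[1, 2] <- A[2, 1] <- 1; A })
  m3 <- edge_frequency_map(nets_all)
  expect_equal(retain_frequent_edges(m3, 0.8)$values[1, 2], 1)
  # count equal to p * max is discarded (strict inequality)
  half <- c(lapply(1:6, function(i) always), lapply(1:6, function(i) always * 0))
  m4 <- edge_frequency_map(half)
  expect_equal(retain_frequent_edges(m4, 0.5)$values[1, 2], 0)
  expect_error(edge_frequency_map(list()), "empty")
})
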