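# Graph-attribute features of binary networks: shortest paths, efficiencies,
# clustering, per-network 1 + 2*n feature blocks, and edge-frequency
# aggregation across networks.

as_adjacency <- function(adj) {
  A <- if (inherits(adj, "adjacency_matrix")) adj$values else as.matrix(adj)
  A <- (A != 0) * 1
  diag(A) <- 0
  A
}

#' Unweighted shortest-path (hop-count) distances
#'
#' Breadth-first distances on a simple undirected binary graph, computed by
#' boolean matrix powers. Disconnected pairs get `Inf`; `d(i, i) = 0`.
#'
#' @param adj `adjacency_matrix` or binary matrix.
#' @return numeric matrix of hop counts.
#' @export
shortest_paths <- function(adj) {
  A <- as_adjacency(adj)
  n <- nrow(A)
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  P <- A > 0
  step <- 1
  while (step <= n) {
    new <- P & is.infinite(D)
    if (!any(new)) break
    D[new] <- step
    P <- (P %*% A) > 0
    step <- step + 1
  }
  dimnames(D) <- dimnames(A)
  D
}

#' Characteristic path length
#'
#' Mean shortest-path length over ordered node pairs,
#' `Lp = sum(L_ij) / (N (N - 1))`. Meaningful only on connected graphs: with
#' any disconnected pair the value is infinite and the result is flagged,
#' which is why this quantity is computed but excluded from the feature
#' vectors built on thresholded (possibly disconnected) networks.
#'
#' @param adj `adjacency_matrix` or binary matrix.
#' @return list with `value` (`Inf` when disconnected) and `connected`
#'   (logical).
#' @export
characteristic_path_length <- function(adj) {
  D <- shortest_paths(adj)
  n <- nrow(D)
  off <- D[row(D) != col(D)]
  if (any(is.infinite(off)))
    return(list(value = Inf, connected = FALSE))
  list(value = sum(off) / (n * (n - 1)), connected = TRUE)
}

#' Global efficiency
#'
#' Mean inverse shortest-path length over ordered node pairs, with
#' `1 / Inf = 0` for disconnected pairs. Ranges from 0 (edgeless) to 1
#' (complete graph).
#'
#' @param adj `adjacency_matrix` or binary matrix with at least 2 nodes.
#' @return global efficiency in `[0, 1]`.
#' @export
global_efficiency <- function(adj) {
  A <- as_adjacency(adj)
  n <- nrow(A)
  if (n < 2) stop("global efficiency needs at least 2 nodes")
  D <- shortest_paths(A)
  inv <- 1 / D
  diag(inv) <- 0
  sum(inv) / (n * (n - 1))
}

#' Local efficiency
#'
#' Local efficiency of node `i` is the global efficiency of the subgraph
#' induced by the neighbours of `i` (node `i` itself excluded, the standard
#' Latora-Marchiori form); nodes with fewer than 2 neighbours have local
#' efficiency 0. Set `include_node = TRUE` for the variant in which the node
#' is kept inside its own subgraph.
#'
#' @param adj `adjacency_matrix` or binary matrix.
#' @param node node index, or `NULL` for all nodes.
#' @param include_node include node `i` in its neighbourhood subgraph.
#' @return numeric vector (or scalar) of local efficiencies in `[0, 1]`.
#' @export
local_efficiency <- function(adj, node = NULL, include_node = FALSE) {
  A <- as_adjacency(adj)
  one <- function(i) {
    nb <- which(A[i, ] > 0)
    if (length(nb) < 2) return(0)
    sub <- if (include_node) c(i, nb) else nb
    global_efficiency(A[sub, sub, drop = FALSE])
  }
  if (!is.null(node)) return(one(node))
  vapply(seq_len(nrow(A)), one, numeric(1))
}

#' Local clustering coefficient
#'
#' Fraction of realized edges among a node's neighbours,
#' `C_i = E_i / (D_i (D_i - 1) / 2)`; 0 for nodes of degree < 2.
#'
#' @param adj `adjacency_matrix` or binary matrix.
#' @param node node index, or `NULL` for all nodes.
#' @return numeric vector (or scalar) of clustering coefficients in `[0, 1]`.
#' @export
clustering_coefficient <- function(adj, node = NULL) {
  A <- as_adjacency(adj)
  d <- rowSums(A)
  tri <- diag(A %*% A %*% A) / 2   # edges among neighbours of each node
  ci <- ifelse(d < 2, 0, tri / (d * (d - 1) / 2))
  names(ci) <- rownames(A)
  if (!is.null(node)) ci[node] else ci
}

#' Feature block of one binary network
#'
#' Concatenates global efficiency (1 value), per-node local efficiency
#' (`n` values) and per-node clustering (`n` values), giving `1 + 2 n` values
#' per network — 65 for a 32-channel graph.
#'
#' @param adj `adjacency_matrix` or binary matrix.
#' @return named numeric vector `c(Eg, Eloc_..., Ci_...)`.
#' @export
network_feature_vector <- function(adj) {
  A <- as_adjacency(adj)
  nm <- rownames(A) %||% sprintf("Ch%02d", seq_len(nrow(A)))
  el <- local_efficiency(A)
  ci <- clustering_coefficient(A)
  out <- c(global_efficiency(A), el, ci)
  names(out) <- c("Eg", paste0("Eloc_", nm), paste0("Ci_", nm))
  out
}

#' Assemble one trial's feature vector from its networks
#'
#' Concatenates the per-network feature blocks of one trial in signal-major,
#' window-minor order. With 12 difference signals, `duration_s / window_s`
#' windows each and `1 + 2 n` features per network, a 32-channel, 60-second
#' trial at window length `t` yields `12 * (60 / t) * 65` values.
#'
#' @param networks list of `adjacency_matrix` objects (or binary matrices) in
#'   signal-major, window-minor order.
#' @param window_s window length in seconds.
#' @param duration_s trial duration in seconds (default 60).
#' @param n_signals number of difference signals (default 12).
#' @return object of class `trial_features`: a named numeric vector with a
#'   `layout` attribute (data frame with one row per network: `signal_index`,
#'   `window_index`).
#' @export
assemble_trial_features <- function(networks, window_s, duration_s = 60,
                                    n_signals = 12) {
  n_win <- duration_s / window_s
  expected <- n_signals * n_win
  if (length(networks) != expected)
    stop("expected ", expected, " networks (", n_signals, " signals x ",
         n_win, " windows), got ", length(networks))
  blocks <- lapply(networks, network_feature_vector)
  layout <- data.frame(
    signal_index = rep(seq_len(n_signals), each = n_win),
    window_index = rep(seq_len(n_win), times = n_signals))
  ids <- names(networks) %||%
    sprintf("s%02d_w%02d", layout$signal_index, layout$window_index)
  out <- unlist(lapply(seq_along(blocks), function(i) {
    b <- blocks[[i]]
    names(b) <- paste(ids[i], names(b), sep = ".")
    b
  }))
  structure(out, layout = layout, class = c("trial_features", "numeric"))
}

#' Edge occurrence counts across networks
#'
#' Sums edge indicators over a collection of binary networks on a shared node
#' set, e.g. the 12 networks of a static analysis or the 120 networks of a
#' 6-second dynamic analysis of one trial.
#'
#' @param networks non-empty list of `adjacency_matrix` objects or binary
#'   matrices with identical dimensions.
#' @return object of class `edge_frequency_map` with fields `counts`
#'   (symmetric integer matrix, zero diagonal) and `max_count` (number of
#'   networks aggregated).
#' @export
edge_frequency_map <- function(networks) {
  if (length(networks) == 0) stop("empty network list")
  mats <- lapply(networks, as_adjacency)
  d <- dim(mats[[1]])
  for (m in mats) if (!identical(dim(m), d))
    stop("networks must share the same node set")
  counts <- Reduce(`+`, mats)
  structure(list(counts = counts, max_count = length(mats)),
            class = "edge_frequency_map")
}

#' Retain frequently occurring edges
#'
#' Keeps the edges whose occurrence count strictly exceeds `p` times the
#' number of aggregated networks, producing the aggregate network map used to
#' compare static and dynamic analyses at retention levels such as 70%, 75%
#' and 80%.
#'
#' @param map an [edge_frequency_map()].
#' @param p retention fraction in `[0, 1)`.
#' @return an `adjacency_matrix` of the retained edges.
#' @export
retain_frequent_edges <- function(map, p) {
  stopifnot(inherits(map, "edge_frequency_map"))
  A <- (map$counts > p * map$max_count) * 1
  diag(A) <- 0
  structure(list(values = A, q = NA_real_, threshold_index = NA_integer_,
                 threshold_value = p * map$max_count),
            class = "adjacency_matrix")
}
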