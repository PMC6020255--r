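# Shared fixtures and independent brute-force oracles for the test suite.

# The worked-example bipartite graph: variables x1, x2, x3, x5, x6 with
# degrees 3, 2, 2, 1, 1 and edge polynomials Z1 = {x1}, Z2 = {x1, x2, x3},
# Z4 = {x1, x2, x3, x5}, Z8 = {x6}.
fig4_bg <- function(p = c(0.5, 0.5, 0.5, 0.5)) {
  bipartite_graph(
    edge_ids = c(1L, 2L, 4L, 8L),
    p = p,
    links = list(1L, c(1L, 2L, 3L), c(1L, 2L, 3L, 4L), 5L),
    var_ids = c("x1", "x2", "x3", "x5", "x6")
  )
}

# Random bipartite graph: every polynomial covers a nonempty variable
# subset and every variable occurs at least once.
random_bg <- function(n1, n2, seed) {
  set.seed(seed)
  repeat {
    links <- lapply(seq_len(n2), function(j) {
      sort(sample(n1, sample(1:min(n1, 4), 1)))
    })
    if (all(seq_len(n1) %in% unlist(links))) break
  }
  bipartite_graph(seq_len(n2), stats::runif(n2, 0.05, 0.95), links)
}

# Overlap structure of the six-embedding example: under the edge-sharing
# measure only H1 and H6 are non-adjacent; under node-sharing the graph is
# complete.
example_overlap <- function(measure = "F2") {
  embeds <- tibble::tibble(
    id = 1:6,
    node_set = as.list(paste0("v", 1:6)),
    edge_ids = as.list(1:6),
    gain = rep(1, 6)
  )
  nbrs <- lapply(1:6, function(i) setdiff(1:6, i))
  if (measure == "F2") {
    nbrs[[1]] <- setdiff(nbrs[[1]], 6L)
    nbrs[[6]] <- setdiff(nbrs[[6]], 1L)
  }
  structure(list(ids = 1:6, nbrs = nbrs, deg = lengths(nbrs),
                 measure = measure),
            class = "overlap_graph")
}

# Independent embedding enumerator: all edge subsets of motif size, kept
# when connected and isomorphic to the motif (no anchored growth).
brute_embeddings <- function(net, motif) {
  motif <- as_motif(motif)
  k <- nrow(motif$edges)
  if (nrow(net) < k) return(list())
  mg <- igraph::graph_from_edgelist(
    cbind(match(motif$edges[, 1], motif$nodes),
          match(motif$edges[, 2], motif$nodes)), directed = FALSE)
  subsets <- utils::combn(net$edge_id, k, simplify = FALSE)
  Filter(function(s) {
    sg <- igraph::graph_from_edgelist(
      cbind(net$from[s], net$to[s]), directed = FALSE)
    igraph::is_connected(sg) && igraph::isomorphic(sg, mg)
  }, subsets)
}

# Small random probabilistic network on n nodes (connected-ish chain plus
# random extras), handy for exhaustive-oracle comparisons.
small_random_net <- function(n_nodes, n_edges, seed) {
  set.seed(seed)
  nodes <- paste0("v", seq_len(n_nodes))
  pairs <- t(utils::combn(nodes, 2))
  pick <- sample(nrow(pairs), min(n_edges, nrow(pairs)))
  prob_network(tibble::tibble(from = pairs[pick, 1], to = pairs[pick, 2],
                              p = stats::runif(length(pick), 0.1, 0.95)))
}

expect_dist_equal <- function(a, b, tol = 1e-12) {
  la <- max(length(a), length(b))
  pa <- c(as.numeric(a), numeric(la - length(a)))
  pb <- c(as.numeric(b), numeric(la - length(b)))
  expect_lt(max(abs(pa - pb)), tol)
}
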