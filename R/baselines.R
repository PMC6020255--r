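#' Binary transform: discard probabilities
#'
#' Keeps every edge and sets its probability to 1, i.e. treats the network
#' as deterministic. First of the three literature transforms used for
#' comparison.
#'
#' @param net A [prob_network()].
#' @return A deterministic [prob_network()] (all p = 1).
#' @export
binarize <- function(net) {
  net$p <- rep(1, nrow(net))
  net
}

#' Threshold transform: keep confidently present edges
#'
#' Keeps the edges with probability strictly above `theta` and sets their
#' probability to 1. The default `theta = 0.2` is the value at which this
#' transform performs best across a broad range of settings. `theta = 0`
#' reduces to [binarize()].
#'
#' @param net A [prob_network()].
#' @param theta Threshold in `[0, 1)`.
#' @return A deterministic [prob_network()] on the surviving edges.
#' @export
threshold_filter <- function(net, theta = 0.2) {
  stopifnot(theta >= 0, theta < 1)
  kept <- net[net$p > theta, c("from", "to")]
  kept$p <- rep(1, nrow(kept))
  prob_network(kept)
}

#' Sampling transform: one Bernoulli draw per edge
#'
#' Realizes a deterministic instance by keeping each edge independently
#' with its own probability.
#'
#' @param net A [prob_network()].
#' @param seed Integer seed for reproducibility.
#' @return A deterministic [prob_network()] on the sampled edges.
#' @export
sample_network <- function(net, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  keep <- stats::runif(nrow(net)) < net$p
  kept <- net[keep, c("from", "to")]
  kept$p <- rep(1, nrow(kept))
  prob_network(kept)
}

#' Least-overlap greedy motif count on a deterministic network
#'
#' The deterministic counter the literature transforms feed into:
#' repeatedly select the embedding with the fewest overlapping embeddings
#' (minimum overlap-graph degree, ties by lowest id), remove it together
#' with its neighbours, and count the selections.
#'
#' @param g A deterministic network (probabilities are ignored).
#' @param motif Motif pattern, catalog name or file path.
#' @param measure `"F2"` or `"F3"`.
#' @return List with `set` (chosen embedding ids) and `count` (integer).
#' @export
deterministic_count <- function(g, motif, measure = c("F2", "F3")) {
  measure <- match.arg(measure)
  embeds <- enumerate_embeddings(g, motif)
  og <- build_overlap_graph(embeds, measure)
  alive <- embeds$id
  chosen <- integer(0)
  while (length(alive) > 0) {
    sub <- induced_overlap(og, alive)
    pick <- sub$ids[order(sub$deg, sub$ids)[1]]
    chosen <- c(chosen, pick)
    alive <- setdiff(alive, c(pick, sub$nbrs[[match(pick, sub$ids)]]))
  }
  list(set = chosen, count = length(chosen))
}

#' Average motif count over sampled deterministic instances
#'
#' Runs [sample_network()] + [deterministic_count()] `n_runs` times and
#' averages the counts (default 10 runs).
#'
#' @inheritParams deterministic_count
#' @param net A [prob_network()].
#' @param n_runs Number of sampled instances.
#' @param seed Master seed; per-run seeds are derived from it.
#' @return Mean count over the runs.
#' @export
sampling_count <- function(net, motif, measure = c("F2", "F3"),
                           n_runs = 10, seed = 1) {
  measure <- match.arg(measure)
  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max, n_runs)
  counts <- purrr::map_dbl(seeds, function(s) {
    deterministic_count(sample_network(net, seed = s), motif,
                        measure)$count
  })
  mean(counts)
}
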