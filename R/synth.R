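#' Generate a synthetic probabilistic network
#'
#' Draws a random topology from one of three standard models and assigns each
#' edge an independent existence probability from uniform(0, 1). Defaults
#' mirror the evaluation setting for this kind of method: average node degree
#' 2 and uniform probabilities strictly inside (0, 1).
#'
#' Model parameterizations achieving the requested average degree:
#' \describe{
#'   \item{er}{Erdős–Rényi G(n, p) with p = avg_degree / (n - 1).}
#'   \item{ws}{Watts–Strogatz ring lattice with round(avg_degree) neighbours
#'     (i.e. round(avg_degree / 2) per side), rewired with probability
#'     `ws_rewire_prob`.}
#'   \item{ba}{Barabási–Albert preferential attachment adding
#'     m = max(1, round(avg_degree / 2)) edges per new node.}
#' }
#' Multi-edges and self-loops produced by rewiring are simplified away.
#'
#' @param model `"er"`, `"ws"` or `"ba"`.
#' @param n_nodes Number of nodes (node labels are `"n1"`, `"n2"`, ...).
#' @param avg_degree Target average node degree (default 2).
#' @param ws_rewire_prob Rewiring probability for the WS model (default 0.1).
#' @param seed Integer seed; the draw is reproducible given the seed.
#' @return A [prob_network()] tibble.
#' @examples
#' generate_network("er", n_nodes = 50, seed = 1)
#' @export
generate_network <- function(model = c("er", "ws", "ba"), n_nodes,
                             avg_degree = 2, ws_rewire_prob = 0.1,
                             seed = NULL) {
  model <- match.arg(model)
  stopifnot(n_nodes >= 2, avg_degree > 0)
  if (!is.null(seed)) set.seed(seed)
  g <- switch(model,
    er = igraph::sample_gnp(n_nodes, p = min(1, avg_degree / (n_nodes - 1))),
    ws = {
      nei <- max(1L, round(avg_degree / 2))
      igraph::sample_smallworld(1, n_nodes, nei = nei, p = ws_rewire_prob)
    },
    ba = {
      m <- max(1L, round(avg_degree / 2))
      if (m >= n_nodes) stop("infeasible parameters: attachment count >= n",
                             call. = FALSE)
      igraph::sample_pa(n_nodes, m = m, directed = FALSE)
    }
  )
  g <- igraph::simplify(g)
  el <- igraph::as_edgelist(g, names = FALSE)
  p <- stats::runif(nrow(el))
  # probabilities strictly inside (0, 1); boundary draws have measure zero
  # but runif can return 0 exactly
  while (any(p <= 0 | p >= 1)) {
    bad <- p <= 0 | p >= 1
    p[bad] <- stats::runif(sum(bad))
  }
  prob_network(tibble::tibble(
    from = paste0("n", el[, 1]),
    to = paste0("n", el[, 2]),
    p = p
  ))
}

#' Generate a suite of replicate networks
#'
#' Spawns `n_replicates` networks from per-replicate seeds derived
#' deterministically from the master seed. The companion
#' [trimmed_aggregate()] implements the matching aggregation rule: drop the
#' `trim` largest and `trim` smallest values, then average (default suite:
#' 20 replicates, trim 2, so 16 values are aggregated).
#'
#' @inheritParams generate_network
#' @param n_replicates Number of replicate networks (must exceed `2 * trim`).
#' @param trim Number of extreme values dropped at each end when aggregating.
#' @param seed Master seed.
#' @return List of [prob_network()]s with attributes `seeds` and `trim`.
#' @export
replicate_suite <- function(model = c("er", "ws", "ba"), n_nodes,
                            avg_degree = 2, ws_rewire_prob = 0.1,
                            n_replicates = 20, trim = 2, seed = 1) {
  model <- match.arg(model)
  if (n_replicates <= 2 * trim) {
    stop("n_replicates must exceed 2 * trim", call. = FALSE)
  }
  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max, n_replicates)
  nets <- purrr::map(seeds, function(s) {
    generate_network(model, n_nodes, avg_degree, ws_rewire_prob, seed = s)
  })
  attr(nets, "seeds") <- seeds
  attr(nets, "trim") <- trim
  nets
}

#' Trimmed aggregation of replicate measurements
#'
#' Drops the `trim` largest and `trim` smallest values and summarizes the
#' rest; with `trim = 0` this is the plain mean/min/max.
#'
#' @param x Numeric vector of per-replicate values.
#' @param trim Number of values dropped at each end.
#' @return One-row tibble with `mean`, `min`, `max` and `n_used`.
#' @export
trimmed_aggregate <- function(x, trim = 2) {
  stopifnot(length(x) > 2 * trim, trim >= 0)
  x <- sort(x)
  if (trim > 0) x <- x[(trim + 1):(length(x) - trim)]
  tibble::tibble(mean = mean(x), min = min(x), max = max(x),
                 n_used = length(x))
}
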