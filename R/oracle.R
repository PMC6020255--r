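#' Enumerate all deterministic instances of a probabilistic network
#'
#' A probabilistic network with |E| edges summarizes 2^|E| deterministic
#' instances (possible worlds); each instance realizes a subset of edges
#' and occurs with probability prod(p over present) * prod(1 - p over
#' absent). Brute-force reference for tests; guarded to small networks.
#'
#' @param net A [prob_network()] with at most `max_edges` edges.
#' @param max_edges Enumeration guard (default 20).
#' @return Tibble with `present` (list column of logical vectors over edge
#'   ids) and `mass`; masses sum to 1.
#' @export
enum_deterministic <- function(net, max_edges = 20) {
  m <- nrow(net)
  if (m > max_edges) {
    stop("network too large for deterministic enumeration", call. = FALSE)
  }
  masks <- instance_masks(m)
  mass <- apply(masks, 1, function(b) {
    prod(ifelse(b, net$p, 1 - net$p))
  })
  if (m == 0) mass <- 1
  tibble::tibble(present = asplit(masks, 1), mass = mass)
}

instance_masks <- function(m) {
  if (m == 0) return(matrix(logical(0), nrow = 1, ncol = 0))
  masks <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), m)))
  dimnames(masks) <- NULL
  masks
}

#' Exact expected count of a chosen embedding set
#'
#' Evaluates, by exhaustive enumeration over all deterministic instances,
#' the expected number of chosen embeddings fully present. For an
#' independent set this equals the sum of the embeddings' gains (linearity
#' of expectation), which is the identity the greedy counter relies on.
#'
#' @param net A small [prob_network()].
#' @param embeds Embedding tibble.
#' @param chosen_ids Ids of the chosen embeddings.
#' @inheritParams enum_deterministic
#' @return The exact expectation.
#' @export
expected_count_given_set <- function(net, embeds, chosen_ids,
                                     max_edges = 20) {
  if (length(chosen_ids) == 0) return(0)
  inst <- enum_deterministic(net, max_edges)
  edge_sets <- embeds$edge_ids[match(chosen_ids, embeds$id)]
  counts <- purrr::map_dbl(inst$present, function(b) {
    sum(purrr::map_lgl(edge_sets, function(es) all(b[es])))
  })
  sum(counts * inst$mass)
}

#' Exact distribution of the overlapping-embedding count
#'
#' Enumerates all 2^|V2| outcomes of the V2 edges of a bipartite graph. An
#' overlapping embedding exists in an outcome when all of its V2-linked
#' edges are present (the edges it shares with the focal embedding count as
#' present). Histogram of existing-neighbour counts, weighted by outcome
#' mass. Independent reference for the polynomial engine.
#'
#' @param bg A [bipartite_graph()] with at most `max_edges` V2 edges.
#' @param max_edges Enumeration guard (default 16).
#' @return A [b_distribution()].
#' @export
exact_b_distribution <- function(bg, max_edges = 16) {
  m <- length(bg$edge_ids)
  if (m > max_edges) {
    stop("bipartite graph too large for exact enumeration", call. = FALSE)
  }
  n1 <- length(bg$var_ids)
  probs <- numeric(n1 + 1)
  masks <- instance_masks(m)
  # variable i exists in an outcome iff all its linked edges are present
  need <- purrr::map(seq_len(n1), function(i) {
    which(purrr::map_lgl(bg$links, function(vs) i %in% vs))
  })
  for (r in seq_len(nrow(masks))) {
    b <- masks[r, ]
    mass <- prod(ifelse(b, bg$p, 1 - bg$p))
    if (m == 0) mass <- 1
    count <- sum(purrr::map_lgl(need, function(es) all(b[es])))
    probs[count + 1] <- probs[count + 1] + mass
  }
  b_distribution(probs)
}

#' Maximum-gain independent set of an overlap graph
#'
#' Enumerates the maximal independent sets of the overlap graph (gains are
#' positive, so some maximal set attains the optimum) and returns the one
#' with the largest total gain; ties resolve lexicographically by sorted
#' member ids.
#'
#' @param og An overlap graph.
#' @param gains Named or positional gains, one per embedding of `og`
#'   (default 1: maximum cardinality).
#' @param max_embeddings Enumeration guard (default 20).
#' @return List with `set` (embedding ids) and `value` (total gain).
#' @export
max_independent_set <- function(og, gains = NULL,
                                max_embeddings = 20) {
  n <- length(og$ids)
  if (n > max_embeddings) {
    stop("too many embeddings for exact enumeration", call. = FALSE)
  }
  if (n == 0) return(list(set = integer(0), value = 0))
  if (is.null(gains)) gains <- rep(1, n)
  edges <- purrr::imap(og$nbrs, function(nb, i) {
    id <- og$ids[i]
    nb <- nb[nb > id]
    if (length(nb)) rbind(match(id, og$ids), match(nb, og$ids))
  })
  el <- do.call(cbind, purrr::compact(edges))
  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (!is.null(el)) g <- igraph::add_edges(g, as.vector(el))
  sets <- igraph::max_ivs(g)
  vals <- purrr::map_dbl(sets, function(s) sum(gains[as.integer(s)]))
  best <- which(vals == max(vals))
  keys <- purrr::map_chr(sets[best], function(s) {
    paste(sprintf("%09d", sort(og$ids[as.integer(s)])), collapse = ",")
  })
  pick <- best[order(keys)[1]]
  list(set = sort(og$ids[as.integer(sets[[pick]])]), value = vals[pick])
}

#' Exact optimum of the independent motif counting problem
#'
#' Brute-force reference: enumerates embeddings, builds the overlap graph,
#' and returns the independent embedding set maximizing the expected count
#' (sum of gains, valid by linearity of expectation). Guarded to small
#' instances.
#'
#' @inheritParams count_independent
#' @param max_embeddings Enumeration guard.
#' @return List with `set` (embedding ids), `value` and the embedding
#'   tibble.
#' @export
exact_def1_solution <- function(net, motif, measure = c("F2", "F3"),
                                max_embeddings = 20) {
  measure <- match.arg(measure)
  embeds <- enumerate_embeddings(net, motif)
  og <- build_overlap_graph(embeds, measure)
  mis <- max_independent_set(og, gains = embeds$gain,
                             max_embeddings = max_embeddings)
  c(mis, list(embeds = embeds))
}
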