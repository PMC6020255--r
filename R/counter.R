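#' Loss of an embedding from its overlap distribution
#'
#' The loss penalizes embeddings whose selection would knock out many
#' overlapping embeddings. Any monotone function of the distribution of the
#' overlapping-embedding count B keeps the priority bound valid; here
#' `f(B) = 1 + Exp(B)` is used: the +1 regularizes the division for isolated
#' embeddings (Exp(B) = 0) and preserves monotonicity, so prefix
#' distributions give upper bounds on the priority.
#'
#' @param dist A [b_distribution()] (complete or prefix).
#' @return `1 + b_expectation(dist)`.
#' @export
loss_value <- function(dist) {
  1 + b_expectation(dist)
}

#' Priority of an embedding
#'
#' The gain divided by the loss: `rho = a / f(B)`. With `f >= 1` this is
#' finite and at most the gain. Because the loss computed from a prefix of
#' the edge polynomials underestimates the full loss, the corresponding
#' prefix priority is an upper bound on the exact priority.
#'
#' @param gain Existence probability of the embedding, in (0, 1].
#' @param loss A loss value, `>= 1`.
#' @return `gain / loss`.
#' @export
priority_value <- function(gain, loss) {
  stopifnot(gain > 0, gain <= 1, loss >= 1)
  gain / loss
}

#' Proxy ordering of candidate embeddings
#'
#' Ranks embeddings by the cheap proxy `Q = gain / overlap-degree`
#' (descending), an inexpensive stand-in for the exact priority used to
#' front-load likely winners so the priority bound prunes early.
#' Zero-degree embeddings rank first (`Q = Inf`); ties break by embedding
#' id.
#'
#' @param embeds Embedding tibble.
#' @param og Overlap graph over (at least) those embeddings.
#' @return Embedding ids in evaluation order.
#' @export
proxy_order <- function(embeds, og) {
  deg <- og$deg[match(embeds$id, og$ids)]
  q <- ifelse(deg == 0, Inf, embeds$gain / deg)
  embeds$id[order(-q, embeds$id)]
}

#' Select the highest-priority embedding
#'
#' Evaluates candidates in proxy order. For each candidate it builds the
#' bipartite graph, orders its edge polynomials (greedy W/D ordering when
#' `strategy2`, else by edge id), and computes the overlap distribution via
#' the (optionally memory-bounded) polynomial product. With `strategy1`,
#' after each polynomial product the intermediate priority bound
#' `rho_j = gain / (1 + Exp(B | prefix j))` is compared against the best
#' exact priority seen; the candidate is abandoned as soon as the bound
#' drops strictly below it, which cannot change the final choice. Ties on
#' exact priority resolve to the lower embedding id.
#'
#' @param og Overlap graph of the surviving embeddings.
#' @param embeds Embedding tibble (surviving rows).
#' @param net The [prob_network()].
#' @param strategy1 Priority-bound early termination.
#' @param strategy2 Greedy collapse-ordering of edge polynomials.
#' @param strategy3 Memory-bounded polynomial product.
#' @param max_terms Live-term budget when `strategy3` is on.
#' @param cache Optional environment memoizing exact (gain, loss, rho)
#'   records across calls; entries must be invalidated by the caller when
#'   an embedding's overlap neighbourhood changes.
#' @return List with `id` (chosen embedding), `record` (tibble of
#'   per-candidate gain, loss, rho, exact flag) and `n_pruned`.
#' @export
best_embedding <- function(og, embeds, net, strategy1 = TRUE,
                           strategy2 = TRUE, strategy3 = FALSE,
                           max_terms = 4096, cache = NULL) {
  stopifnot(nrow(embeds) > 0)
  ord <- proxy_order(embeds, og)
  rho_star <- -Inf
  best_id <- NA_integer_
  records <- vector("list", length(ord))
  n_pruned <- 0L
  for (i in seq_along(ord)) {
    id <- ord[i]
    key <- as.character(id)
    if (!is.null(cache) && !is.null(cache[[key]])) {
      rec <- cache[[key]]
    } else {
      row <- embeds[match(id, embeds$id), ]
      bg <- build_bipartite(id, og, net, embeds)
      res <- candidate_distribution(bg, row$gain, rho_star, strategy1,
                                    strategy2, strategy3, max_terms)
      exact <- isTRUE(attr(res$dist, "complete"))
      loss <- loss_value(res$dist)
      rec <- tibble::tibble(id = id, gain = row$gain, loss = loss,
                            rho = row$gain / loss, exact = exact)
      # pruned candidates carry only a bound; do not memoize them
      if (!is.null(cache) && exact) cache[[key]] <- rec
    }
    if (!rec$exact) n_pruned <- n_pruned + 1L
    records[[i]] <- rec
    if (rec$exact &&
        (rec$rho > rho_star ||
         (rec$rho == rho_star && (is.na(best_id) || id < best_id)))) {
      rho_star <- rec$rho
      best_id <- id
    }
  }
  list(id = best_id, record = dplyr::bind_rows(records),
       n_pruned = n_pruned)
}

candidate_distribution <- function(bg, gain, rho_star, strategy1, strategy2,
                                   strategy3, max_terms) {
  if (length(bg$edge_ids) == 0) {
    return(list(dist = b_distribution(1)))
  }
  order <- if (strategy2) order_polynomials(bg) else sort(bg$edge_ids)
  on_prefix <- NULL
  if (strategy1) {
    on_prefix <- function(dist, j) {
      gain / loss_value(dist) >= rho_star
    }
  }
  if (strategy3) {
    # bounded product completes every polynomial before a distribution is
    # available, so the prefix bound cannot stream; prune afterwards
    res <- multiply_collapse_bounded(bg, order, max_terms = max_terms)
  } else {
    res <- multiply_collapse(bg, order, on_prefix = on_prefix)
  }
  list(dist = res$dist, cost = res$cost)
}

#' Count non-overlapping motif embeddings in a probabilistic network
#'
#' The central driver. Enumerates all embeddings of the motif in the
#' network skeleton, then greedily builds an independent (non-overlapping
#' under the chosen measure) embedding set: at every iteration the
#' highest-priority embedding (gain over loss, [best_embedding()]) is
#' selected, its existence probability is added to the expected count, and
#' it is removed from the overlap graph together with all of its
#' neighbours. Priorities are recomputed from the surviving embeddings each
#' iteration, since removals change the overlap neighbourhoods that define
#' the loss. By linearity of expectation the reported expected count equals
#' the exact expected number of selected embeddings present across all
#' deterministic instances of the network.
#'
#' @param net A [prob_network()].
#' @param motif Motif pattern, catalog name or file path.
#' @param measure `"F2"` (edge-disjoint) or `"F3"` (node-disjoint).
#' @param strategy1,strategy2,strategy3 Scaling-strategy toggles; they
#'   change cost, never the selected set.
#' @param max_terms Live-term budget used when `strategy3 = TRUE`.
#' @return A `motif_count` object: `chosen` (tibble of selected
#'   embeddings), `expected_count`, `measure`, `motif`, `n_embeddings`
#'   and a per-iteration `trace` tibble.
#' @examples
#' net <- generate_network("er", 30, seed = 7)
#' count_independent(net, "M1")
#' @export
count_independent <- function(net, motif, measure = c("F2", "F3"),
                              strategy1 = TRUE, strategy2 = TRUE,
                              strategy3 = FALSE, max_terms = 4096) {
  measure <- match.arg(measure)
  motif <- as_motif(motif)
  embeds <- enumerate_embeddings(net, motif)
  og <- build_overlap_graph(embeds, measure)
  alive <- embeds$id
  chosen <- integer(0)
  trace <- list()
  iter <- 0L
  cache <- new.env(parent = emptyenv())
  while (length(alive) > 0) {
    iter <- iter + 1L
    sub_og <- induced_overlap(og, alive)
    sub_embeds <- embeds[match(alive, embeds$id), ]
    sel <- best_embedding(sub_og, sub_embeds, net,
                          strategy1 = strategy1, strategy2 = strategy2,
                          strategy3 = strategy3, max_terms = max_terms,
                          cache = cache)
    chosen <- c(chosen, sel$id)
    nbrs <- sub_og$nbrs[[match(sel$id, sub_og$ids)]]
    removed <- c(sel$id, nbrs)
    # survivors overlapping a removed embedding get a new neighbourhood,
    # hence a new loss: drop their memoized priorities
    stale <- unique(unlist(sub_og$nbrs[match(removed, sub_og$ids)]))
    rm(list = intersect(as.character(c(removed, stale)), names(cache)),
       envir = cache)
    alive <- setdiff(alive, removed)
    rec <- sel$record[match(sel$id, sel$record$id), ]
    trace[[iter]] <- tibble::tibble(
      iteration = iter, chosen_id = sel$id, rho = rec$rho,
      n_candidates = nrow(sub_embeds), n_pruned = sel$n_pruned,
      n_removed = length(nbrs) + 1L
    )
  }
  chosen_tbl <- embeds[match(chosen, embeds$id), ]
  structure(list(
    chosen = chosen_tbl,
    expected_count = sum(chosen_tbl$gain),
    measure = measure,
    motif = motif$name,
    n_embeddings = nrow(embeds),
    trace = dplyr::bind_rows(trace)
  ), class = "motif_count")
}

#' @export
print.motif_count <- function(x, ...) {
  cat(sprintf(
    "# Independent motif count (%s, motif %s)\n# %d of %d embeddings selected; expected count %.6g\n",
    x$measure, x$motif, nrow(x$chosen), x$n_embeddings, x$expected_count))
  invisible(x)
}
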