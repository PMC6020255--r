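#' Enumerate all embeddings of a motif in the deterministic skeleton
#'
#' Finds every distinct edge subset of the network skeleton G' = (V, E)
#' whose induced subgraph is isomorphic to the motif. An embedding is
#' identified by its edge set, so automorphic relabelings collapse to a
#' single embedding. Each embedding carries its gain: the probability that
#' all of its edges exist simultaneously, i.e. the product of edge
#' probabilities.
#'
#' Enumeration grows connected edge subsets from a smallest-edge anchor
#' (each subset is generated exactly once) and keeps those isomorphic to
#' the motif. Intended for small motifs (at most 5 edges).
#'
#' @param net A [prob_network()].
#' @param motif A [motif_pattern()], catalog name or motif file path.
#' @return Tibble with one row per embedding: `id` (dense, ordered by sorted
#'   edge-id tuple), `node_set` and `edge_ids` (list columns) and `gain`.
#' @examples
#' net <- prob_network(data.frame(from = c("a", "b", "a"),
#'                                to = c("b", "c", "c"), p = 0.5))
#' enumerate_embeddings(net, "M1")
#' @export
enumerate_embeddings <- function(net, motif) {
  motif <- as_motif(motif)
  k <- nrow(motif$edges)
  subsets <- if (k > nrow(net)) list() else connected_edge_subsets(net, k)
  mg <- motif_igraph(motif)
  motif_sig <- graph_signature(mg)

  ends <- cbind(net$from, net$to)
  keep <- purrr::keep(subsets, function(s) {
    sg <- igraph::graph_from_edgelist(ends[s, , drop = FALSE],
                                      directed = FALSE)
    identical(graph_signature(sg), motif_sig) && igraph::isomorphic(sg, mg)
  })
  if (length(keep) == 0) {
    return(tibble::tibble(id = integer(), node_set = list(),
                          edge_ids = list(), gain = numeric()))
  }
  keep <- purrr::map(keep, sort)
  ord <- order(purrr::map_chr(keep, function(s) {
    paste(sprintf("%09d", s), collapse = ",")
  }))
  keep <- keep[ord]
  tibble::tibble(
    id = seq_along(keep),
    node_set = purrr::map(keep, function(s) {
      sort(unique(c(net$from[s], net$to[s])))
    }),
    edge_ids = keep,
    gain = purrr::map_dbl(keep, function(s) prod(net$p[s]))
  )
}

# quick isomorphism pre-filter: vertex count + sorted degree sequence
graph_signature <- function(g) {
  as.numeric(c(igraph::vcount(g), sort(unname(igraph::degree(g)))))
}

# All connected edge subsets of size k, each exactly once (anchored
# extension: subsets are grown from their minimum edge id, and an edge
# enters the extension set only when first reachable).
connected_edge_subsets <- function(net, k) {
  m <- nrow(net)
  if (m == 0 || k == 0) return(list())
  # edge adjacency: edges sharing a node
  node_edges <- split(rep(net$edge_id, 2), c(net$from, net$to))
  adj <- vector("list", m)
  for (es in node_edges) {
    for (e in es) adj[[e]] <- c(adj[[e]], setdiff(es, e))
  }
  adj <- purrr::map(adj, function(x) sort(unique(x)))

  out <- list()
  n_out <- 0L
  extend <- function(sub, ext, seen, anchor) {
    if (length(sub) == k) {
      n_out <<- n_out + 1L
      out[[n_out]] <<- sub
      return(invisible())
    }
    while (length(ext) > 0) {
      w <- ext[1]
      ext <- ext[-1]
      nbrs <- adj[[w]]
      new <- nbrs[nbrs > anchor & !(nbrs %in% seen)]
      extend(c(sub, w), c(ext, new), c(seen, new), anchor)
    }
  }
  for (anchor in seq_len(m)) {
    nbrs <- adj[[anchor]]
    new <- nbrs[nbrs > anchor]
    extend(anchor, new, c(anchor, new), anchor)
  }
  out
}

#' Build the overlap graph of a set of embeddings
#'
#' Embeddings are nodes; two embeddings are adjacent when they overlap under
#' the chosen frequency measure: `F2` if they share at least one edge, `F3`
#' if they share at least one node. A set of embeddings is independent
#' (non-overlapping) exactly when it is an independent set of this graph.
#'
#' @param embeds Embedding tibble from [enumerate_embeddings()].
#' @param measure `"F2"` (edge-sharing) or `"F3"` (node-sharing).
#' @return An `overlap_graph` object: embedding ids, adjacency lists and
#'   degrees.
#' @export
build_overlap_graph <- function(embeds, measure = c("F2", "F3")) {
  measure <- match.arg(measure)
  n <- nrow(embeds)
  items <- if (measure == "F2") embeds$edge_ids else embeds$node_set
  member <- split(rep(embeds$id, lengths(items)), unlist(items))
  nbrs <- rep(list(integer()), n)
  for (ids in member) {
    if (length(ids) < 2) next
    for (i in ids) nbrs[[i]] <- c(nbrs[[i]], setdiff(ids, i))
  }
  nbrs <- purrr::map(nbrs, function(x) sort(unique(x)))
  structure(list(ids = embeds$id, nbrs = nbrs,
                 deg = lengths(nbrs), measure = measure),
            class = "overlap_graph")
}

#' @export
print.overlap_graph <- function(x, ...) {
  cat(sprintf("# Overlap graph (%s): %d embeddings, %d overlaps\n",
              x$measure, length(x$ids), sum(x$deg) / 2))
  invisible(x)
}

#' Construct a bipartite graph directly
#'
#' Low-level constructor for the per-embedding bipartite structure that the
#' polynomial engine consumes: one variable per overlapping embedding
#' (the V1 side), one edge polynomial per network edge those embeddings need
#' beyond the focal embedding's own edges (the V2 side). Variable degrees
#' are derived from the links.
#'
#' @param edge_ids Integer ids of the V2 edges.
#' @param p Existence probability of each V2 edge.
#' @param links List (one element per V2 edge) of integer indices into
#'   `var_ids`: the variables whose embeddings contain that edge.
#' @param var_ids Identifiers of the V1 variables (default `1..n`).
#' @return A `bipartite_graph` object.
#' @export
bipartite_graph <- function(edge_ids, p, links, var_ids = NULL) {
  stopifnot(length(edge_ids) == length(p), length(links) == length(p))
  all_links <- as.integer(unlist(links))
  n_var <- if (length(all_links)) max(all_links) else 0L
  if (is.null(var_ids)) var_ids <- seq_len(n_var)
  stopifnot(length(var_ids) >= n_var)
  deg <- tabulate(all_links, nbins = length(var_ids))
  structure(list(
    edge_ids = as.integer(edge_ids),
    p = as.numeric(p),
    links = purrr::map(links, as.integer),
    var_ids = var_ids,
    deg = as.integer(deg),
    focal = NA_integer_
  ), class = "bipartite_graph")
}

#' @export
print.bipartite_graph <- function(x, ...) {
  cat(sprintf("# Bipartite graph: |V1| = %d variables, |V2| = %d edges\n",
              length(x$var_ids), length(x$edge_ids)))
  invisible(x)
}

#' Build the bipartite graph of a focal embedding
#'
#' For a focal embedding H_k, V1 holds one variable per embedding
#' overlapping H_k in the overlap graph, and V2 holds every network edge
#' those overlapping embeddings use, excluding the edges of H_k itself.
#' A variable links to a V2 edge when its embedding contains that edge;
#' the variable's degree is its number of linked V2 edges.
#'
#' @param focal_id Id of the focal embedding.
#' @param og Overlap graph from [build_overlap_graph()].
#' @param net The [prob_network()].
#' @param embeds Embedding tibble the overlap graph was built from.
#' @return A [bipartite_graph()] whose `var_ids` are the overlapping
#'   embedding ids.
#' @export
build_bipartite <- function(focal_id, og, net, embeds) {
  v1 <- og$nbrs[[match(focal_id, og$ids)]]
  focal_edges <- embeds$edge_ids[[match(focal_id, embeds$id)]]
  v1_edges <- purrr::map(v1, function(id) {
    embeds$edge_ids[[match(id, embeds$id)]]
  })
  v2 <- sort(setdiff(unique(unlist(v1_edges)), focal_edges))
  links <- purrr::map(v2, function(e) {
    which(purrr::map_lgl(v1_edges, function(es) e %in% es))
  })
  bg <- bipartite_graph(v2, net$p[match(v2, net$edge_id)], links,
                        var_ids = v1)
  bg$focal <- focal_id
  bg
}

# restrict an overlap graph to a surviving subset of embedding ids
induced_overlap <- function(og, alive) {
  idx <- match(alive, og$ids)
  nbrs <- purrr::map(og$nbrs[idx], function(x) x[x %in% alive])
  structure(list(ids = alive, nbrs = nbrs, deg = lengths(nbrs),
                 measure = og$measure),
            class = "overlap_graph")
}
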