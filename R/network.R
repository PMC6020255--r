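#' Build a probabilistic network from an edge table
#'
#' A probabilistic network is an undirected graph in which every edge carries
#' an independent existence probability in (0, 1]. It is represented as a
#' tibble with one row per edge and columns `from`, `to` (node labels), `p`
#' (existence probability) and `edge_id` (dense, stable 1..|E|), carrying the
#' class `"prob_network"`.
#'
#' Edges are undirected: `(u, v)` and `(v, u)` denote the same edge. Self
#' loops are rejected. Duplicate edges with identical probability are merged
#' with a warning; duplicates with conflicting probabilities are an error.
#'
#' @param edges A data frame with columns `from`, `to` and `p`.
#' @return A `prob_network` tibble.
#' @examples
#' prob_network(data.frame(from = "a", to = "b", p = 0.5))
#' @export
prob_network <- function(edges) {
  edges <- tibble::as_tibble(edges)
  stopifnot(all(c("from", "to", "p") %in% names(edges)))
  edges <- dplyr::mutate(edges,
    from = as.character(.data$from),
    to = as.character(.data$to),
    p = as.numeric(.data$p)
  )
  if (any(is.na(edges$p)) || any(edges$p <= 0) || any(edges$p > 1)) {
    stop("probability out of range: every p must satisfy 0 < p <= 1",
         call. = FALSE)
  }
  if (any(edges$from == edges$to)) {
    stop("self-loops are not allowed", call. = FALSE)
  }
  # canonical undirected key
  key <- paste(pmin(edges$from, edges$to), pmax(edges$from, edges$to))
  if (anyDuplicated(key)) {
    conflicting <- stats::ave(edges$p, key, FUN = function(x) diff(range(x))) > 0
    if (any(conflicting)) {
      stop("duplicate edge with conflicting probability", call. = FALSE)
    }
    warning("duplicate edges with identical probability were merged",
            call. = FALSE)
    edges <- edges[!duplicated(key), ]
  }
  edges$edge_id <- seq_len(nrow(edges))
  edges <- edges[, c("from", "to", "p", "edge_id")]
  class(edges) <- c("prob_network", class(edges))
  edges
}

#' @export
print.prob_network <- function(x, ...) {
  cat(sprintf("# Probabilistic network: %d nodes, %d edges\n",
              length(network_nodes(x)), nrow(x)))
  NextMethod()
  invisible(x)
}

#' Nodes of a probabilistic network
#'
#' @param net A `prob_network`.
#' @return Sorted character vector of node labels.
#' @export
network_nodes <- function(net) {
  sort(unique(c(net$from, net$to)))
}

#' Read a probabilistic network from an edge-list file
#'
#' The file dialect is a whitespace-separated three-column edge list
#' `u v p`, with `#` starting comment lines. Node labels are arbitrary
#' strings; `p` must lie in (0, 1]. Edge ids are assigned in file order
#' after deduplication, so repeated reads of the same file yield
#' identical ids.
#'
#' @param path Path to the edge-list file.
#' @return A [prob_network()] tibble.
#' @export
read_network <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0) {
    return(prob_network(tibble::tibble(from = character(), to = character(),
                                       p = numeric())))
  }
  parts <- strsplit(lines, "[[:space:]]+")
  if (any(lengths(parts) != 3)) {
    stop("malformed edge list: every line must be 'u v p'", call. = FALSE)
  }
  m <- do.call(rbind, parts)
  p <- suppressWarnings(as.numeric(m[, 3]))
  if (any(is.na(p))) stop("malformed probability column", call. = FALSE)
  prob_network(tibble::tibble(from = m[, 1], to = m[, 2], p = p))
}

#' Write a probabilistic network to an edge-list file
#'
#' Edges are written sorted by edge id, probabilities with 15 significant
#' digits, so write/read round-trips are exact and repeated writes are
#' byte-identical.
#'
#' @param net A `prob_network`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path) {
  net <- dplyr::arrange(net, .data$edge_id)
  lines <- c("# probabilistic edge list: u v p",
             sprintf("%s %s %.15g", net$from, net$to, net$p))
  writeLines(lines, path)
  invisible(path)
}

#' Export the deterministic skeleton as a two-column edge list
#'
#' Drops probabilities; useful for interoperability with deterministic
#' graph tools.
#'
#' @inheritParams write_network
#' @return `path`, invisibly.
#' @export
write_skeleton <- function(net, path) {
  net <- dplyr::arrange(net, .data$edge_id)
  writeLines(sprintf("%s %s", net$from, net$to), path)
  invisible(path)
}

# igraph view of the skeleton G' = (V, E); edge order follows edge_id so
# igraph edge indices coincide with edge ids.
network_igraph <- function(net) {
  igraph::graph_from_data_frame(
    dplyr::arrange(net, .data$edge_id)[, c("from", "to")],
    directed = FALSE,
    vertices = network_nodes(net)
  )
}
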