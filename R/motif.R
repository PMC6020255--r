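#' Define a motif pattern
#'
#' A motif pattern is a small connected undirected graph on integer-labelled
#' nodes, with between 2 and `max_edges` edges. Motifs are matched against
#' networks up to isomorphism, so node labels only fix the topology.
#'
#' @param edges Two-column matrix or data frame of node pairs (integers).
#' @param name Optional label.
#' @param max_edges Upper bound on motif size (default 5).
#' @return An object of class `motif_pattern` with fields `nodes`, `edges`
#'   (two-column integer matrix) and `name`.
#' @examples
#' motif_pattern(rbind(c(1, 2), c(2, 3)), name = "path")
#' @export
motif_pattern <- function(edges, name = "custom", max_edges = 5L) {
  edges <- as.matrix(edges)
  storage.mode(edges) <- "integer"
  if (ncol(edges) != 2) stop("motif edges must be two columns", call. = FALSE)
  if (nrow(edges) < 2 || nrow(edges) > max_edges) {
    stop(sprintf("motif must have between 2 and %d edges", max_edges),
         call. = FALSE)
  }
  if (any(edges[, 1] == edges[, 2])) {
    stop("motif must not contain self-loops", call. = FALSE)
  }
  key <- paste(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
  if (anyDuplicated(key)) stop("motif must not contain duplicate edges",
                               call. = FALSE)
  nodes <- sort(unique(as.integer(edges)))
  g <- motif_igraph_raw(nodes, edges)
  if (!igraph::is_connected(g)) stop("motif must be connected", call. = FALSE)
  structure(list(nodes = nodes, edges = edges, name = name),
            class = "motif_pattern")
}

motif_igraph_raw <- function(nodes, edges) {
  igraph::graph_from_edgelist(
    cbind(match(edges[, 1], nodes), match(edges[, 2], nodes)),
    directed = FALSE
  )
}

motif_igraph <- function(motif) motif_igraph_raw(motif$nodes, motif$edges)

#' @export
print.motif_pattern <- function(x, ...) {
  cat(sprintf("# Motif pattern '%s': %d nodes, %d edges\n",
              x$name, length(x$nodes), nrow(x$edges)))
  for (i in seq_len(nrow(x$edges))) {
    cat(sprintf("  %d -- %d\n", x$edges[i, 1], x$edges[i, 2]))
  }
  invisible(x)
}

#' Built-in motif catalog
#'
#' The four small undirected motifs with two and three edges:
#' \describe{
#'   \item{M1}{two-edge path on 3 nodes}
#'   \item{M2}{triangle (loop pattern): 3 nodes, 3 edges}
#'   \item{M3}{three-edge star on 4 nodes}
#'   \item{M4}{three-edge path on 4 nodes}
#' }
#' M1 is a subgraph of each of M2, M3 and M4.
#'
#' @param name One of `"M1"`, `"M2"`, `"M3"`, `"M4"`.
#' @return A [motif_pattern()].
#' @examples
#' motif_catalog("M2")
#' @export
motif_catalog <- function(name) {
  switch(name,
    M1 = motif_pattern(rbind(c(1L, 2L), c(2L, 3L)), name = "M1"),
    M2 = motif_pattern(rbind(c(1L, 2L), c(2L, 3L), c(1L, 3L)), name = "M2"),
    M3 = motif_pattern(rbind(c(1L, 2L), c(1L, 3L), c(1L, 4L)), name = "M3"),
    M4 = motif_pattern(rbind(c(1L, 2L), c(2L, 3L), c(3L, 4L)), name = "M4"),
    stop(sprintf("unknown motif '%s': catalog has M1, M2, M3, M4", name),
         call. = FALSE)
  )
}

#' Resolve a motif argument
#'
#' Accepts a `motif_pattern`, a catalog name, or a path to a small
#' two-column edge-list file.
#'
#' @param motif Motif pattern, catalog name, or file path.
#' @return A [motif_pattern()].
#' @export
as_motif <- function(motif) {
  if (inherits(motif, "motif_pattern")) return(motif)
  if (is.character(motif) && length(motif) == 1) {
    if (motif %in% c("M1", "M2", "M3", "M4")) return(motif_catalog(motif))
    if (file.exists(motif)) {
      m <- as.matrix(utils::read.table(motif, comment.char = "#"))
      return(motif_pattern(m, name = basename(motif)))
    }
  }
  stop("cannot interpret motif argument", call. = FALSE)
}
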