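#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy the selected embeddings of a motif count
#'
#' @param x A `motif_count` from [count_independent()].
#' @param ... Unused.
#' @return Tibble with one row per selected embedding: `id`, `nodes`
#'   (comma-separated labels), `n_edges` and `gain`.
#' @method tidy motif_count
#' @export
tidy.motif_count <- function(x, ...) {
  tibble::tibble(
    id = x$chosen$id,
    nodes = purrr::map_chr(x$chosen$node_set, paste, collapse = ","),
    n_edges = lengths(x$chosen$edge_ids),
    gain = x$chosen$gain
  )
}

#' One-row summary of a motif count
#'
#' @inheritParams tidy.motif_count
#' @return Tibble with `motif`, `measure`, `n_embeddings`, `n_chosen` and
#'   `expected_count`.
#' @method glance motif_count
#' @export
glance.motif_count <- function(x, ...) {
  tibble::tibble(
    motif = x$motif,
    measure = x$measure,
    n_embeddings = x$n_embeddings,
    n_chosen = nrow(x$chosen),
    expected_count = x$expected_count
  )
}

#' Tidy an overlap-count distribution
#'
#' @param x A [b_distribution()].
#' @param ... Unused.
#' @return Tibble with columns `b` and `prob`.
#' @method tidy b_distribution
#' @export
tidy.b_distribution <- function(x, ...) {
  tibble::tibble(b = seq_along(x) - 1, prob = as.numeric(x))
}

#' Plot an overlap-count distribution
#'
#' @param object A [b_distribution()].
#' @param ... Unused.
#' @return A ggplot column chart of P(B = j).
#' @method autoplot b_distribution
#' @export
autoplot.b_distribution <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(x = .data$b, y = .data$prob)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "overlapping embeddings B", y = "probability")
}

#' Plot the gains of the selected embeddings
#'
#' @param object A `motif_count`.
#' @param ... Unused.
#' @return A ggplot column chart of per-embedding gains, ordered by gain.
#' @method autoplot motif_count
#' @export
autoplot.motif_count <- function(object, ...) {
  d <- tidy(object)
  d$id <- stats::reorder(factor(d$id), -d$gain)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$id, y = .data$gain)) +
    ggplot2::geom_col() +
    ggplot2::labs(
      x = "selected embedding",
      y = "existence probability (gain)",
      title = sprintf("%s count: %d embeddings, expected count %.4g",
                      object$measure, nrow(d), object$expected_count)
    )
}
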