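#' Distribution of the overlapping-embedding count
#'
#' The number of embeddings that overlap a focal embedding is a random
#' variable B (each overlapping embedding exists only when all of its extra
#' edges do). A `b_distribution` is its probability mass function: a numeric
#' vector whose element `i + 1` is P(B = i). The attribute `complete` is
#' `FALSE` when the distribution was built from a prefix of the edge
#' polynomials (a stochastic lower bound on B).
#'
#' @param probs Numeric vector of probabilities for B = 0, 1, ....
#' @param complete Whether all edge polynomials were multiplied.
#' @return A `b_distribution`.
#' @export
b_distribution <- function(probs, complete = TRUE) {
  stopifnot(all(probs >= -1e-12))
  probs <- pmax(probs, 0)
  structure(as.numeric(probs), class = "b_distribution", complete = complete)
}

#' @export
print.b_distribution <- function(x, ...) {
  cat(sprintf("# Distribution of the overlapping-embedding count%s\n",
              if (isTRUE(attr(x, "complete"))) "" else " (prefix bound)"))
  print(stats::setNames(as.numeric(x), seq_along(x) - 1))
  invisible(x)
}

#' Expected number of overlapping embeddings
#'
#' @param dist A [b_distribution()].
#' @return `sum(j * P(B = j))`.
#' @export
b_expectation <- function(dist) {
  sum((seq_along(dist) - 1) * as.numeric(dist))
}

# P(B >= tau)
b_tail <- function(dist, tau) {
  if (tau <= 0) return(sum(dist))
  if (tau >= length(dist)) return(0)
  sum(dist[(tau + 1):length(dist)])
}

#' Build an edge polynomial
#'
#' Each V2 edge j of a bipartite graph defines the polynomial
#' `Z_j = p_j * prod(x_i) + q_j` over the variables of the embeddings that
#' contain it. With the V1 pre-collapse optimization, variables of degree 1
#' (edges that are an embedding's only missing edge) are folded directly
#' into a power of t: `Z_j = p_j * t^m * prod(remaining x_i) + q_j`, which
#' avoids ever applying their collapse operator during the product.
#'
#' @param bg A [bipartite_graph()].
#' @param edge_id Id of a V2 edge of `bg`.
#' @param v1_optimize Apply the degree-1 pre-collapse rewrite.
#' @return List with `edge_id`, `p`, `q`, `vars` (variable indices into
#'   `bg$var_ids`) and `pre_t` (count of pre-collapsed degree-1 variables).
#' @export
make_edge_polynomial <- function(bg, edge_id, v1_optimize = TRUE) {
  j <- match(edge_id, bg$edge_ids)
  if (is.na(j)) stop("edge not in V2 of the bipartite graph", call. = FALSE)
  vars <- bg$links[[j]]
  pre_t <- 0L
  if (v1_optimize) {
    deg1 <- vars[bg$deg[vars] == 1L]
    pre_t <- length(deg1)
    vars <- setdiff(vars, deg1)
  }
  list(edge_id = edge_id, p = bg$p[j], q = 1 - bg$p[j],
       vars = vars, pre_t = pre_t)
}

#' Apply a collapse operator to one polynomial term
#'
#' The collapse operator for variable `x_r` removes the variable from a term
#' and increments the term's power of t exactly when the variable's exponent
#' equals its degree in the bipartite graph (all edges of that overlapping
#' embedding are present); otherwise the variable is removed without
#' incrementing t (the embedding is missing at least one edge). The
#' coefficient never changes.
#'
#' @param term List with `coeff`, `t_exp`, and `x_exps` (named integer
#'   vector of variable exponents).
#' @param var Name of the variable to collapse.
#' @param degree The variable's degree in the bipartite graph.
#' @return The collapsed term.
#' @examples
#' term <- list(coeff = 0.1, t_exp = 0, x_exps = c(x1 = 2, x2 = 2))
#' collapse_term(term, "x1", degree = 3)  # x1 dropped, t unchanged
#' collapse_term(term, "x2", degree = 2)  # x2 replaced, t incremented
#' @export
collapse_term <- function(term, var, degree) {
  exp_r <- if (var %in% names(term$x_exps)) term$x_exps[[var]] else 0L
  if (exp_r == degree) term$t_exp <- term$t_exp + 1L
  term$x_exps <- term$x_exps[setdiff(names(term$x_exps), var)]
  term
}

# per-edge polynomial list in bipartite-graph order
prepare_polys <- function(bg, v1_optimize) {
  purrr::map(bg$edge_ids, make_edge_polynomial, bg = bg,
             v1_optimize = v1_optimize)
}

# For each position in `order`, the variables whose final edge polynomial
# is multiplied there (they collapse immediately after that product).
collapse_schedule <- function(polys, order_pos, n_var) {
  last_pos <- integer(n_var)
  for (j in seq_along(order_pos)) {
    vs <- polys[[order_pos[j]]]$vars
    last_pos[vs] <- j
  }
  purrr::map(seq_along(order_pos), function(j) which(last_pos == j))
}

# Collapse-cost accounting follows the dense unmerged convention: the term
# count doubles with every two-branch polynomial product, and each round of
# collapses costs (terms present after the product) x (variables collapsing).
virtual_cost <- function(polys, order_pos, sched) {
  virtual <- 1
  ops <- 0
  for (j in seq_along(order_pos)) {
    if (polys[[order_pos[j]]]$q > 0) virtual <- virtual * 2
    ops <- ops + virtual * length(sched[[j]])
  }
  ops
}

#' Multiply and collapse the edge polynomials of a bipartite graph
#'
#' Multiplies the edge polynomials in the given order. After each product,
#' every variable whose last containing polynomial has now been multiplied
#' is collapsed ([collapse_term()] semantics, vectorized over terms), and
#' like terms are merged. The coefficients of the fully collapsed
#' polynomial, read off the powers of t, are the exact distribution of the
#' overlapping-embedding count B.
#'
#' `on_prefix`, if supplied, is called after each of the first
#' `|V2| - 1` products with the current partial t-power distribution (a
#' prefix [b_distribution()], `complete = FALSE`) and the prefix length;
#' returning `FALSE` aborts the product (used for priority-bound early
#' termination).
#'
#' @param bg A [bipartite_graph()].
#' @param order Permutation of `bg$edge_ids` (default: increasing edge id).
#' @param v1_optimize Apply the degree-1 pre-collapse rewrite.
#' @param on_prefix Optional callback `function(dist, j)` returning `TRUE`
#'   to continue.
#' @return List of class `collapse_result` with `dist` (a
#'   [b_distribution()]; `complete = FALSE` if aborted) and `cost` (a
#'   `cost_report`: `collapse_ops`, `peak_terms`, `order`).
#' @export
multiply_collapse <- function(bg, order = NULL, v1_optimize = TRUE,
                              on_prefix = NULL) {
  n2 <- length(bg$edge_ids)
  n1 <- length(bg$var_ids)
  if (is.null(order)) order <- sort(bg$edge_ids)
  order_pos <- match(order, bg$edge_ids)
  if (length(order_pos) != n2 || anyNA(order_pos) ||
      anyDuplicated(order_pos)) {
    stop("order must be a permutation of the V2 edge ids", call. = FALSE)
  }
  polys <- prepare_polys(bg, v1_optimize)
  sched <- collapse_schedule(polys, order_pos, n1)
  # degree-1 variables folded into t powers never collapse via the operator
  collapse_ops <- virtual_cost(polys, order_pos, sched)

  exps <- matrix(0L, nrow = 1, ncol = n1)
  coeff <- 1
  t_exp <- 0L
  peak <- 1L

  for (j in seq_len(n2)) {
    poly <- polys[[order_pos[j]]]
    if (poly$q > 0) {
      exps_p <- exps
      if (length(poly$vars)) {
        exps_p[, poly$vars] <- exps_p[, poly$vars] + 1L
      }
      exps <- rbind(exps_p, exps)
      t_exp <- c(t_exp + poly$pre_t, t_exp)
      coeff <- c(coeff * poly$p, coeff * poly$q)
    } else {
      if (length(poly$vars)) exps[, poly$vars] <- exps[, poly$vars] + 1L
      t_exp <- t_exp + poly$pre_t
      coeff <- coeff * poly$p
    }
    for (v in sched[[j]]) {
      t_exp <- t_exp + as.integer(exps[, v] == bg$deg[v])
      exps[, v] <- 0L
    }
    merged <- merge_terms(exps, coeff, t_exp)
    exps <- merged$exps; coeff <- merged$coeff; t_exp <- merged$t_exp
    peak <- max(peak, length(coeff))
    if (!is.null(on_prefix) && j < n2) {
      dist <- t_marginal(coeff, t_exp, n1, complete = FALSE)
      if (!isTRUE(on_prefix(dist, j))) {
        return(collapse_result(dist, collapse_ops, peak, order,
                               aborted_at = j))
      }
    }
  }
  dist <- t_marginal(coeff, t_exp, n1, complete = TRUE)
  collapse_result(dist, collapse_ops, peak, order)
}

merge_terms <- function(exps, coeff, t_exp) {
  if (length(coeff) <= 1) {
    return(list(exps = exps, coeff = coeff, t_exp = t_exp))
  }
  # key only on columns still carrying exponents
  nz <- which(colSums(exps) > 0L)
  cols <- lapply(nz, function(cc) exps[, cc])
  key <- do.call(paste, c(list(t_exp), cols, sep = ","))
  if (!anyDuplicated(key)) {
    return(list(exps = exps, coeff = coeff, t_exp = t_exp))
  }
  first <- !duplicated(key)
  sums <- rowsum(coeff, key)
  list(exps = exps[first, , drop = FALSE],
       coeff = as.numeric(sums[match(key[first], rownames(sums)), ]),
       t_exp = t_exp[first])
}

t_marginal <- function(coeff, t_exp, n1, complete) {
  probs <- numeric(n1 + 1)
  agg <- rowsum(coeff, t_exp)
  probs[as.integer(rownames(agg)) + 1] <- agg[, 1]
  b_distribution(probs, complete = complete)
}

collapse_result <- function(dist, collapse_ops, peak, order,
                            aborted_at = NA_integer_, extra = list()) {
  cost <- structure(c(list(collapse_ops = collapse_ops, peak_terms = peak,
                           order = order, aborted_at = aborted_at), extra),
                    class = "cost_report")
  structure(list(dist = dist, cost = cost), class = "collapse_result")
}

#' @export
print.cost_report <- function(x, ...) {
  cat(sprintf("# Collapse cost: %g operations, peak %d live terms\n",
              x$collapse_ops, x$peak_terms))
  invisible(x)
}

#' Contribution matrices used to order the edge polynomials
#'
#' `W` relates variables to edge polynomials: `W[r, s] = 1/deg(x_r)` (the
#' variable's degree in the current bipartite graph) when polynomial `Z_s`
#' contains `x_r`, else 0. An entry of 1 marks the final polynomial of a
#' variable. `D` counts the contribution levels of each polynomial:
#' `D[r, s]` is the number of entries of value `1/s` in `W`'s column `r`,
#' times the edge probability of `Z_r`.
#'
#' @param bg A [bipartite_graph()].
#' @return List with matrices `W` (|V1| x |V2|, dimnames from variable and
#'   edge ids) and `D` (|V2| x max degree).
#' @export
ordering_matrices <- function(bg) {
  n1 <- length(bg$var_ids)
  n2 <- length(bg$edge_ids)
  W <- matrix(0, n1, n2,
              dimnames = list(as.character(bg$var_ids),
                              as.character(bg$edge_ids)))
  for (s in seq_len(n2)) {
    vars <- bg$links[[s]]
    W[vars, s] <- 1 / bg$deg[vars]
  }
  maxdeg <- max(bg$deg, 1L)
  D <- matrix(0, n2, maxdeg,
              dimnames = list(as.character(bg$edge_ids),
                              as.character(seq_len(maxdeg))))
  for (s in seq_len(n2)) {
    counts <- tabulate(bg$deg[bg$links[[s]]], nbins = maxdeg)
    D[s, ] <- counts * bg$p[s]
  }
  list(W = W, D = D)
}

#' Greedy ordering of the edge polynomials
#'
#' Chooses, at each step, the edge polynomial contributing to the collapse
#' of the most variables in the current residual bipartite graph: the D
#' matrix is scanned left to right (column s holds contributions at level
#' 1/s), keeping the rows maximizing each column; remaining ties are broken
#' by lowest edge id (a deterministic stand-in for a random choice, so runs
#' are reproducible). The chosen edge is removed along with its incident
#' links and degrees are recomputed.
#'
#' @param bg A [bipartite_graph()].
#' @return The edge ids of `bg` in multiplication order.
#' @export
order_polynomials <- function(bg) {
  remaining <- seq_along(bg$edge_ids)
  out <- integer(0)
  while (length(remaining) > 1) {
    deg_cur <- tabulate(unlist(bg$links[remaining]),
                        nbins = length(bg$var_ids))
    maxdeg <- max(deg_cur, 1L)
    D <- do.call(rbind, lapply(remaining, function(s) {
      tabulate(deg_cur[bg$links[[s]]], nbins = maxdeg) * bg$p[s]
    }))
    cand <- seq_along(remaining)
    for (s in seq_len(maxdeg)) {
      vals <- D[cand, s]
      cand <- cand[vals == max(vals)]
      if (length(cand) == 1) break
    }
    pick <- remaining[cand[which.min(bg$edge_ids[remaining[cand]])]]
    out <- c(out, pick)
    remaining <- setdiff(remaining, pick)
  }
  bg$edge_ids[c(out, remaining)]
}

#' Memory-bounded polynomial product
#'
#' Computes the same collapsed distribution as [multiply_collapse()] while
#' never holding more than about `max_terms` polynomial terms in memory.
#' Each product step multiplies the next edge polynomial with an active
#' batch of at most N1 terms, deferring the rest on a last-in, first-out
#' stack tagged with the index of the next unapplied polynomial; deferred
#' batches are completed after the main pass. After j products of the main
#' pass the live term count is at most (j + 1) * N1 + N2. The batch sizes
#' are N1 = max(1, floor(max_terms / (|V2| + 1))) and N2 the remainder, so
#' the bound never exceeds `max_terms`.
#'
#' @inheritParams multiply_collapse
#' @param max_terms Live-term budget (>= 2); `Inf` reduces to
#'   [multiply_collapse()] exactly.
#' @return A `collapse_result`; its cost report additionally carries
#'   `memory_trace`, a tibble with the live-term count and the
#'   (j + 1) * N1 + N2 bound after each main-pass product.
#' @export
multiply_collapse_bounded <- function(bg, order = NULL, max_terms = Inf,
                                      v1_optimize = TRUE) {
  if (is.infinite(max_terms)) return(multiply_collapse(bg, order, v1_optimize))
  if (max_terms < 2) {
    stop("max_terms must be at least 2 to hold one bifurcation",
         call. = FALSE)
  }
  n2 <- length(bg$edge_ids)
  n1 <- length(bg$var_ids)
  if (is.null(order)) order <- sort(bg$edge_ids)
  order_pos <- match(order, bg$edge_ids)
  if (length(order_pos) != n2 || anyNA(order_pos) ||
      anyDuplicated(order_pos)) {
    stop("order must be a permutation of the V2 edge ids", call. = FALSE)
  }
  polys <- prepare_polys(bg, v1_optimize)
  sched <- collapse_schedule(polys, order_pos, n1)
  collapse_ops <- virtual_cost(polys, order_pos, sched)

  N1 <- max(1L, floor(max_terms / (n2 + 1)))
  N2 <- max(0L, max_terms - (n2 + 1L) * N1)

  probs <- numeric(n1 + 1)
  stack <- list(list(exps = matrix(0L, 1, n1), coeff = 1, t_exp = 0L,
                     next_j = 1L))
  deferred_n <- 0L
  peak <- 1L
  main_pass <- TRUE
  trace_live <- numeric(0)
  trace_j <- integer(0)

  first_batch <- TRUE
  while (length(stack) > 0) {
    batch <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    if (!first_batch) deferred_n <- deferred_n - length(batch$coeff)
    first_batch <- FALSE
    exps <- batch$exps; coeff <- batch$coeff; t_exp <- batch$t_exp
    j0 <- batch$next_j
    if (j0 > n2) {
      agg <- rowsum(coeff, t_exp)
      probs[as.integer(rownames(agg)) + 1] <-
        probs[as.integer(rownames(agg)) + 1] + agg[, 1]
      next
    }
    for (j in j0:n2) {
      if (length(coeff) > N1) {
        keep <- seq_len(N1)
        stack[[length(stack) + 1]] <- list(
          exps = exps[-keep, , drop = FALSE], coeff = coeff[-keep],
          t_exp = t_exp[-keep], next_j = j
        )
        deferred_n <- deferred_n + (length(coeff) - N1)
        exps <- exps[keep, , drop = FALSE]
        coeff <- coeff[keep]
        t_exp <- t_exp[keep]
      }
      poly <- polys[[order_pos[j]]]
      if (poly$q > 0) {
        exps_p <- exps
        if (length(poly$vars)) {
          exps_p[, poly$vars] <- exps_p[, poly$vars] + 1L
        }
        exps <- rbind(exps_p, exps)
        t_exp <- c(t_exp + poly$pre_t, t_exp)
        coeff <- c(coeff * poly$p, coeff * poly$q)
      } else {
        if (length(poly$vars)) exps[, poly$vars] <- exps[, poly$vars] + 1L
        t_exp <- t_exp + poly$pre_t
        coeff <- coeff * poly$p
      }
      for (v in sched[[j]]) {
        t_exp <- t_exp + as.integer(exps[, v] == bg$deg[v])
        exps[, v] <- 0L
      }
      merged <- merge_terms(exps, coeff, t_exp)
      exps <- merged$exps; coeff <- merged$coeff; t_exp <- merged$t_exp
      live <- length(coeff) + deferred_n
      peak <- max(peak, live)
      if (main_pass) {
        trace_j <- c(trace_j, j)
        trace_live <- c(trace_live, live)
      }
    }
    main_pass <- FALSE
    agg <- rowsum(coeff, t_exp)
    probs[as.integer(rownames(agg)) + 1] <-
      probs[as.integer(rownames(agg)) + 1] + agg[, 1]
  }
  trace <- tibble::tibble(j = trace_j, live = trace_live,
                          bound = (trace_j + 1) * N1 + N2)
  collapse_result(b_distribution(probs), collapse_ops, peak, order,
                  extra = list(memory_trace = trace, N1 = N1, N2 = N2))
}
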