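test_that("edge polynomials carry the linked variables; degree-1 variables pre-collapse to t", {
  bg <- fig4_bg()
  z2 <- make_edge_polynomial(bg, 2L, v1_optimize = FALSE)
  expect_equal(z2$vars, c(1L, 2L, 3L)) # p2 x1 x2 x3 + q2
  expect_equal(z2$pre_t, 0L)
  z1 <- make_edge_polynomial(bg, 1L, v1_optimize = TRUE)
  expect_equal(z1$vars, 1L) # x1 has degree 3: stays a variable
  z8 <- make_edge_polynomial(bg, 8L, v1_optimize = TRUE)
  expect_equal(z8$vars, integer(0)) # x6 has degree 1: p8 t + q8
  expect_equal(z8$pre_t, 1L)
  expect_error(make_edge_polynomial(bg, 99L), "not in V2")
})

test_that("collapse operator keeps or drops the t increment by exponent vs degree", {
  # the worked term q1 p2 p4 q8 x1^2 x2^2 x3^2 x5
  term <- list(coeff = 0.5 * 0.5 * 0.5 * 0.5, t_exp = 0L,
               x_exps = c(x1 = 2L, x2 = 2L, x3 = 2L, x5 = 1L))
  t1 <- collapse_term(term, "x1", degree = 3)
  expect_equal(t1$t_exp, 0L) # exponent 2 != degree 3: removed silently
  expect_false("x1" %in% names(t1$x_exps))
  t2 <- collapse_term(term, "x2", degree = 2)
  expect_equal(t2$t_exp, 1L) # exponent equals degree: replaced by t
  # full collapse yields t^3 with unchanged coefficient
  full <- term
  for (spec in list(c("x1", 3), c("x2", 2), c("x3", 2), c("x5", 1))) {
    full <- collapse_term(full, spec[1], as.numeric(spec[2]))
  }
  expect_equal(full$t_exp, 3L)
  expect_length(full$x_exps, 0)
  expect_equal(full$coeff, term$coeff)
})

test_that("worked-example collapse costs: 48 for Z1,Z2,Z4,Z8 and 34 for Z4,Z2,Z8,Z1", {
  bg <- fig4_bg()
  r_bad <- multiply_collapse(bg, order = c(1L, 2L, 4L, 8L),
                             v1_optimize = FALSE)
  expect_equal(r_bad$cost$collapse_ops, 48)
  r_good <- multiply_collapse(bg, order = c(4L, 2L, 8L, 1L),
                              v1_optimize = FALSE)
  expect_equal(r_good$cost$collapse_ops, 34)
  expect_dist_equal(r_bad$dist, r_good$dist)
})

test_that("single Bernoulli neighbour gives the two-point distribution", {
  bg <- bipartite_graph(edge_ids = 1L, p = 0.3, links = list(1L))
  r <- multiply_collapse(bg)
  expect_equal(as.numeric(r$dist), c(0.7, 0.3))
})

test_that("ordering matrices match the worked example", {
  om <- ordering_matrices(fig4_bg(p = c(0.5, 0.5, 0.5, 0.5)))
  expect_equal(om$W["x2", "2"], 1 / 2)
  expect_equal(om$W["x2", "4"], 1 / 2)
  expect_equal(om$W["x1", "1"], 1 / 3)
  # second row of D is [0, 2 p2, p2]
  expect_equal(unname(om$D["2", ]), c(0, 2 * 0.5, 0.5))
})

test_that("greedy ordering picks Z4 first when p4 = p8", {
  ord <- order_polynomials(fig4_bg())
  expect_equal(ord[1], 4L)
  # and never exceeds the identity-order cost on the worked example
  bg <- fig4_bg()
  expect_lte(multiply_collapse(bg, ord, v1_optimize = FALSE)$cost$collapse_ops,
             multiply_collapse(bg, c(1L, 2L, 4L, 8L),
                               v1_optimize = FALSE)$cost$collapse_ops)
})

test_that("engine matches the exhaustive distribution on random bipartite graphs", {
  worst <- 0
  for (seed in 1:40) {
    bg <- random_bg(n1 = sample(2:6, 1), n2 = sample(2:9, 1), seed = seed)
    got <- multiply_collapse(bg)$dist
    want <- exact_b_distribution(bg)
    worst <- max(worst, max(abs(as.numeric(got) - as.numeric(want))))
  }
  expect_lt(worst, 1e-10)
})

test_that("the answer is order-invariant; only the cost changes", {
  for (seed in 1:15) {
    bg <- random_bg(n1 = sample(2:5, 1), n2 = sample(3:8, 1),
                    seed = seed + 100)
    ref <- multiply_collapse(bg)$dist
    set.seed(seed)
    rand_order <- sample(bg$edge_ids)
    expect_dist_equal(multiply_collapse(bg, rand_order)$dist, ref)
    expect_dist_equal(multiply_collapse(bg, order_polynomials(bg))$dist, ref)
    expect_dist_equal(
      multiply_collapse_bounded(bg, max_terms = 16)$dist, ref)
    expect_dist_equal(multiply_collapse(bg, v1_optimize = FALSE)$dist, ref)
  }
})

test_that("probability mass is conserved at every prefix", {
  for (seed in 1:10) {
    bg <- random_bg(4, 7, seed + 200)
    sums <- c()
    multiply_collapse(bg, on_prefix = function(dist, j) {
      sums <<- c(sums, sum(dist))
      TRUE
    })
    expect_true(all(abs(sums - 1) < 1e-9))
  }
})

test_that("tail probabilities and expectation grow monotonically with the prefix", {
  for (seed in 1:50) {
    bg <- random_bg(n1 = sample(2:5, 1), n2 = sample(3:9, 1),
                    seed = seed + 300)
    prefixes <- list()
    res <- multiply_collapse(bg, on_prefix = function(dist, j) {
      prefixes[[j]] <<- dist
      TRUE
    })
    prefixes[[length(bg$edge_ids)]] <- res$dist
    n1 <- length(bg$var_ids)
    for (j in seq_len(length(prefixes) - 1)) {
      for (tau in 0:n1) {
        expect_gte(promote:::b_tail(prefixes[[j + 1]], tau),
                   promote:::b_tail(prefixes[[j]], tau) - 1e-12)
      }
      expect_gte(b_expectation(prefixes[[j + 1]]),
                 b_expectation(prefixes[[j]]) - 1e-12)
    }
  }
})

test_that("memory-bounded product matches the unbounded one and respects its bound", {
  for (seed in 1:50) {
    bg <- random_bg(n1 = sample(3:6, 1), n2 = 8, seed = seed + 400)
    free <- multiply_collapse(bg)
    capped <- multiply_collapse_bounded(bg, max_terms = 16)
    expect_dist_equal(capped$dist, free$dist)
    trace <- capped$cost$memory_trace
    expect_true(all(trace$live <= trace$bound))
    expect_lte(capped$cost$peak_terms, free$cost$peak_terms)
  }
})

test_that("an infinite budget reduces exactly to the unbounded product", {
  bg <- random_bg(4, 6, 999)
  free <- multiply_collapse(bg)
  inf <- multiply_collapse_bounded(bg, max_terms = Inf)
  expect_identical(as.numeric(inf$dist), as.numeric(free$dist))
  expect_identical(inf$cost$collapse_ops, free$cost$collapse_ops)
  expect_identical(inf$cost$peak_terms, free$cost$peak_terms)
  expect_error(multiply_collapse_bounded(bg, max_terms = 1), "at least 2")
})

test_that("invalid orders are rejected", {
  bg <- fig4_bg()
  expect_error(multiply_collapse(bg, order = c(1L, 2L, 4L)), "permutation")
  expect_error(multiply_collapse(bg, order = c(1L, 2L, 4L, 4L)),
               "permutation")
})
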