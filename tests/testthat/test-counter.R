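test_that("loss is one plus the expected overlap count", {
  expect_equal(loss_value(b_distribution(1)), 1) # point mass at 0
  expect_equal(loss_value(b_distribution(c(0.5, 0, 0.5))), 2)
  # against the exhaustive oracle
  bg <- random_bg(4, 6, 77)
  expect_equal(loss_value(multiply_collapse(bg)$dist),
               1 + b_expectation(exact_b_distribution(bg)),
               tolerance = 1e-12)
})

test_that("priority is gain over loss", {
  expect_equal(priority_value(0.8, 1), 0.8) # isolated embedding
  expect_equal(priority_value(0.4, 2), priority_value(0.8, 2) / 2)
  expect_error(priority_value(0, 1))
})

test_that("prefix priorities upper-bound the exact priority", {
  for (seed in 1:50) {
    bg <- random_bg(n1 = sample(2:5, 1), n2 = sample(3:8, 1),
                    seed = seed + 500)
    gain <- 0.6
    prefix_rhos <- c()
    res <- multiply_collapse(bg, on_prefix = function(dist, j) {
      prefix_rhos <<- c(prefix_rhos, gain / loss_value(dist))
      TRUE
    })
    rho_exact <- gain / loss_value(res$dist)
    expect_true(all(prefix_rhos >= rho_exact - 1e-12))
    # and they decrease as the prefix grows
    expect_true(all(diff(prefix_rhos) <= 1e-12))
  }
})

test_that("proxy order ranks by gain over degree, isolated first", {
  embeds <- tibble::tibble(
    id = 1:4,
    node_set = list("a", "b", "c", "d"),
    edge_ids = list(1L, 2L, 3L, 4L),
    gain = c(0.5, 0.5, 0.9, 0.2)
  )
  og <- structure(list(ids = 1:4,
                       nbrs = list(integer(0), c(3L, 4L), c(2L, 4L),
                                   c(2L, 3L)),
                       deg = c(0L, 2L, 2L, 2L), measure = "F2"),
                  class = "overlap_graph")
  expect_equal(proxy_order(embeds, og), c(1L, 3L, 2L, 4L))
})

test_that("proxy order agrees with an explicit Q sort on random instances", {
  for (seed in 1:20) {
    net <- small_random_net(9, 13, seed + 600)
    em <- enumerate_embeddings(net, "M1")
    if (nrow(em) == 0) next
    og <- build_overlap_graph(em, "F2")
    q <- ifelse(og$deg == 0, Inf, em$gain / og$deg)
    expect_equal(proxy_order(em, og), em$id[order(-q, em$id)])
  }
})

test_that("early termination never changes the selected embedding", {
  for (seed in 1:20) {
    net <- small_random_net(10, 14, seed + 700)
    em <- enumerate_embeddings(net, "M1")
    if (nrow(em) == 0) next
    og <- build_overlap_graph(em, "F2")
    on <- best_embedding(og, em, net, strategy1 = TRUE)
    off <- best_embedding(og, em, net, strategy1 = FALSE)
    expect_equal(on$id, off$id)
    expect_equal(off$n_pruned, 0)
  }
})

test_that("pruning fires when the proxy front-loads a dominant embedding", {
  # an isolated high-gain triangle plus a dense cluster of weak 2-paths
  net <- prob_network(data.frame(
    from = c("a", "b", "a", "x", "x", "x", "x"),
    to = c("b", "c", "c", "u", "v", "w", "y"),
    p = c(0.95, 0.95, 0.95, 0.2, 0.2, 0.2, 0.2)
  ))
  em <- enumerate_embeddings(net, "M1")
  og <- build_overlap_graph(em, "F2")
  sel <- best_embedding(og, em, net, strategy1 = TRUE)
  expect_gt(sel$n_pruned, 0)
  expect_equal(sel$id, best_embedding(og, em, net, strategy1 = FALSE)$id)
})

test_that("two disjoint triangles are both chosen with expected count 0.25", {
  net <- prob_network(data.frame(
    from = c("a", "b", "a", "d", "e", "d"),
    to = c("b", "c", "c", "e", "f", "f"),
    p = 0.5
  ))
  res <- count_independent(net, "M2")
  expect_equal(nrow(res$chosen), 2)
  expect_equal(res$expected_count, 2 * 0.5^3)
  expect_equal(glance(res)$n_chosen, 2)
})

test_that("on a deterministic network the count equals the least-overlap greedy count", {
  for (seed in 1:8) {
    net <- binarize(small_random_net(9, 12, seed + 800))
    for (measure in c("F2", "F3")) {
      res <- count_independent(net, "M1", measure)
      det <- deterministic_count(net, "M1", measure)
      expect_equal(res$expected_count, det$count)
    }
  }
})

test_that("chosen sets are independent and their value matches the exhaustive expectation", {
  for (seed in 1:10) {
    net <- small_random_net(8, 9, seed + 900)
    for (measure in c("F2", "F3")) {
      res <- count_independent(net, "M1", measure)
      em <- enumerate_embeddings(net, "M1")
      og <- build_overlap_graph(em, measure)
      ids <- res$chosen$id
      for (id in ids) {
        expect_length(intersect(og$nbrs[[match(id, og$ids)]], ids), 0)
      }
      expect_equal(res$expected_count,
                   expected_count_given_set(net, em, ids),
                   tolerance = 1e-12)
    }
  }
})

test_that("strategy toggles change costs, never the selection", {
  grid <- expand.grid(s1 = c(TRUE, FALSE), s2 = c(TRUE, FALSE),
                      s3 = c(TRUE, FALSE))
  for (seed in 1:10) {
    model <- c("er", "ws", "ba")[1 + seed %% 3]
    net <- generate_network(model, 25, seed = seed + 40)
    ref <- count_independent(net, "M1", strategy1 = FALSE,
                             strategy2 = FALSE, strategy3 = FALSE)
    for (r in seq_len(nrow(grid))) {
      res <- count_independent(net, "M1", strategy1 = grid$s1[r],
                               strategy2 = grid$s2[r],
                               strategy3 = grid$s3[r], max_terms = 64)
      expect_equal(res$chosen$id, ref$chosen$id)
      expect_equal(res$expected_count, ref$expected_count)
    }
  }
})

test_that("the greedy count approaches the exact optimum on small instances", {
  ratios <- c()
  for (seed in 1:10) {
    net <- small_random_net(7, 9, seed + 1000)
    opt <- exact_def1_solution(net, "M1", "F2", max_embeddings = 40)
    if (opt$value == 0) next
    got <- count_independent(net, "M1", "F2")$expected_count
    expect_lte(got, opt$value + 1e-12) # heuristic bounded by the optimum
    ratios <- c(ratios, got / opt$value)
  }
  expect_gte(mean(ratios), 0.9)
  # on two disjoint triangles the heuristic is exact
  net <- prob_network(data.frame(
    from = c("a", "b", "a", "d", "e", "d"),
    to = c("b", "c", "c", "e", "f", "f"),
    p = 0.5
  ))
  expect_equal(count_independent(net, "M2")$expected_count,
               exact_def1_solution(net, "M2")$value)
})

test_that("tidiers and autoplot expose the selection", {
  net <- generate_network("er", 20, seed = 3)
  res <- count_independent(net, "M1")
  td <- tidy(res)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), nrow(res$chosen))
  gl <- glance(res)
  expect_equal(gl$expected_count, res$expected_count)
  expect_s3_class(autoplot(res), "ggplot")
  expect_s3_class(autoplot(b_distribution(c(0.25, 0.5, 0.25))), "ggplot")
})
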