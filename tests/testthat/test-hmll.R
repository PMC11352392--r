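test_that("planted pure 3-uniform bipartition is recovered at the enumeration maximum", {
  ph <- simulate_planted_hypergraph(planted_config(8, 2, edge_sizes = 3,
                                                   p_within = 1, p_between = 0,
                                                   seed = 1))
  par <- modularity_params(c(`3` = 1), gamma = c(`3` = 1e-4))
  pt <- hmll(ph$hypergraph, params = par, n_restarts = 20, seed = 3,
             audit = TRUE)
  expect_equal(adjusted_rand_index(ph$truth, pt$labels), 1)
  expect_equal(pt$n_clusters, 2L)
  # against exhaustive enumeration of all 4140 set partitions
  parts <- all_partitions(8)
  qbest <- max(vapply(parts, function(z)
    hypergraph_modularity(ph$hypergraph, z, par), numeric(1)))
  expect_equal(pt$Q, qbest, tolerance = 1e-9)
  expect_lt(pt$audit_max_dev, 1e-9)
})

test_that("edgeless hypergraphs stay all-singleton", {
  g <- hypergraph(list(), 6)
  pt <- hmll(g, params = modularity_params(c(`2` = 1), gamma = c(`2` = 0.1)),
             n_restarts = 3, seed = 1)
  expect_equal(pt$n_clusters, 6L)
  expect_equal(pt$Q, 0)
})

test_that("hmll is deterministic given seed and config", {
  ph <- simulate_planted_hypergraph(planted_config(10, 2, edge_sizes = c(2, 3),
                                                   p_within = c(0.8, 0.5),
                                                   p_between = c(0.15, 0.05),
                                                   seed = 4))
  a <- hmll(ph$hypergraph, params = "estimate", n_restarts = 5, seed = 9)
  b <- hmll(ph$hypergraph, params = "estimate", n_restarts = 5, seed = 9)
  expect_identical(a$labels, b$labels)
  expect_identical(a$Q, b$Q)
  expect_identical(a$restart, b$restart)
})

test_that("incremental dQ matches full recomputation on random instances", {
  for (rep in 1:8) {
    g <- random_hg(n = 10, m = 18, sizes = 2:4, seed = 90 + rep)
    pt <- hmll(g, params = "default", n_restarts = 5, seed = rep,
               audit = TRUE)
    expect_lt(pt$audit_max_dev, 1e-9)
    # returned Q agrees with a from-scratch evaluation of the partition
    expect_equal(pt$Q,
                 hypergraph_modularity(
                   idhypergraph:::hmll_work(g, FALSE)$g, pt$labels, pt$params),
                 tolerance = 1e-9)
  }
})

test_that("singleton hyperedges are excluded from clustering by default", {
  # two components joined only through a singleton edge's vertex
  g <- hypergraph(list(c(1, 2), c(1, 2), 3L, c(3, 4), c(3, 4)), 4)
  p1 <- hmll(g, params = "default", n_restarts = 5, seed = 2)
  p2 <- hmll(g, params = "default", n_restarts = 5, seed = 2,
             include_singletons = TRUE)
  # both find {1,2} and {3,4}; Q differs because the singleton edge inflates
  # the volume term when included
  expect_equal(adjusted_rand_index(p1$labels, c(1, 1, 2, 2)), 1)
  expect_false(isTRUE(all.equal(p1$Q, p2$Q)))
})

test_that("estimate mode recovers a mixed-size planted bipartition", {
  ph <- simulate_planted_hypergraph(planted_config(10, 2, edge_sizes = c(2, 3),
                                                   p_within = c(0.9, 0.7),
                                                   p_between = c(0.1, 0.05),
                                                   seed = 7))
  pt <- hmll(ph$hypergraph, params = "estimate", n_restarts = 10, seed = 5)
  expect_equal(adjusted_rand_index(ph$truth, pt$labels), 1)
  expect_gt(pt$params$beta[["3"]], 0)
})

test_that("super-node merges leave the flat-partition Q reproducible", {
  # the merge pass must never report a Q different from direct recomputation
  for (rep in 1:5) {
    g <- random_hg(n = 12, m = 20, sizes = 2:4, seed = 130 + rep)
    pt <- hmll(g, params = "default", n_restarts = 8, seed = rep, audit = TRUE)
    expect_lt(pt$audit_max_dev, 1e-9)
  }
})
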