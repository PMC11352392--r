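test_that("cut_k matches hand counts on the triangle hypergraph", {
  tri <- triangle_hg()
  expect_equal(cut_k(tri, c(1, 1, 2), 2), 2)
  expect_equal(cut_k(tri, c(1, 1, 1), 2), 0)
  expect_equal(cut_k(tri, c(1, 2, 3), 2), 3)
  # absent size: empty sum
  expect_equal(cut_k(tri, c(1, 1, 2), 3), 0)
})

test_that("volume_term matches hand arithmetic and conservation at k = 1", {
  tri <- triangle_hg()
  expect_equal(volume_term(tri, c(1, 1, 2), 2), 20)
  expect_equal(volume_term(tri, c(1, 1, 1), 2), 36)
  # k = 1 is the total volume, identical for every partition
  for (z in list(c(1, 1, 1), c(1, 2, 1), c(1, 2, 3))) {
    expect_equal(volume_term(tri, z, 1), 6)
  }
})

test_that("volume powers beyond 2^53 are computed exactly, not wrapped", {
  # one cluster of volume 3^20 would overflow naive 64-bit powers at k = 3;
  # build a hypergraph whose vertex degree is large via multiplicity
  g <- hypergraph(list(c(1, 2)), 2, multiplicities = 100000L)
  # vol(C) = 200000 for the merged cluster; 200000^4 = 1.6e21 > 2^53
  v <- volume_term(g, c(1, 1), 4)
  expect_equal(v, 2e5^4, tolerance = 1e-15)
  # split: 1e5^4 + 1e5^4
  expect_equal(volume_term(g, c(1, 2), 4), 2 * 1e5^4, tolerance = 1e-15)
  # internal big-integer helpers agree with double arithmetic where exact
  expect_equal(idhypergraph:::big_to_double(
    idhypergraph:::big_pow(idhypergraph:::big_from_num(3), 33)), 3^33)
  expect_equal(idhypergraph:::big_to_double(idhypergraph:::big_add(
    idhypergraph:::big_from_num(2^52), idhypergraph:::big_from_num(2^52))),
    2^53)
})

test_that("modularity follows the printed sign convention", {
  # two vertices, one edge: together Q = -0.4, apart Q = -1.2
  g <- hypergraph(list(c(1, 2)), 2)
  p <- modularity_params(c(`2` = 1), gamma = c(`2` = 0.1))
  expect_equal(hypergraph_modularity(g, c(1, 1), p), -0.4)
  expect_equal(hypergraph_modularity(g, c(1, 2), p), -1.2)
  # triangle: split Q = -(2 + 20 g2), merged Q = -36 g2
  tri <- triangle_hg()
  g2 <- 0.05
  p2 <- modularity_params(c(`2` = 1), gamma = c(`2` = g2))
  expect_equal(hypergraph_modularity(tri, c(1, 1, 2), p2), -(2 + 20 * g2))
  expect_equal(hypergraph_modularity(tri, c(1, 1, 1), p2), -36 * g2)
  # zero parameters give zero modularity for every partition
  p0 <- modularity_params(c(`2` = 0), gamma = c(`2` = 0))
  expect_equal(hypergraph_modularity(tri, c(1, 2, 3), p0), 0)
  # missing size is a configuration error
  g3 <- hypergraph(list(c(1, 2, 3)), 3)
  expect_error(hypergraph_modularity(g3, c(1, 1, 1), p0), "missing")
})

test_that("modularity is invariant under cluster relabeling", {
  set.seed(9)
  for (rep in 1:10) {
    g <- random_hg(n = 8, m = 12, seed = 50 + rep)
    par <- default_modularity_params(g)
    z <- sample(1:3, 8, replace = TRUE)
    perm <- sample(3)
    expect_equal(hypergraph_modularity(g, z, par),
                 hypergraph_modularity(g, perm[z], par))
  }
})

test_that("cut conservation: cut_k + interior_k = m_k for all partitions", {
  for (rep in 1:10) {
    g <- random_hg(n = 7, m = 15, sizes = 2:4, seed = 70 + rep)
    sz <- edge_sizes(g)
    z <- with_seed_t(rep, sample(1:3, 7, replace = TRUE))
    for (k in unique(sz)) {
      mk <- sum(g$multiplicities[sz == k])
      interior <- sum(vapply(which(sz == k), function(j) {
        zi <- z[g$edges[[j]]]
        if (all(zi == zi[1L])) g$multiplicities[j] else 0
      }, numeric(1)))
      expect_equal(cut_k(g, z, k) + interior, mk)
    }
  }
})

test_that("2-uniform modularity equals a direct graph implementation", {
  set.seed(10)
  for (rep in 1:8) {
    n <- sample(5:9, 1)
    em <- t(combn(n, 2))
    keep <- runif(nrow(em)) < 0.5
    if (!any(keep)) next
    em <- em[keep, , drop = FALSE]
    mult <- sample(1:2, nrow(em), replace = TRUE)
    g <- hypergraph(split(em, row(em)), n, multiplicities = mult)
    beta2 <- 1; gamma2 <- runif(1, 0.001, 0.1)
    par <- modularity_params(c(`2` = beta2), gamma = c(`2` = gamma2))
    d <- degrees(g)$vertex
    for (r2 in 1:5) {
      z <- sample(1:3, n, replace = TRUE)
      expect_equal(hypergraph_modularity(g, z, par),
                   graph_objective(em, mult, z, beta2, gamma2, d))
    }
  }
})

test_that("estimate_params behaves per its rate contracts", {
  # planted: all edges interior -> clamped beta hits its cap, gamma > 0
  g <- hypergraph(list(c(1, 2, 3), c(4, 5, 6)), 6)
  z <- c(1, 1, 1, 2, 2, 2)
  p <- estimate_params(g, z)
  expect_true(is.finite(p$beta[["3"]]))
  expect_gt(p$beta[["3"]], 0)
  expect_gt(p$gamma_scaled[["3"]], 0)
  # equal interior and exterior rates -> beta = 0: two equal-volume
  # clusters (P2 = 0.5) with as much interior as cut mass
  g2 <- hypergraph(list(c(1, 2), c(3, 4), c(1, 3), c(2, 4)), 4)
  p2 <- estimate_params(g2, c(1, 1, 2, 2))
  expect_equal(unname(p2$beta[["2"]]), 0)
  # mostly-interior planted instance at equal volumes -> beta > 0
  g3 <- hypergraph(list(c(1, 2), c(1, 2), c(3, 4), c(3, 4), c(2, 3)), 4)
  p3 <- estimate_params(g3, c(1, 1, 2, 2))
  expect_gt(p3$beta[["2"]], 0)
  # single-cluster partition falls back to defaults
  pd <- estimate_params(g3, rep(1, 4))
  expect_equal(pd$beta, default_modularity_params(g3)$beta)
})
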