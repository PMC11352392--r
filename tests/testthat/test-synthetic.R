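test_that("cohort simulation is seed-deterministic and validates config", {
  a <- simulate_cohort(cohort_config(n_case = 20, n_control = 15,
                                     n_features = 30, n_subtypes = 2,
                                     regions_per_subtype = 5, seed = 5))
  b <- simulate_cohort(cohort_config(n_case = 20, n_control = 15,
                                     n_features = 30, n_subtypes = 2,
                                     regions_per_subtype = 5, seed = 5))
  expect_identical(a$features$values, b$features$values)
  expect_identical(a$truth, b$truth)
  expect_identical(a$features$covariates, b$features$covariates)
  # truth labels separate from the table; one per case in table order
  expect_length(a$truth, 20L)
  expect_false("truth" %in% colnames(a$features$covariates))
  # infeasible block allocation
  expect_error(cohort_config(n_features = 10, n_subtypes = 4,
                             regions_per_subtype = 5), "fit")
  expect_error(cohort_config(n_case = 3, n_subtypes = 5), "subtypes")
})

test_that("planted shifts move exactly the intended region blocks", {
  cfg <- cohort_config(n_case = 300, n_control = 300, n_features = 20,
                       n_subtypes = 2, regions_per_subtype = 5,
                       effect_size = 3, noise_sd = 0.1, site_count = 1,
                       seed = 6)
  sim <- simulate_cohort(cfg)
  cases <- group_values(sim$features, "case")
  ctrl <- group_values(sim$features, "control")
  k1 <- sim$truth == 1
  shift_obs <- colMeans(cases[k1, ]) - colMeans(ctrl)
  expect_equal(unname(shift_obs[1:5]), rep(0.3, 5), tolerance = 0.05)
  expect_equal(unname(shift_obs[11:20]), rep(0, 10), tolerance = 0.05)
})

test_that("zero effect size leaves the two groups distributionally identical", {
  # scaled-down version of the calibration contract: pooled-feature t-test
  # non-significant for the vast majority of seeds
  pvals <- vapply(1:20, function(s) {
    sim <- simulate_cohort(cohort_config(n_case = 25, n_control = 25,
                                         n_features = 20, n_subtypes = 2,
                                         regions_per_subtype = 5,
                                         effect_size = 0, site_count = 1,
                                         seed = 500 + s))
    stats::t.test(rowMeans(group_values(sim$features, "case")),
                  rowMeans(group_values(sim$features, "control")))$p.value
  }, numeric(1))
  expect_gte(sum(pvals > 0.05), 17L)
})

test_that("planted hypergraph generation enumerates exactly when it can", {
  cfg <- planted_config(8, 2, edge_sizes = 3, p_within = 1, p_between = 0,
                        seed = 2)
  ph <- simulate_planted_hypergraph(cfg)
  # all C(4,3) = 4 triples per block, nothing else
  expect_length(ph$hypergraph$edges, 8L)
  expect_equal(cut_k(ph$hypergraph, ph$truth, 3), 0)
  # determinism
  ph2 <- simulate_planted_hypergraph(cfg)
  expect_identical(ph$hypergraph$edges, ph2$hypergraph$edges)
  # no planted signal when p_within = p_between
  cfg0 <- planted_config(9, 3, edge_sizes = 2, p_within = 0.3,
                         p_between = 0.3, seed = 3)
  ph0 <- simulate_planted_hypergraph(cfg0)
  par <- default_modularity_params(ph0$hypergraph)
  q_true <- hypergraph_modularity(ph0$hypergraph, ph0$truth, par)
  q_rand <- vapply(1:30, function(i) {
    hypergraph_modularity(ph0$hypergraph,
                          with_seed_t(i, sample(1:3, 9, replace = TRUE)), par)
  }, numeric(1))
  # truth is statistically indistinguishable from random partitions
  expect_lt(abs(q_true - mean(q_rand)) / stats::sd(q_rand), 3)
  expect_error(planted_config(5, p_within = 1.4), "\\[0, 1\\]")
})

test_that("adjusted Rand index matches its contingency definition", {
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c(1, 1, 2, 2)), 1)
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c(7, 7, 3, 3)), 1)
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c(1, 2, 1, 2)), -0.5)
  expect_error(adjusted_rand_index(1:3, 1:4), "equal length")
  # expectation near zero under independent random labelings
  set.seed(44)
  aris <- replicate(200, adjusted_rand_index(sample(1:3, 40, TRUE),
                                             sample(1:3, 40, TRUE)))
  expect_lt(abs(mean(aris)), 0.03)
})

test_that("pipeline recovery improves with effect size (scaled-down)", {
  ari_at <- function(es, seeds) {
    mean(vapply(seeds, function(s) {
      sim <- simulate_cohort(cohort_config(n_case = 60, n_control = 50,
                                           n_features = 60, n_subtypes = 2,
                                           regions_per_subtype = 15,
                                           effect_size = es, seed = 700 + s))
      X <- deviation_matrix(sim$features)
      g <- build_id_hypergraph(X, enet_config(selection = "frac", seed = s))
      pt <- hmll(merge_duplicates(g), params = "estimate", n_restarts = 5,
                 seed = s)
      adjusted_rand_index(sim$truth, pt$labels)
    }, numeric(1)))
  }
  lo <- ari_at(0, 1:3)
  hi <- ari_at(3, 1:3)
  expect_lt(abs(lo), 0.25)
  expect_gt(hi, lo + 0.3)
})
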