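test_that("KKT bound: lambda1 >= 2 max|x_j . x| gives an exactly zero fit", {
  set.seed(2)
  for (rep in 1:5) {
    P <- matrix(rnorm(10 * 4), 10, 4)
    x <- rnorm(10)
    lmax <- enet_lambda_max(x, P)
    f <- enet_fit(x, P, lambda1 = lmax, lambda2 = 0.3, standardize = FALSE)
    expect_identical(unname(f$coefficients), rep(0, 4))
    f2 <- enet_fit(x, P, lambda1 = lmax * 1.5, lambda2 = 0.3,
                   standardize = FALSE)
    expect_identical(unname(f2$coefficients), rep(0, 4))
    # just below the bound the fit is nonzero
    f3 <- enet_fit(x, P, lambda1 = lmax * 0.99, lambda2 = 0.3,
                   standardize = FALSE)
    expect_gt(sum(f3$coefficients != 0), 0)
  }
})

test_that("single-predictor closed form: w = (2 - 0.2) / (2 (1 + 0.5))", {
  x <- c(1, 0, 0)                      # ||x||^2 = 1
  f <- enet_fit(x, matrix(x, ncol = 1), lambda1 = 0.2, lambda2 = 0.5,
                standardize = FALSE)
  expect_equal(unname(f$coefficients), 0.6, tolerance = 1e-9)
})

test_that("unpenalized limit recovers an exact representation", {
  set.seed(3)
  P <- qr.Q(qr(matrix(rnorm(6 * 3), 6, 3)))
  w_true <- c(1.5, -0.7, 0.2)
  x <- as.vector(P %*% w_true)
  f <- enet_fit(x, P, lambda1 = 1e-10, lambda2 = 1e-10, standardize = FALSE)
  expect_lt(sqrt(sum((x - P %*% f$coefficients)^2)), 1e-5)
})

test_that("solver matches an independent convex oracle on random instances", {
  set.seed(4)
  for (rep in 1:20) {
    m <- sample(5:15, 1); p <- sample(2:8, 1)
    P <- matrix(rnorm(m * p), m, p)
    x <- rnorm(m)
    l1 <- runif(1, 0.05, 2); l2 <- runif(1, 0.01, 1)
    f <- enet_fit(x, P, l1, l2, standardize = FALSE)
    orc <- enet_oracle(x, P, l1, l2)
    expect_lte(f$objective, orc$objective + 1e-4)
    expect_lt(abs(f$objective - orc$objective), 1e-4)
  }
})

test_that("feature-sign search and coordinate descent agree to machine precision", {
  set.seed(14)
  for (rep in 1:10) {
    m <- sample(6:14, 1); p <- sample(2:7, 1)
    P <- matrix(rnorm(m * p), m, p); x <- rnorm(m)
    G <- crossprod(P); q <- drop(crossprod(P, x))
    l1 <- runif(1, 0.02, 1.5); l2 <- runif(1, 0.01, 0.8)
    w1 <- idhypergraph:::enet_solve_gram(G, q, l1, l2, 1e5, 1e-11, "fss")[, 1]
    w2 <- idhypergraph:::enet_solve_gram(G, q, l1, l2, 1e5, 1e-11, "cd")[, 1]
    expect_equal(w1, w2, tolerance = 1e-6)
  }
})

test_that("solver agrees with glmnet through the augmented-lasso reduction", {
  skip_if_not_installed("glmnet")
  set.seed(15)
  m <- 30; p <- 10
  P <- matrix(rnorm(m * p), m, p); x <- rnorm(m)
  l1 <- 0.4; l2 <- 0.2
  f <- enet_fit(x, P, l1, l2, standardize = FALSE)
  # ||x - Pw||^2 + l2 ||w||^2 = ||x~ - P~ w||^2 with P~ = [P; sqrt(l2) I]
  Pa <- rbind(P, sqrt(l2) * diag(p)); xa <- c(x, rep(0, p))
  lam <- l1 / (2 * nrow(Pa))
  gfit <- glmnet::glmnet(Pa, xa, alpha = 1, standardize = FALSE,
                         intercept = FALSE, thresh = 1e-14,
                         lambda = c(lam * 4, lam * 2, lam))
  wg <- as.numeric(gfit$beta[, 3])
  expect_equal(unname(f$coefficients), wg, tolerance = 1e-5)
})

test_that("support size is non-increasing in lambda1 at fixed lambda2", {
  set.seed(5)
  P <- matrix(rnorm(20 * 8), 20, 8)
  x <- rnorm(20)
  lmax <- enet_lambda_max(x, P)
  sizes <- vapply(c(0.9, 0.5, 0.25, 0.1, 0.02), function(fr) {
    sum(enet_fit(x, P, fr * lmax, 0.1, standardize = FALSE)$coefficients != 0)
  }, numeric(1))
  expect_true(all(diff(sizes) >= 0))
})

test_that("grouping effect: duplicated predictors get equal coefficients", {
  set.seed(6)
  base <- rnorm(15)
  P <- cbind(base, base, rnorm(15))
  x <- 0.8 * base + rnorm(15, sd = 0.1)
  f <- enet_fit(x, P, lambda1 = 0.3, lambda2 = 0.5, standardize = FALSE)
  expect_equal(f$coefficients[1], f$coefficients[2], tolerance = 1e-6)
})

test_that("non-finite inputs are rejected", {
  expect_error(enet_fit(c(1, NA), matrix(1, 2, 1), 0.1, 0.1), "finite")
  expect_error(enet_fit(c(1, 2), matrix(c(Inf, 1), 2, 1), 0.1, 0.1), "finite")
})

test_that("select_lambdas honours its contracts", {
  set.seed(7)
  m <- 24
  P <- matrix(rnorm(m * 5), m, 5)
  x <- rnorm(m)
  # a one-pair grid is returned as-is with a finite error
  cfg1 <- enet_config(lambda1_grid = 0.3, lambda2_grid = 0.1, n_folds = 4,
                      seed = 3)
  s1 <- select_lambdas(x, P, cfg1)
  expect_equal(s1$lambda1, 0.3)
  expect_equal(s1$lambda2, 0.1)
  expect_true(is.finite(s1$cv_error))
  # target equal to a duplicated predictor: tiny lambda1 wins with ~0 error
  P2 <- cbind(x, x, rnorm(m))
  cfg2 <- enet_config(lambda1_grid = c(5, 1e-4), lambda2_grid = 1e-4,
                      n_folds = 4, seed = 3)
  s2 <- select_lambdas(x, P2, cfg2)
  expect_equal(s2$lambda1, 1e-4)
  expect_lt(s2$cv_error, 1e-4)
  # determinism under a fixed seed
  cfg3 <- enet_config(n_folds = 6, seed = 11)
  expect_identical(select_lambdas(x, P, cfg3), select_lambdas(x, P, cfg3))
  # infeasible folds are a configuration error
  expect_error(select_lambdas(x[1:4], P[1:4, ], enet_config(n_folds = 10)),
               "folds")
})

test_that("build_hyperedge unions the centroid with the support", {
  fit0 <- structure(list(coefficients = rep(0, 4)), class = "enet_fit")
  expect_equal(build_hyperedge(fit0, centroid = 3, predictor_index = c(1, 2, 4, 5)),
               3)
  fit1 <- structure(list(coefficients = c(0, 0.4, 0, -0.2)),
                    class = "enet_fit")
  expect_equal(build_hyperedge(fit1, centroid = 4,
                               predictor_index = c(1, 2, 6, 7)),
               c(2, 4, 7))
})

test_that("build_id_hypergraph yields one hyperedge per case with unit diagonal", {
  set.seed(8)
  X <- matrix(abs(rnorm(5 * 12, 1, 0.3)), 5, 12)
  cfg <- enet_config(lambda1_grid = c(0.5, 0.05), lambda2_grid = 0.1,
                     n_folds = 3, seed = 2)
  g <- build_id_hypergraph(X, cfg)
  expect_length(g$edges, 5L)
  H <- incidence_matrix(g, sparse = FALSE)
  expect_equal(unname(diag(H)), rep(1, 5))
  expect_equal(g$weights, rep(1, 5))
  # two identical deviation rows select each other at small lambda1
  X2 <- X; X2[2, ] <- X2[1, ]
  g2 <- build_id_hypergraph(X2, enet_config(lambda1_grid = 1e-3,
                                            lambda2_grid = 0.1, n_folds = 3,
                                            seed = 2))
  expect_true(2 %in% g2$edges[[1]])
  expect_true(1 %in% g2$edges[[2]])
  # a huge fixed lambda1 gives all-singleton hyperedges
  g3 <- build_id_hypergraph(X, enet_config(lambda_fixed = c(1e6, 0.1)))
  expect_true(all(lengths(g3$edges) == 1L))
  expect_error(build_id_hypergraph(X[1:2, ]), "at least 3")
})

test_that("fixed-sparsity selection modes behave as documented", {
  set.seed(9)
  X <- matrix(abs(rnorm(8 * 20, 1, 0.3)), 8, 20)
  # frac: every centroid gets lambda1 = frac * its own KKT bound
  gf <- build_id_hypergraph(X, enet_config(selection = "frac",
                                           lambda1_frac = 0.5))
  rep <- attr(gf, "fit_report")
  expect_equal(nrow(rep), 8L)
  expect_equal(unique(rep$lambda2), 0.01)
  expect_true(all(lengths(gf$edges) >= 1))
  # target_size: the support reaches the requested size when possible
  sel <- select_lambda_target(X[1, ], t(X[-1, ]), size = 3)
  expect_gte(sel$support_size, 3)
  f <- enet_fit(X[1, ], t(X[-1, ]), sel$lambda1, sel$lambda2)
  expect_gte(length(f$support), 3)
  gt <- build_id_hypergraph(X, enet_config(selection = "target_size",
                                           target_size = 3))
  expect_true(all(lengths(gt$edges) >= 3))
})
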