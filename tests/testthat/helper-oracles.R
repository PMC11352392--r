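# Shared fixtures and independent oracles for the test suite.

# triangle hypergraph: edges {1,2}, {1,3}, {2,3}; degrees (2,2,2)
triangle_hg <- function() hypergraph(list(c(1, 2), c(1, 3), c(2, 3)), 3)

# all set partitions of n items as label vectors (restricted growth strings)
all_partitions <- function(n) {
  out <- list()
  rec <- function(z, mx) {
    i <- length(z) + 1L
    if (i > n) {
      out[[length(out) + 1L]] <<- z
      return(invisible())
    }
    for (lab in seq_len(mx + 1L)) rec(c(z, lab), max(mx, lab))
  }
  rec(integer(0), 0L)
  out
}

# random hypergraph with mixed edge sizes for property tests
random_hg <- function(n, m, sizes = 2:3, seed = 1) {
  with_seed_t(seed, {
    edges <- lapply(seq_len(m), function(j) {
      k <- sample(sizes, 1)
      sort(sample.int(n, min(k, n)))
    })
    mult <- sample(1:3, m, replace = TRUE)
    hypergraph(edges, n, multiplicities = mult)
  })
}

with_seed_t <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  force(code)
}

# independent elastic-net oracle: optim(L-BFGS-B) on the split formulation
# w = u - v with u, v >= 0 (smooth objective, box constraints)
enet_oracle <- function(target, predictors, lambda1, lambda2,
                        reltol = 1e-12) {
  p <- ncol(predictors)
  fn <- function(uv) {
    w <- uv[1:p] - uv[(p + 1):(2 * p)]
    sum((target - predictors %*% w)^2) + lambda1 * sum(uv) +
      lambda2 * sum(w^2)
  }
  gr <- function(uv) {
    w <- uv[1:p] - uv[(p + 1):(2 * p)]
    g <- -2 * as.vector(crossprod(predictors, target - predictors %*% w)) +
      2 * lambda2 * w
    c(g + lambda1, -g + lambda1)
  }
  best <- NULL
  for (st in list(rep(0, 2 * p), rep(0.1, 2 * p))) {
    o <- stats::optim(st, fn, gr, method = "L-BFGS-B", lower = 0,
                      control = list(maxit = 2000, factr = 10))
    if (is.null(best) || o$value < best$value) best <- o
  }
  list(w = best$par[1:p] - best$par[(p + 1):(2 * p)], objective = best$value)
}

# brute-force degree recount straight from the membership lists
brute_degrees <- function(g) {
  d <- numeric(g$n_vertices)
  for (j in seq_along(g$edges)) {
    for (v in g$edges[[j]]) d[v] <- d[v] + g$weights[j] * g$multiplicities[j]
  }
  d
}

# graph cut-plus-volume objective for 2-uniform hypergraphs (independent of
# the package's cut/volume code)
graph_objective <- function(edges_mat, mult, z, beta2, gamma2, degrees) {
  cut <- sum(mult[z[edges_mat[, 1]] != z[edges_mat[, 2]]])
  vols <- tapply(degrees, z, sum)
  -(beta2 * cut + gamma2 * sum(vols^2))
}

# tiny synthetic cohort for fast pipeline tests
small_cohort <- function(seed = 7, n_case = 40L, n_control = 30L,
                         n_subtypes = 2L, effect_size = 3) {
  simulate_cohort(cohort_config(
    n_case = n_case, n_control = n_control, n_features = 40L,
    n_subtypes = n_subtypes, regions_per_subtype = 10L,
    effect_size = effect_size, seed = seed))
}
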