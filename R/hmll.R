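# Internal working representation for the Louvain-style ascent: edges with
# multiplicities and per-edge beta, per-size scaled gamma, and normalized
# vertex volumes rho_v = d(v)/vol(V).
hmll_work <- function(g, include_singletons) {
  keep <- if (include_singletons) seq_along(g$edges) else
    which(edge_sizes(g) >= 2L)
  gw <- hypergraph(g$edges[keep], g$n_vertices,
                   weights = g$weights[keep],
                   multiplicities = g$multiplicities[keep],
                   labels = g$labels)
  d <- degrees(gw)$vertex
  vol_total <- sum(d)
  sz <- edge_sizes(gw)
  ks <- sort(unique(sz))
  v2e <- vector("list", gw$n_vertices)
  for (j in seq_along(gw$edges)) {
    for (v in gw$edges[[j]]) v2e[[v]] <- c(v2e[[v]], j)
  }
  list(g = gw, n = gw$n_vertices, edges = gw$edges, a = gw$multiplicities,
       sz = sz, ks = ks, rho = if (vol_total > 0) d / vol_total else d * 0,
       vol_total = vol_total, v2e = v2e,
       mk = vapply(ks, function(k) sum(gw$multiplicities[sz == k]), numeric(1)))
}

# per-edge beta and per-size scaled gamma from a modularity_params object
hmll_coefs <- function(work, params) {
  miss <- setdiff(work$ks, params$k)
  if (length(miss)) {
    stop("modularity parameters missing for hyperedge size(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  gs_all <- params_gamma_scaled(params, work$vol_total)
  list(beta_e = params$beta[as.character(work$sz)],
       beta_k = params$beta[as.character(work$ks)],
       gs = gs_all[as.character(work$ks)])
}

# full Q on the working structure (normalized volume representation)
hmll_full_q <- function(work, coefs, z) {
  q <- 0
  for (j in seq_along(work$edges)) {
    zi <- z[work$edges[[j]]]
    if (any(zi != zi[1L])) q <- q - coefs$beta_e[j] * work$a[j]
  }
  if (work$vol_total > 0) {
    rhoC <- as.vector(rowsum(work$rho, group = z))
    for (i in seq_along(work$ks)) {
      q <- q - coefs$gs[i] * sum(rhoC^work$ks[i])
    }
  }
  unname(q)
}

hmll_estimate <- function(work, z, eps = 1e-10) {
  if (length(unique(z)) < 2L || work$vol_total <= 0 || !length(work$ks)) {
    return(default_modularity_params(work$g))
  }
  rhoC <- as.vector(rowsum(work$rho, group = z))
  beta <- gs <- stats::setNames(numeric(length(work$ks)), work$ks)
  for (i in seq_along(work$ks)) {
    k <- work$ks[i]
    idx <- which(work$sz == k)
    ck <- 0
    for (j in idx) {
      zi <- z[work$edges[[j]]]
      if (any(zi != zi[1L])) ck <- ck + work$a[j]
    }
    mk <- work$mk[i]
    Pk <- sum(rhoC^k)
    floor_k <- eps * max(mk, 1)
    r_in <- max((mk - ck) / max(Pk, eps), floor_k)
    r_out <- max(ck / max(1 - Pk, eps), floor_k)
    beta[i] <- log(r_in / r_out)
    gs[i] <- r_in - r_out
  }
  modularity_params(beta, gamma_scaled = gs)
}

# One ascent phase (single-vertex sweeps alternating with edge-collapse
# proposals) implemented in C++; see src/hmll.cpp for the move semantics and
# why composite edge-collapse moves are needed. Randomness flows through R's
# RNG, so results are reproducible under the caller's seed.
hmll_moves <- function(work, coefs, z, max_sweeps, tol, audit,
                       merge_pass = TRUE) {
  if (!length(work$edges)) {
    return(list(z = z, q = hmll_full_q(work, coefs, z), moves = 0L,
                audit_dev = 0))
  }
  res <- .hmll_ascent(work$n, work$edges, as.numeric(work$a),
                      as.numeric(coefs$beta_e),
                      match(work$sz, work$ks) - 1L, as.numeric(work$ks),
                      as.numeric(coefs$gs), work$rho, as.integer(z),
                      as.integer(max_sweeps), tol, audit, merge_pass)
  if (!is.finite(res$q)) {
    stop(structure(class = c("hmll_numerical_error", "error", "condition"),
                   list(message = "non-finite modularity during ascent",
                        call = sys.call(-1), state = res)))
  }
  list(z = res$z, q = res$q, moves = res$moves, audit_dev = res$audit_dev)
}

#' Hypergraph maximum-likelihood Louvain clustering
#'
#' Maximizes the symmetric hypergraph modularity by coordinate ascent on
#' single-vertex moves: starting from the all-singleton partition, vertices
#' are visited in a seeded random order and each is moved to the label (among
#' the labels of its co-hyperedge neighbours, plus a fresh label) with the
#' largest modularity gain, until a full sweep makes no move. With
#' `params = "estimate"` the ascent alternates with a maximum-likelihood
#' style update of `(beta_k, gamma_k)` from the current partition until the
#' objective stabilizes. The best partition over `n_restarts` seeded restarts
#' is returned. The number of clusters is not an input; it emerges from the
#' maximization.
#'
#' @param g a [hypergraph()].
#' @param params a [modularity_params()], or `"default"` (fixed
#'   [default_modularity_params()]), or `"estimate"` (alternating estimation).
#' @param n_restarts number of seeded restarts (default 20).
#' @param seed integer master seed; every restart derives its own stream.
#' @param max_sweeps cap on move sweeps per ascent (default 100).
#' @param tol minimum modularity gain for a move, and the stabilization
#'   tolerance of the alternating scheme.
#' @param include_singletons size-1 hyperedges carry no partition information
#'   (`cut_1 = 0`) and only inflate the volume term, so they are excluded
#'   from clustering by default.
#' @param audit if `TRUE`, every accepted move's incremental gain is checked
#'   against a full recomputation of Q; the maximum absolute deviation is
#'   reported in the result.
#' @param max_outer cap on (partition, parameter) alternations.
#' @param restart_select how the winning restart is chosen: by modularity
#'   (`"Q"`, sound when parameters are fixed across restarts) or as the
#'   consensus medoid, i.e. the restart partition with the largest mean
#'   adjusted Rand index to all other restarts (`"consensus"`, the default
#'   for estimated parameters, whose Q values live on restart-specific
#'   scales).
#' @return object of class `"hg_partition"`: `labels` (contiguous cluster
#'   ids, 1-based), `n_clusters`, `Q`, `params` (the final
#'   [modularity_params()]), `seed`, `restart` (index of the winning
#'   restart), `audit_max_dev`.
#' @export
hmll <- function(g, params = "estimate", n_restarts = 20L, seed = 1L,
                 max_sweeps = 100L, tol = 1e-10, include_singletons = FALSE,
                 audit = FALSE, max_outer = 20L,
                 restart_select = c("auto", "consensus", "Q")) {
  restart_select <- match.arg(restart_select)
  stopifnot(inherits(g, "hypergraph"))
  if (g$n_vertices < 1L) stop("empty hypergraph", call. = FALSE)
  work <- hmll_work(g, include_singletons)
  estimate <- identical(params, "estimate")
  if (identical(params, "default")) params <- default_modularity_params(work$g)
  if (!estimate && !inherits(params, "modularity_params")) {
    stop("`params` must be a modularity_params object, \"default\" or \"estimate\"",
         call. = FALSE)
  }
  if (restart_select == "auto") {
    # modularity values are comparable across restarts only when the
    # parameters are fixed; with per-restart estimated parameters the
    # consensus medoid (max mean pairwise ARI) is the sound choice
    restart_select <- if (estimate) "consensus" else "Q"
  }
  all_res <- vector("list", n_restarts)
  for (r in seq_len(n_restarts)) {
    res <- with_seed(derive_seed(seed, paste0("hmll-restart-", r)), {
      z <- seq_len(work$n)
      if (estimate) {
        # coordinate ascent between the partition and (beta_k, gamma_k):
        # each alternation re-solves the partition from the singleton start
        # under the current parameters (an incremental update cannot split a
        # wrongly fused cluster, nor unfreeze the huge volume penalties that
        # a fine partition induces), then re-estimates the parameters from
        # the new partition, until the partition is a fixed point.
        audit_dev <- 0
        mv <- hmll_moves(work, hmll_coefs(work, default_modularity_params(work$g)),
                         seq_len(work$n), max_sweeps, tol, audit)
        z_best <- mv$z
        audit_dev <- max(audit_dev, mv$audit_dev)
        par_cur <- hmll_estimate(work, z_best)
        for (outer in seq_len(max_outer)) {
          coefs <- hmll_coefs(work, par_cur)
          mv <- hmll_moves(work, coefs, seq_len(work$n), max_sweeps, tol,
                           audit)
          audit_dev <- max(audit_dev, mv$audit_dev)
          # keep whichever partition scores better under the current
          # parameters (the re-solve can land in a worse local optimum)
          q_new <- hmll_full_q(work, coefs, mv$z)
          q_old <- hmll_full_q(work, coefs, z_best)
          if (q_new <= q_old + tol) break
          z_best <- mv$z
          par_cur <- hmll_estimate(work, z_best)
        }
        list(z = z_best, q = hmll_full_q(work, hmll_coefs(work, par_cur), z_best),
             params = par_cur, audit_dev = audit_dev)
      } else {
        coefs <- hmll_coefs(work, params)
        mv <- hmll_moves(work, coefs, z, max_sweeps, tol, audit)
        list(z = mv$z, q = mv$q, params = params, audit_dev = mv$audit_dev)
      }
    })
    all_res[[r]] <- res
  }
  if (restart_select == "consensus" && n_restarts > 1L) {
    sim <- vapply(all_res, function(a) {
      vapply(all_res, function(b) adjusted_rand_index(a$z, b$z), numeric(1))
    }, numeric(n_restarts))
    win <- which.max(colMeans(sim))
  } else {
    win <- which.max(vapply(all_res, `[[`, numeric(1), "q"))
  }
  best <- all_res[[win]]
  best$restart <- win
  lab <- match(best$z, unique(best$z))  # compact, first-appearance order
  structure(list(labels = lab, n_clusters = length(unique(lab)),
                 Q = best$q, params = best$params, seed = seed,
                 restart = best$restart, audit_max_dev = best$audit_dev,
                 include_singletons = include_singletons),
            class = "hg_partition")
}

#' @exportS3Method base::print
print.hg_partition <- function(x, ...) {
  cat("hg_partition: ", length(x$labels), " vertices in ", x$n_clusters,
      " clusters, Q = ", format(x$Q, digits = 8), "\n", sep = "")
  cat("cluster sizes: ", paste(as.integer(table(x$labels)), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}
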