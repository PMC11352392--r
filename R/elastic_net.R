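#' Elastic-net configuration for hyperedge learning
#'
#' Controls the per-subject sparse self-representation fits that define the
#' hyperedges. The `lambda1` grid is instance-relative by default: for each
#' regression task the grid is `lambda1_fracs * lambda_max`, where
#' `lambda_max = 2 * max_j |x_j . x_i|` is the smallest `lambda1` at which the
#' solution is exactly zero (KKT bound). `lambda2` values are absolute.
#'
#' @param lambda1_fracs fractions of the per-instance `lambda_max` forming the
#'   sparsity grid (descending; spans empty to dense supports).
#' @param lambda1_grid optional absolute `lambda1` grid overriding
#'   `lambda1_fracs`.
#' @param lambda2_grid ridge ("grouping") penalty grid.
#' @param n_folds cross-validation folds over the deviation features
#'   (default 10).
#' @param seed integer seed controlling the fold shuffle.
#' @param standardize scale each predictor profile to unit Euclidean norm
#'   before fitting (coefficients are reported on the standardized scale).
#' @param tol_zero support threshold; 0 with the coordinate-descent solver
#'   (its zeros are exact).
#' @param maxit,tol coordinate-descent sweep cap and convergence tolerance
#'   (max absolute coefficient change per sweep).
#' @param lambda_fixed optional `c(lambda1, lambda2)`; when set, grid search
#'   and cross-validation are skipped (replication mode).
#' @param selection how the per-subject sparsity is chosen. `"cv"`: grid
#'   search minimizing out-of-fold prediction error (see [select_lambdas()]).
#'   `"target_size"`: fixed-sparsity rule -- the largest `lambda1` whose
#'   support reaches `target_size` is taken (with `lambda2 =
#'   lambda2_grid[1]`); prediction-error CV systematically prefers dense
#'   self-representations whose hyperedges are useless to an all-or-nothing
#'   modularity, so the pipeline sizes hyperedges directly.
#'   `"frac"`: fixed-sparsity rule -- per centroid, `lambda1 = lambda1_frac *
#'   lambda_max` with `lambda2 = lambda2_grid[1]`, letting each subject keep
#'   its natural support size at a common relative penalty.
#'   `"fixed"`: use `lambda_fixed` verbatim.
#' @param lambda1_frac fraction of the per-instance KKT bound for
#'   `selection = "frac"` (default 0.65, which yields median hyperedge sizes
#'   near `1.5 * log(n)` on cohorts of a few hundred subjects).
#' @param target_size desired support size for `selection = "target_size"`;
#'   default `ceiling(1.5 * log(n))`, balancing within-community hyperedge
#'   connectivity (which needs on the order of `log(n)` peers) against
#'   support purity.
#' @return list of class `"enet_config"`.
#' @export
enet_config <- function(lambda1_fracs = c(0.5, 0.2, 0.1, 0.05, 0.01),
                        lambda1_grid = NULL,
                        lambda2_grid = c(0.01, 0.1, 1),
                        n_folds = 10L, seed = 1L, standardize = TRUE,
                        tol_zero = 0, maxit = 5000L, tol = 1e-10,
                        lambda_fixed = NULL,
                        selection = c("cv", "frac", "target_size", "fixed"),
                        target_size = NULL, lambda1_frac = 0.65) {
  selection <- match.arg(selection)
  if (!is.null(lambda_fixed)) selection <- "fixed"
  if (is.null(lambda1_grid) && (!length(lambda1_fracs) || any(lambda1_fracs <= 0))) {
    stop("lambda1 grid must be nonempty and positive", call. = FALSE)
  }
  if (!length(lambda2_grid) || any(lambda2_grid <= 0)) {
    stop("lambda2 grid must be nonempty and positive", call. = FALSE)
  }
  if (n_folds < 2L) stop("n_folds must be at least 2", call. = FALSE)
  structure(list(lambda1_fracs = sort(lambda1_fracs, decreasing = TRUE),
                 lambda1_grid = if (is.null(lambda1_grid)) NULL
                                else sort(lambda1_grid, decreasing = TRUE),
                 lambda2_grid = lambda2_grid, n_folds = as.integer(n_folds),
                 seed = as.integer(seed), standardize = isTRUE(standardize),
                 tol_zero = tol_zero, maxit = as.integer(maxit), tol = tol,
                 lambda_fixed = lambda_fixed, selection = selection,
                 target_size = if (!is.null(target_size)) as.integer(target_size),
                 lambda1_frac = lambda1_frac),
            class = "enet_config")
}

#' Smallest lambda1 with an all-zero elastic-net solution
#'
#' The KKT bound for `min_w ||x - P w||^2 + lambda1 ||w||_1 + lambda2 ||w||_2^2`:
#' `w = 0` is optimal iff `lambda1 >= 2 * max_j |p_j . x|`.
#'
#' @param target response vector `x` (length m).
#' @param predictors `m x p` predictor matrix.
#' @return the bound `2 * max_j |p_j . x|`.
#' @export
enet_lambda_max <- function(target, predictors) {
  2 * max(abs(crossprod(predictors, target)))
}

enet_objective <- function(target, predictors, w, lambda1, lambda2) {
  r <- target - as.vector(predictors %*% w)
  sum(r^2) + lambda1 * sum(abs(w)) + lambda2 * sum(w^2)
}

# Core solver on Gram form along a (warm-started) lambda1 path. The primary
# route is the exact active-set feature-sign search; `method = "cd"` exposes
# the plain coordinate-descent kernel (used as an internal cross-check).
# Returns p x length(lambda1) coefficient matrix with exact off-support zeros.
enet_solve_gram <- function(G, q, lambda1, lambda2, maxit, tol,
                            method = c("fss", "cd")) {
  method <- match.arg(method)
  if (any(!is.finite(G)) || any(!is.finite(q))) {
    stop("non-finite values in elastic-net inputs", call. = FALSE)
  }
  res <- if (method == "fss") {
    .enet_fss_path(G, q, as.numeric(lambda1), lambda2, as.integer(maxit), tol)
  } else {
    .enet_cd_path(G, q, as.numeric(lambda1), lambda2, as.integer(maxit), tol)
  }
  if (!all(res$converged)) {
    bad <- which(!res$converged)
    cond <- structure(
      class = c("enet_convergence_error", "error", "condition"),
      list(message = paste0("elastic net did not converge for lambda1 = ",
                            paste(signif(lambda1[bad], 4), collapse = ", "),
                            " (residual trace attached)"),
           call = sys.call(-1), trace = res))
    stop(cond)
  }
  res$W
}

#' Fit one elastic-net self-representation
#'
#' Solves `min_w ||x - P w||^2 + lambda1 ||w||_1 + lambda2 ||w||_2^2` by
#' cyclic coordinate descent (soft-threshold updates; zeros are exact). No
#' intercept. With `standardize = TRUE` the columns of `P` are scaled to unit
#' norm first and coefficients are returned on that standardized scale.
#'
#' @param target response vector (length `m`), e.g. one case subject's
#'   deviation profile.
#' @param predictors `m x p` matrix whose columns are the other subjects'
#'   deviation profiles (the target's own column must not be present).
#' @param lambda1 lasso penalty (> 0 for a sparse hyperedge).
#' @param lambda2 ridge penalty (> 0 activates the grouping effect).
#' @param standardize,maxit,tol see [enet_config()].
#' @return list of class `"enet_fit"`: `coefficients` (length `p`, exact
#'   zeros off-support), `support` (column indices with
#'   `|w| > 0`), `lambda1`, `lambda2`, `objective`.
#' @export
enet_fit <- function(target, predictors, lambda1, lambda2,
                     standardize = TRUE, maxit = 5000L, tol = 1e-10) {
  predictors <- as.matrix(predictors)
  if (length(target) != nrow(predictors)) {
    stop("target length must equal nrow(predictors)", call. = FALSE)
  }
  if (any(!is.finite(target)) || any(!is.finite(predictors))) {
    stop("non-finite values in elastic-net inputs", call. = FALSE)
  }
  if (lambda1 < 0 || lambda2 < 0) stop("penalties must be nonnegative", call. = FALSE)
  scales <- rep(1, ncol(predictors))
  if (standardize) {
    nrm <- sqrt(colSums(predictors^2))
    scales <- ifelse(nrm > 0, 1 / nrm, 1)
    predictors <- sweep(predictors, 2, scales, "*")
  }
  G <- crossprod(predictors)
  q <- as.vector(crossprod(predictors, target))
  # warm-start path from just below lambda_max down to the requested lambda1
  lmax <- 2 * max(abs(q))
  path <- if (lambda1 >= lmax) lambda1 else {
    unique(c(exp(seq(log(lmax), log(max(lambda1, 1e-12)), length.out = 5L)),
             lambda1))
  }
  W <- enet_solve_gram(G, q, path, lambda2, maxit, tol)
  w <- W[, ncol(W)]
  structure(list(coefficients = w, support = which(w != 0),
                 lambda1 = lambda1, lambda2 = lambda2,
                 objective = enet_objective(target, predictors, w,
                                            lambda1, lambda2),
                 scales = scales),
            class = "enet_fit")
}

#' Select elastic-net penalties by cross-validation over features
#'
#' Grid search over `(lambda1, lambda2)` by `n_folds`-fold cross-validation:
#' the folds partition the `m` deviation features (the regression's samples)
#' contiguously after a seeded shuffle; for every grid pair the mean
#' out-of-fold squared prediction error is computed, and the minimizing pair
#' is returned (ties: sparser, i.e. larger `lambda1`, then earlier `lambda2`
#' in the grid). Deterministic given `cfg$seed`.
#'
#' @param target,predictors as in [enet_fit()].
#' @param cfg an [enet_config()].
#' @return list: `lambda1`, `lambda2`, `cv_error` (the winning mean error),
#'   `cv_table` (full grid of mean errors, lambda1 x lambda2),
#'   `lambda1_grid`.
#' @export
select_lambdas <- function(target, predictors, cfg = enet_config()) {
  stopifnot(inherits(cfg, "enet_config"))
  predictors <- as.matrix(predictors)
  m <- length(target)
  if (cfg$n_folds > m) {
    stop("n_folds exceeds the number of deviation features (", m, ")",
         call. = FALSE)
  }
  if (cfg$standardize) {
    nrm <- sqrt(colSums(predictors^2))
    predictors <- sweep(predictors, 2, ifelse(nrm > 0, 1 / nrm, 1), "*")
  }
  l1 <- cfg$lambda1_grid
  if (is.null(l1)) {
    l1 <- cfg$lambda1_fracs * enet_lambda_max(target, predictors)
  }
  l2 <- cfg$lambda2_grid
  # seeded contiguous folds of a shuffled feature order
  perm <- local({
    rng <- local_rng(cfg$seed)
    on.exit(rng(), add = TRUE)
    sample.int(m)
  })
  fold_id <- rep(seq_len(cfg$n_folds), length.out = m)[order(perm)]
  if (min(tabulate(fold_id, cfg$n_folds)) < 1L) {
    stop("cross-validation fold with no samples", call. = FALSE)
  }
  G_full <- crossprod(predictors)
  q_full <- as.vector(crossprod(predictors, target))
  err <- array(0, dim = c(length(l1), length(l2)))
  for (f in seq_len(cfg$n_folds)) {
    test <- which(fold_id == f)
    Pt <- predictors[test, , drop = FALSE]
    G_tr <- G_full - crossprod(Pt)
    q_tr <- q_full - as.vector(crossprod(Pt, target[test]))
    for (b in seq_along(l2)) {
      W <- enet_solve_gram(G_tr, q_tr, l1, l2[b], cfg$maxit, cfg$tol)
      pred <- Pt %*% W
      err[, b] <- err[, b] + colMeans((target[test] - pred)^2) *
        (length(test) / m)
    }
  }
  dimnames(err) <- list(signif(l1, 6), signif(l2, 6))
  # ties resolved toward sparser models: l1 is stored descending
  best <- which(err == min(err), arr.ind = TRUE)[1L, ]
  list(lambda1 = l1[best[1L]], lambda2 = l2[best[2L]],
       cv_error = err[best[1L], best[2L]], cv_table = err, lambda1_grid = l1)
}

#' Select lambda1 by a fixed support-size rule
#'
#' Follows a dense descending `lambda1` path (fractions of the per-instance
#' KKT bound) with warm starts and returns the largest `lambda1` whose
#' support size reaches `size`; if none does, the densest path point is
#' returned. `lambda2` is taken from the first element of the config grid.
#'
#' @param target,predictors as in [enet_fit()] (predictors standardized
#'   according to `cfg$standardize`).
#' @param size desired support size.
#' @param cfg an [enet_config()].
#' @return list: `lambda1`, `lambda2`, `cv_error` (`NA`), `support_size`.
#' @export
select_lambda_target <- function(target, predictors, size,
                                 cfg = enet_config()) {
  predictors <- as.matrix(predictors)
  if (cfg$standardize) {
    nrm <- sqrt(colSums(predictors^2))
    predictors <- sweep(predictors, 2, ifelse(nrm > 0, 1 / nrm, 1), "*")
  }
  size <- min(size, ncol(predictors))
  l2 <- cfg$lambda2_grid[1L]
  lmax <- enet_lambda_max(target, predictors)
  fracs <- exp(seq(log(0.98), log(0.02), length.out = 40L))
  G <- crossprod(predictors)
  q <- as.vector(crossprod(predictors, target))
  W <- enet_solve_gram(G, q, fracs * lmax, l2, cfg$maxit, cfg$tol)
  nnz <- colSums(W != 0)
  hit <- which(nnz >= size)
  pick <- if (length(hit)) hit[1L] else length(fracs)
  list(lambda1 = fracs[pick] * lmax, lambda2 = l2, cv_error = NA_real_,
       support_size = nnz[pick])
}

#' Hyperedge from a fitted self-representation
#'
#' The hyperedge is the centroid subject together with every subject whose
#' fitted coefficient magnitude exceeds `tol_zero` (0 by default: the
#' coordinate-descent zeros are exact).
#'
#' @param fit an [enet_fit()].
#' @param centroid index of the centroid subject (in case indexing).
#' @param predictor_index mapping from predictor columns to case indices.
#' @param tol_zero support threshold.
#' @return sorted integer vertex set containing at least the centroid.
#' @export
build_hyperedge <- function(fit, centroid, predictor_index, tol_zero = 0) {
  stopifnot(inherits(fit, "enet_fit"))
  sup <- which(abs(fit$coefficients) > tol_zero)
  sort(unique(c(centroid, predictor_index[sup])))
}

#' Build the ID-Hypergraph from a deviation matrix
#'
#' One hyperedge per case subject: the subject's deviation profile is
#' regressed on all other case subjects' profiles with the elastic net
#' (penalties chosen per subject by cross-validated grid search, unless
#' `cfg$lambda_fixed` is set), and the hyperedge is the centroid plus the
#' support of the fitted coefficient vector. The resulting hypergraph has
#' exactly `n` hyperedges (before duplicate merging), all with weight 1, and
#' its incidence matrix has a unit diagonal.
#'
#' @param X a [deviation_matrix()] (or any numeric `n x m` matrix with case
#'   row names), `n >= 3`.
#' @param cfg an [enet_config()].
#' @return a [hypergraph()] over the `n` case subjects, with attribute
#'   `"fit_report"`: a data.frame (centroid, lambda1, lambda2, cv_error,
#'   support_size).
#' @export
build_id_hypergraph <- function(X, cfg = enet_config()) {
  X <- unclass(as.matrix(X))
  n <- nrow(X)
  if (n < 3L) stop("need at least 3 case subjects", call. = FALSE)
  edges <- vector("list", n)
  rep_rows <- vector("list", n)
  for (i in seq_len(n)) {
    idx <- setdiff(seq_len(n), i)
    target <- X[i, ]
    predictors <- t(X[idx, , drop = FALSE])
    sel <- tryCatch({
      if (cfg$selection == "fixed") {
        list(lambda1 = cfg$lambda_fixed[1L], lambda2 = cfg$lambda_fixed[2L],
             cv_error = NA_real_)
      } else if (cfg$selection == "frac") {
        lmax <- enet_lambda_max(target, if (cfg$standardize) {
          nrm <- sqrt(colSums(predictors^2))
          sweep(predictors, 2, ifelse(nrm > 0, 1 / nrm, 1), "*")
        } else predictors)
        list(lambda1 = cfg$lambda1_frac * lmax,
             lambda2 = cfg$lambda2_grid[1L], cv_error = NA_real_)
      } else if (cfg$selection == "target_size") {
        size <- cfg$target_size %||% ceiling(1.5 * log(n))
        select_lambda_target(target, predictors, size, cfg)
      } else {
        select_lambdas(target, predictors, cfg)
      }
    }, error = function(e) {
      stop("hyperedge fit failed for centroid ", rownames(X)[i] %||% i,
           ": ", conditionMessage(e), call. = FALSE)
    })
    fit <- enet_fit(target, predictors, sel$lambda1, sel$lambda2,
                    standardize = cfg$standardize, maxit = cfg$maxit,
                    tol = cfg$tol)
    edges[[i]] <- build_hyperedge(fit, i, idx, cfg$tol_zero)
    rep_rows[[i]] <- data.frame(
      centroid = rownames(X)[i] %||% as.character(i),
      lambda1 = sel$lambda1, lambda2 = sel$lambda2, cv_error = sel$cv_error,
      support_size = length(fit$support))
  }
  g <- hypergraph(edges, n_vertices = n, labels = rownames(X))
  attr(g, "fit_report") <- do.call(rbind, rep_rows)
  g
}

`%||%` <- function(a, b) if (is.null(a)) b else a
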