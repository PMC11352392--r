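#' Number of size-k hyperedges cut by a partition
#'
#' `cut_k(Z) = m_k - sum_{R in R_k} a_R [all vertices of R share one label]`,
#' i.e. the multiplicity mass of size-`k` hyperedges whose vertices span two
#' or more clusters. Satisfies `0 <= cut_k <= m_k` and
#' `cut_k + interior_k = m_k` for every partition.
#'
#' @param g a [hypergraph()].
#' @param z integer vector of cluster labels, one per vertex.
#' @param k hyperedge size.
#' @return the cut mass (a real; integral when multiplicities are).
#' @export
cut_k <- function(g, z, k) {
  stopifnot(inherits(g, "hypergraph"), length(z) == g$n_vertices, k >= 1)
  sz <- edge_sizes(g)
  idx <- which(sz == k)
  if (!length(idx)) return(0)
  straddles <- vapply(g$edges[idx], function(e) {
    zi <- z[e]
    any(zi != zi[1L])
  }, logical(1))
  sum(g$multiplicities[idx][straddles])
}

#' Sum of k-th powers of cluster volumes
#'
#' `sum_C vol(C)^k` with `vol(C) = sum_{i in C} d(v_i)`. When vertex degrees
#' are integral (the default identity-weight case) the sum is computed with
#' exact integer arithmetic, escalating to an internal arbitrary-precision
#' representation beyond 2^53 and rounding once on return; it never wraps.
#'
#' @inheritParams cut_k
#' @param k power (a positive integer).
#' @return the volume power sum as a double.
#' @export
volume_term <- function(g, z, k) {
  stopifnot(inherits(g, "hypergraph"), length(z) == g$n_vertices, k >= 1)
  d <- degrees(g)$vertex
  vols <- as.vector(rowsum(d, group = z))
  integral <- all(d == round(d))
  if (!integral) {
    out <- sum(vols^k)
    if (!is.finite(out)) warning("volume_term overflowed double range")
    return(out)
  }
  if (length(vols) == 0L) return(0)
  if (max(vols)^k < 2^53 && sum(vols^k) < 2^53) return(sum(vols^k))
  acc <- 0
  for (v in vols) acc <- big_add(acc, big_pow(big_from_num(v), k))
  big_to_double(acc)
}

#' Modularity parameters
#'
#' The per-size coefficients of the symmetric hypergraph modularity: `beta_k`
#' weights the cut term (controls the hyperedge sizes that drive clustering)
#' and `gamma_k` weights the volume term (controls cluster sizes). For
#' numerical stability at large `k` a parameter set may instead carry
#' `gamma_scaled_k = gamma_k * vol(V)^k`, which is how the internal
#' estimation represents it.
#'
#' @param beta named numeric vector, names = hyperedge sizes `k`.
#' @param gamma named numeric vector of raw `gamma_k` (same names), or `NULL`
#'   if `gamma_scaled` is given.
#' @param gamma_scaled named numeric vector of `gamma_k * vol(V)^k`, or
#'   `NULL`.
#' @return object of class `"modularity_params"`.
#' @export
modularity_params <- function(beta, gamma = NULL, gamma_scaled = NULL) {
  if (is.null(gamma) == is.null(gamma_scaled)) {
    stop("give exactly one of `gamma` or `gamma_scaled`", call. = FALSE)
  }
  ks <- as.integer(names(beta))
  if (anyNA(ks)) stop("`beta` must be named by hyperedge size", call. = FALSE)
  g_ref <- if (is.null(gamma)) gamma_scaled else gamma
  if (!identical(sort(as.integer(names(g_ref))), sort(ks))) {
    stop("beta and gamma must cover the same sizes", call. = FALSE)
  }
  structure(list(k = sort(ks), beta = beta, gamma = gamma,
                 gamma_scaled = gamma_scaled),
            class = "modularity_params")
}

#' Default modularity parameters for a hypergraph
#'
#' `beta_k = 1` for every occurring size and a planted-partition-style
#' resolution `gamma_k = m_k * k / vol(V)^k` (i.e. `gamma_scaled_k = m_k *
#' k`), which puts the volume penalty on the same scale as the cut term.
#'
#' @param g a [hypergraph()].
#' @return a [modularity_params()] covering every size occurring in `g`.
#' @export
default_modularity_params <- function(g) {
  sz <- edge_sizes(g)
  ks <- sort(unique(sz))
  if (!length(ks)) ks <- 1L
  mk <- vapply(ks, function(k) sum(g$multiplicities[sz == k]), numeric(1))
  beta <- stats::setNames(rep(1, length(ks)), ks)
  gs <- stats::setNames(mk * ks, ks)
  modularity_params(beta, gamma_scaled = gs)
}

# gamma_scaled for arbitrary params given total volume (stable in log space)
params_gamma_scaled <- function(params, vol_total) {
  if (!is.null(params$gamma_scaled)) return(params$gamma_scaled)
  ks <- as.integer(names(params$gamma))
  g <- params$gamma
  out <- sign(g) * exp(log(abs(g)) + ks * log(vol_total))
  out[g == 0] <- 0
  stats::setNames(out, names(g))
}

#' Symmetric hypergraph modularity
#'
#' `Q(Z) = - sum_k [ beta_k * cut_k(Z) + gamma_k * sum_C vol(C)^k ]`, summed
#' over the hyperedge sizes occurring in `g`; larger is better (the sign
#' convention follows the printed objective, so `Q` is typically negative and
#' is maximized).
#'
#' @inheritParams cut_k
#' @param params a [modularity_params()] covering every size occurring in
#'   `g` (missing sizes are a configuration error).
#' @return the modularity value `Q(Z)`.
#' @export
hypergraph_modularity <- function(g, z, params) {
  stopifnot(inherits(g, "hypergraph"), inherits(params, "modularity_params"))
  sz <- edge_sizes(g)
  ks <- sort(unique(sz))
  miss <- setdiff(ks, params$k)
  if (length(miss)) {
    stop("modularity parameters missing for hyperedge size(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  if (!length(ks)) return(0)
  d <- degrees(g)$vertex
  vol_total <- sum(d)
  gs <- params_gamma_scaled(params, vol_total)
  rho <- if (vol_total > 0) as.vector(rowsum(d, group = z)) / vol_total else
    numeric(0)
  q <- 0
  for (k in ks) {
    kk <- as.character(k)
    q <- q - params$beta[[kk]] * cut_k(g, z, k)
    if (length(rho)) q <- q - gs[[kk]] * sum(rho^k)
  }
  unname(q)
}

#' Estimate modularity parameters from a partition
#'
#' Method-of-moments maximum-likelihood-style update: per occurring size `k`,
#' the interior rate `omega_in = interior_k / sum_C vol(C)^k` and exterior
#' rate `omega_out = cut_k / (vol(V)^k - sum_C vol(C)^k)` give `beta_k =
#' log(omega_in / omega_out)` and `gamma_k = omega_in - omega_out`. Rates are
#' floored at `eps` (relative to the size-k edge mass) so the estimates are
#' never infinite; whenever the within-cluster edge rate exceeds the
#' between-cluster rate, `beta_k > 0`. With fewer than 2 clusters the
#' defaults of [default_modularity_params()] are returned.
#'
#' @inheritParams cut_k
#' @param eps relative rate floor.
#' @return a [modularity_params()] (carrying `gamma_scaled`).
#' @export
estimate_params <- function(g, z, eps = 1e-10) {
  stopifnot(inherits(g, "hypergraph"))
  if (length(unique(z)) < 2L) return(default_modularity_params(g))
  sz <- edge_sizes(g)
  ks <- sort(unique(sz))
  if (!length(ks)) return(default_modularity_params(g))
  d <- degrees(g)$vertex
  vol_total <- sum(d)
  if (vol_total <= 0) return(default_modularity_params(g))
  rho <- as.vector(rowsum(d, group = z)) / vol_total
  beta <- gs <- stats::setNames(numeric(length(ks)), ks)
  for (idx in seq_along(ks)) {
    k <- ks[idx]
    mk <- sum(g$multiplicities[sz == k])
    ck <- cut_k(g, z, k)
    interior <- mk - ck
    Pk <- sum(rho^k)               # = sum_C vol(C)^k / vol(V)^k, in (0, 1]
    floor_k <- eps * max(mk, 1)
    r_in <- max(interior / max(Pk, eps), floor_k)
    r_out <- max(ck / max(1 - Pk, eps), floor_k)
    beta[idx] <- log(r_in / r_out)
    gs[idx] <- r_in - r_out        # = gamma_k * vol(V)^k
  }
  modularity_params(beta, gamma_scaled = gs)
}
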