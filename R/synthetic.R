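#' Synthetic cohort configuration
#'
#' Describes a two-group regional-activity cohort with planted case
#' subtypes. Defaults emulate the discovery cohort scale of the motivating
#' application: 147 cases / 125 controls, 116 atlas regions, 4 subtypes.
#' Each subtype shifts its own disjoint block of regions by
#' `effect_size * noise_sd`; site offsets are additive and shared across
#' groups so covariate-adjusted tests have something real to adjust for.
#'
#' @param n_case,n_control group sizes.
#' @param n_features number of regional features (default 116).
#' @param n_subtypes number of planted case subtypes `K`.
#' @param effect_size subtype shift in units of the subject-level noise SD.
#' @param regions_per_subtype size of each subtype's region block (blocks are
#'   disjoint and must fit in `n_features`).
#' @param noise_sd subject-level Gaussian noise SD around the regional
#'   baseline (baseline means are drawn once in `[0.8, 1.2]`, the scale of
#'   normalized regional ALFF).
#' @param site_count number of acquisition sites; per-site regional offsets
#'   are `N(0, (site_sd)^2)`.
#' @param site_sd SD of the additive site offsets (default half the noise SD).
#' @param age_range range of uniformly drawn ages in years.
#' @param seed master seed; every sub-stream (baseline, noise, ages, sites,
#'   subtype assignment, clinical scores) derives its own stream from it.
#' @return list of class `"cohort_config"`.
#' @export
cohort_config <- function(n_case = 147L, n_control = 125L, n_features = 116L,
                          n_subtypes = 4L, effect_size = 3,
                          regions_per_subtype = 20L, noise_sd = 0.1,
                          site_count = 4L, site_sd = noise_sd / 2,
                          age_range = c(8, 30), seed = 1L) {
  cfg <- list(n_case = as.integer(n_case), n_control = as.integer(n_control),
              n_features = as.integer(n_features),
              n_subtypes = as.integer(n_subtypes), effect_size = effect_size,
              regions_per_subtype = as.integer(regions_per_subtype),
              noise_sd = noise_sd, site_count = as.integer(site_count),
              site_sd = site_sd, age_range = age_range, seed = as.integer(seed))
  if (cfg$n_subtypes > cfg$n_case) {
    stop("more subtypes than case subjects", call. = FALSE)
  }
  if (cfg$n_subtypes * cfg$regions_per_subtype > cfg$n_features) {
    stop("disjoint subtype region blocks do not fit in n_features",
         call. = FALSE)
  }
  structure(cfg, class = "cohort_config")
}

#' Simulate a two-group cohort with planted case subtypes
#'
#' Controls draw every region from a per-region Gaussian baseline plus an
#' additive site offset; each case additionally shifts its subtype's region
#' block by `effect_size * noise_sd`. Ages are uniform in `age_range`;
#' ADOS-like clinical scores (communication, social, behavior) are generated
#' with a mild subtype dependence in the communication domain. Cases come
#' first in the returned table. Byte-identical given the same seed; the true
#' subtype labels are returned separately from the table.
#'
#' @param cfg a [cohort_config()].
#' @return list: `features` (a [feature_table()] with covariates `age`,
#'   `site`, `ados_communication`, `ados_social`, `ados_behavior`), `truth`
#'   (integer subtype per case, in table order), `config`.
#' @export
simulate_cohort <- function(cfg = cohort_config()) {
  stopifnot(inherits(cfg, "cohort_config"))
  n <- cfg$n_case + cfg$n_control
  baseline <- with_seed(derive_seed(cfg$seed, "baseline"),
                        stats::runif(cfg$n_features, 0.8, 1.2))
  site_of <- with_seed(derive_seed(cfg$seed, "sites"),
                       sample.int(cfg$site_count, n, replace = TRUE))
  site_eff <- with_seed(
    derive_seed(cfg$seed, "site-effects"),
    matrix(stats::rnorm(cfg$site_count * cfg$n_features, 0, cfg$site_sd),
           nrow = cfg$site_count))
  truth <- with_seed(derive_seed(cfg$seed, "subtypes"),
                     sample(rep_len(seq_len(cfg$n_subtypes), cfg$n_case)))
  noise <- with_seed(derive_seed(cfg$seed, "noise"),
                     matrix(stats::rnorm(n * cfg$n_features, 0, cfg$noise_sd),
                            nrow = n))
  values <- matrix(baseline, nrow = n, ncol = cfg$n_features, byrow = TRUE) +
    site_eff[site_of, , drop = FALSE] + noise
  shift <- cfg$effect_size * cfg$noise_sd
  for (i in seq_len(cfg$n_case)) {
    k <- truth[i]
    block <- ((k - 1L) * cfg$regions_per_subtype + 1L):
      (k * cfg$regions_per_subtype)
    values[i, block] <- values[i, block] + shift
  }
  ages <- with_seed(derive_seed(cfg$seed, "ages"),
                    round(stats::runif(n, cfg$age_range[1L], cfg$age_range[2L]), 1))
  ados <- with_seed(derive_seed(cfg$seed, "ados"), {
    comm <- pmax(0, round(stats::rnorm(n, 3.5, 1.5) +
                            c(0.25 * (truth - mean(seq_len(cfg$n_subtypes))),
                              rep(0, cfg$n_control))))
    soc <- pmax(0, round(stats::rnorm(n, 7.5, 2.8)))
    beh <- pmax(0, round(stats::rnorm(n, 2.2, 1.3)))
    data.frame(ados_communication = comm, ados_social = soc,
               ados_behavior = beh)
  })
  ids <- c(sprintf("CASE%03d", seq_len(cfg$n_case)),
           sprintf("CTRL%03d", seq_len(cfg$n_control)))
  rownames(values) <- ids
  colnames(values) <- sprintf("R%03d", seq_len(cfg$n_features))
  covs <- cbind(data.frame(age = ages, site = paste0("site", site_of)), ados)
  ft <- feature_table(values,
                      c(rep("case", cfg$n_case), rep("control", cfg$n_control)),
                      covariates = covs)
  list(features = ft, truth = truth, config = cfg)
}

#' Planted-partition hypergraph configuration
#'
#' @param n_vertices number of vertices.
#' @param n_blocks number of planted blocks (near-equal sizes).
#' @param edge_sizes hyperedge sizes `k` to generate.
#' @param p_within,p_between inclusion probability for candidate hyperedges
#'   lying fully inside one block / straddling blocks (scalar or one value
#'   per element of `edge_sizes`).
#' @param seed integer seed.
#' @param max_enum candidate subsets are enumerated exactly up to this count
#'   per class, and sampled (binomially thinned without replacement) beyond
#'   it.
#' @return list of class `"planted_config"`.
#' @export
planted_config <- function(n_vertices, n_blocks = 2L, edge_sizes = 3L,
                           p_within = 0.8, p_between = 0.05, seed = 1L,
                           max_enum = 5000L) {
  p_within <- rep_len(p_within, length(edge_sizes))
  p_between <- rep_len(p_between, length(edge_sizes))
  if (any(c(p_within, p_between) < 0) || any(c(p_within, p_between) > 1)) {
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  }
  structure(list(n_vertices = as.integer(n_vertices),
                 n_blocks = as.integer(n_blocks),
                 edge_sizes = as.integer(edge_sizes),
                 p_within = p_within, p_between = p_between,
                 seed = as.integer(seed), max_enum = as.integer(max_enum)),
            class = "planted_config")
}

#' Simulate a planted-partition hypergraph
#'
#' For each requested hyperedge size `k`, candidate vertex subsets fully
#' inside one block are kept with probability `p_within`, and straddling
#' subsets with `p_between`. When the candidate space is too large to
#' enumerate, the number of retained edges is drawn binomially and that many
#' distinct subsets are sampled. Deterministic per seed.
#'
#' @param cfg a [planted_config()].
#' @return list: `hypergraph` (a [hypergraph()]), `truth` (block label per
#'   vertex).
#' @export
simulate_planted_hypergraph <- function(cfg) {
  stopifnot(inherits(cfg, "planted_config"))
  n <- cfg$n_vertices
  truth <- rep_len(seq_len(cfg$n_blocks), n)  # contiguous near-equal blocks
  edges <- list()
  with_seed(derive_seed(cfg$seed, "planted-hg"), {
    for (si in seq_along(cfg$edge_sizes)) {
      k <- cfg$edge_sizes[si]
      if (k > n) next
      # within-block candidates
      for (b in seq_len(cfg$n_blocks)) {
        vb <- which(truth == b)
        if (length(vb) < k) next
        if (choose(length(vb), k) <= cfg$max_enum) {
          cand <- utils::combn(vb, k, simplify = FALSE)
          keep <- stats::runif(length(cand)) < cfg$p_within[si]
          edges <- c(edges, cand[keep])
        } else {
          n_keep <- stats::rbinom(1L, cfg$max_enum, cfg$p_within[si])
          got <- unique(replicate(n_keep, sort(sample(vb, k)),
                                  simplify = FALSE))
          edges <- c(edges, got)
        }
      }
      # cross-block candidates
      if (choose(n, k) <= cfg$max_enum) {
        cand <- utils::combn(seq_len(n), k, simplify = FALSE)
        cross <- cand[vapply(cand, function(e) length(unique(truth[e])) > 1L,
                             logical(1))]
        keep <- stats::runif(length(cross)) < cfg$p_between[si]
        edges <- c(edges, cross[keep])
      } else {
        n_keep <- stats::rbinom(1L, cfg$max_enum, cfg$p_between[si])
        got <- list()
        while (length(got) < n_keep) {
          e <- sort(sample.int(n, k))
          if (length(unique(truth[e])) > 1L) got <- c(got, list(e))
        }
        edges <- c(edges, unique(got))
      }
    }
  })
  g <- hypergraph(edges, n)
  list(hypergraph = g, truth = truth)
}

#' Adjusted Rand index
#'
#' Chance-corrected agreement between two partitions of the same items: 1
#' for identical partitions up to relabeling, expectation approximately 0
#' for independent random labelings.
#'
#' @param z_true,z_hat label vectors of equal length.
#' @return the ARI (a real `<= 1`).
#' @export
adjusted_rand_index <- function(z_true, z_hat) {
  if (length(z_true) != length(z_hat)) {
    stop("partitions must have equal length", call. = FALSE)
  }
  tab <- table(z_true, z_hat)
  nij <- sum(choose(tab, 2))
  ai <- sum(choose(rowSums(tab), 2))
  bj <- sum(choose(colSums(tab), 2))
  nn <- choose(sum(tab), 2)
  expected <- ai * bj / nn
  maxi <- (ai + bj) / 2
  if (maxi == expected) return(1)     # both partitions trivial
  (nij - expected) / (maxi - expected)
}
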