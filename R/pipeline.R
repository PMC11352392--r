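pipeline_log <- function(cfg, ...) {
  if (!identical(cfg$log_level, "quiet")) {
    message(format(Sys.time(), "%H:%M:%S"), " ", sprintf(...))
  }
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage `", name, "` failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full subtyping pipeline
#'
#' Deviation matrix, elastic-net hypergraph, modularity clustering, pairwise
#' SVM separability and per-subtype difference maps, in that order. All
#' artifacts (and a frozen copy of the effective configuration, with
#' resolved seeds, selected penalties and final modularity parameters, which
#' makes a bit-identical re-run or a replication-style run on new data
#' possible) are written to the output directory when one is configured.
#'
#' @param config a `"run_config"` (see [read_run_config()] /
#'   [as_run_config()]), or a path to a YAML config.
#' @param features optionally a [feature_table()], overriding
#'   `config$paths$features` / `$phenotype`.
#' @return (invisibly) list of class `"idhg_run"`: `deviation`, `hypergraph`,
#'   `fit_report`, `partition`, `svm`, `profiles`, `config_frozen`,
#'   `output_dir`.
#' @export
run_pipeline <- function(config, features = NULL) {
  if (is.character(config)) config <- read_run_config(config)
  config <- as_run_config(unclass(config))
  seed <- config$seed
  hash <- config_hash(unclass(config))
  ft <- stage("read-inputs", {
    if (is.null(features)) {
      p <- config$paths
      if (is.null(p$features) || is.null(p$phenotype)) {
        stop("config$paths must name `features` and `phenotype` files")
      }
      read_feature_table(p$features, p$phenotype)
    } else features
  })
  out_dir <- config$paths$output
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  pipeline_log(config, "pipeline start: %d cases, %d controls, %d features",
               sum(ft$group == "case"), sum(ft$group == "control"),
               ncol(ft$values))

  dv <- config$deviation
  X <- stage("deviation", deviation_matrix(
    ft, zscore_controls = isTRUE(dv$zscore_controls),
    distance = dv$distance %||% "cosine"))

  en <- config$elastic_net %||% list()
  ecfg <- enet_config(
    lambda1_fracs = en$lambda1_fracs %||% c(0.5, 0.2, 0.1, 0.05, 0.01),
    lambda1_grid = en$lambda1_grid,
    lambda2_grid = en$lambda2_grid %||% c(0.01, 0.1, 1),
    n_folds = en$n_folds %||% 10L,
    seed = en$seed %||% derive_seed(seed, "elastic-net"),
    standardize = en$standardize %||% TRUE,
    tol_zero = en$tol_zero %||% 0,
    lambda_fixed = if (!is.null(en$lambda_fixed)) as.numeric(en$lambda_fixed),
    selection = en$selection %||% "frac",
    lambda1_frac = en$lambda1_frac %||% 0.65)
  g <- stage("hyperedge-builder", build_id_hypergraph(X, ecfg))
  fit_report <- attr(g, "fit_report")
  gm <- merge_duplicates(g)
  pipeline_log(config, "hypergraph: %d hyperedges, sizes %s",
               length(gm$edges),
               paste(range(edge_sizes(gm)), collapse = "-"))

  hm <- config$hmll %||% list()
  params <- hm$params %||% "estimate"
  if (is.list(params)) {               # frozen parameters from a prior run
    params <- thaw_params(params, gm)
  }
  part <- stage("community", hmll(
    gm, params = params,
    n_restarts = hm$n_restarts %||% 20L,
    seed = hm$seed %||% derive_seed(seed, "hmll"),
    max_sweeps = hm$max_sweeps %||% 100L,
    tol = hm$tol %||% 1e-10,
    include_singletons = isTRUE(hm$include_singletons)))
  pipeline_log(config, "clustering: %d subtypes, Q = %.6g",
               part$n_clusters, part$Q)

  sv <- config$svm %||% list()
  case_values <- group_values(ft, "case")
  svm_res <- stage("evaluation-svm", pairwise_svm_cv(
    case_values, part$labels,
    C_grid = sv$C_grid %||% 2^(-5:2),
    n_folds = sv$n_folds %||% 10L,
    seed = sv$seed %||% derive_seed(seed, "svm"),
    gamma = sv$gamma))

  st <- config$stats %||% list()
  profiles <- stage("evaluation-stats", subtype_profile(
    ft, part$labels,
    covariates = st$covariates,
    q_threshold = st$q_threshold %||% 0.05))

  frozen <- unclass(config)
  frozen$seed <- seed
  frozen$elastic_net <- en
  frozen$elastic_net$seed <- ecfg$seed
  if (is.null(frozen$elastic_net$lambda_fixed)) {
    # modal selected pair, reusable verbatim on a replication cohort
    frozen$elastic_net$lambda_fixed <-
      c(stats::median(fit_report$lambda1),
        as.numeric(names(sort(-table(fit_report$lambda2)))[1L]))
  }
  frozen$hmll <- hm
  frozen$hmll$seed <- hm$seed %||% derive_seed(seed, "hmll")
  frozen$hmll$params <- list(
    k = part$params$k, beta = as.list(part$params$beta),
    gamma_scaled = as.list(params_gamma_scaled(
      part$params, sum(degrees(gm)$vertex))),
    vol_total = sum(degrees(gm)$vertex))
  frozen$svm <- sv
  frozen$svm$seed <- sv$seed %||% derive_seed(seed, "svm")

  if (!is.null(out_dir)) {
    ids <- rownames(case_values)
    write_deviation_matrix(X, file.path(out_dir, "deviation.csv"), seed, hash)
    write_hypergraph(gm, file.path(out_dir, "hypergraph.txt"))
    write_table_commented(fit_report, file.path(out_dir, "fit_report.csv"),
                          seed, hash)
    write_partition(part, ids, file.path(out_dir, "partition.csv"),
                    file.path(out_dir, "partition.json"), seed, hash)
    write_table_commented(rbind(svm_res$pairs, svm_res$average),
                          file.path(out_dir, "svm_metrics.csv"), seed, hash)
    for (nm in names(profiles)) {
      write_table_commented(profiles[[nm]],
                            file.path(out_dir, paste0("difference_", nm, ".csv")),
                            seed, hash)
    }
    write_run_config(frozen, file.path(out_dir, "config_frozen.yaml"))
  }
  invisible(structure(
    list(deviation = X, hypergraph = gm, fit_report = fit_report,
         partition = part, svm = svm_res, profiles = profiles,
         config_frozen = as_run_config(frozen), output_dir = out_dir),
    class = "idhg_run"))
}

# Rebuild modularity parameters from a frozen-config list for a (possibly
# different) hypergraph: frozen sizes keep their beta and their gamma (the
# scaled gamma is rescaled from the discovery volume to the new volume in
# log space); sizes absent from the frozen set fall back to the defaults.
thaw_params <- function(frozen, g) {
  ks_new <- sort(unique(edge_sizes(g)))
  if (!length(ks_new)) return(default_modularity_params(g))
  vol_new <- sum(degrees(g)$vertex)
  def <- default_modularity_params(g)
  beta <- def$beta
  gs <- def$gamma_scaled
  ks_frozen <- as.integer(unlist(frozen$k))
  vol_old <- frozen$vol_total %||% vol_new
  for (i in seq_along(ks_new)) {
    k <- ks_new[i]
    j <- match(k, ks_frozen)
    if (!is.na(j)) {
      beta[i] <- unlist(frozen$beta)[j]
      g_old <- unlist(frozen$gamma_scaled)[j]
      gs[i] <- if (g_old == 0 || vol_old <= 0 || vol_new <= 0) g_old else
        sign(g_old) * exp(log(abs(g_old)) + k * (log(vol_new) - log(vol_old)))
    }
  }
  modularity_params(beta, gamma_scaled = gs)
}

#' Replication-style re-run with frozen parameters
#'
#' Applies a frozen configuration (as written by [run_pipeline()]) to a new
#' cohort: the elastic-net penalties and the modularity parameters selected
#' on the discovery data are reused verbatim — no grid search and no
#' parameter estimation happens on the replication data.
#'
#' @param frozen_config path to a frozen YAML config, or the list itself.
#' @param features a [feature_table()] for the replication cohort (or `NULL`
#'   to read from the frozen config's paths).
#' @param output optional replacement output directory.
#' @return see [run_pipeline()].
#' @export
replicate_run <- function(frozen_config, features = NULL, output = NULL) {
  if (is.character(frozen_config)) frozen_config <- read_run_config(frozen_config)
  cfg <- unclass(frozen_config)
  if (is.null(cfg$elastic_net$lambda_fixed) || !is.list(cfg$hmll$params)) {
    stop("config is not frozen: needs elastic_net$lambda_fixed and hmll$params",
         call. = FALSE)
  }
  if (!is.null(output)) cfg$paths$output <- output
  run_pipeline(as_run_config(cfg), features = features)
}
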