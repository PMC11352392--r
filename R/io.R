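# FNV-1a hash of a deparsed object; used to stamp outputs with a config
# fingerprint (no cryptographic intent).
config_hash <- function(x) {
  bytes <- utf8ToInt(paste(deparse(x), collapse = "\n"))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

output_header <- function(seed = NA, hash = NA) {
  c(paste0("# idhypergraph ",
           as.character(utils::packageVersion("idhypergraph"))),
    paste0("# seed=", seed, " config=", hash))
}

write_table_commented <- function(df, path, seed = NA, hash = NA) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(output_header(seed, hash), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

read_table_commented <- function(path) {
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Read and write feature / phenotype tables
#'
#' Feature tables are delimited text with the subject ID in the first column
#' and one named feature per remaining column. The phenotype table must have
#' columns `id` and `group` (values `case` / `control`) and may carry
#' covariates (`age`, `site`, clinical scores). Subject order follows the
#' feature file; every subject must appear in both files.
#'
#' @param features_path,phenotype_path CSV file paths.
#' @return a [feature_table()].
#' @export
read_feature_table <- function(features_path, phenotype_path) {
  fv <- read_table_commented(features_path)
  ids <- as.character(fv[[1L]])
  values <- as.matrix(fv[, -1L, drop = FALSE])
  rownames(values) <- ids
  ph <- read_table_commented(phenotype_path)
  for (col in c("id", "group")) {
    if (!col %in% names(ph)) {
      stop("phenotype table lacks required column `", col, "`", call. = FALSE)
    }
  }
  miss <- setdiff(ids, as.character(ph$id))
  if (length(miss)) {
    stop("subjects missing from phenotype table: ",
         paste(utils::head(miss, 5), collapse = ", "), call. = FALSE)
  }
  ph <- ph[match(ids, as.character(ph$id)), , drop = FALSE]
  covs <- ph[, setdiff(names(ph), c("id", "group")), drop = FALSE]
  feature_table(values, ph$group,
                covariates = if (ncol(covs)) covs else NULL)
}

#' @rdname read_feature_table
#' @param ft a [feature_table()].
#' @param seed,hash optional provenance stamps written into the header
#'   comment.
#' @export
write_feature_table <- function(ft, features_path, phenotype_path,
                                seed = NA, hash = NA) {
  stopifnot(inherits(ft, "feature_table"))
  fv <- data.frame(id = rownames(ft$values), ft$values, check.names = FALSE,
                   row.names = NULL)
  write_table_commented(fv, features_path, seed, hash)
  ph <- data.frame(id = rownames(ft$values), group = ft$group,
                   row.names = NULL)
  if (!is.null(ft$covariates)) ph <- cbind(ph, ft$covariates)
  write_table_commented(ph, phenotype_path, seed, hash)
  invisible(c(features_path, phenotype_path))
}

#' Read and write a deviation matrix as CSV
#'
#' Row names are case subject IDs, column names control subject IDs.
#'
#' @param X a [deviation_matrix()].
#' @param path CSV path.
#' @param seed,hash optional provenance stamps.
#' @export
write_deviation_matrix <- function(X, path, seed = NA, hash = NA) {
  df <- data.frame(id = rownames(X), unclass(X), check.names = FALSE,
                   row.names = NULL)
  write_table_commented(df, path, seed, hash)
}

#' @rdname write_deviation_matrix
#' @export
read_deviation_matrix <- function(path) {
  df <- read_table_commented(path)
  X <- as.matrix(df[, -1L, drop = FALSE])
  rownames(X) <- as.character(df[[1L]])
  class(X) <- c("deviation_matrix", class(X))
  X
}

#' Write a partition as CSV and JSON
#'
#' The CSV holds (subject ID, subtype label); the JSON additionally carries
#' the modularity value, the final modularity parameters, the seed and the
#' winning restart.
#'
#' @param part an `"hg_partition"` from [hmll()].
#' @param ids subject IDs, one per vertex.
#' @param csv_path,json_path output paths (either may be `NULL`).
#' @param seed,hash optional provenance stamps.
#' @export
write_partition <- function(part, ids, csv_path = NULL, json_path = NULL,
                            seed = NA, hash = NA) {
  stopifnot(inherits(part, "hg_partition"))
  if (!is.null(csv_path)) {
    write_table_commented(data.frame(id = ids, subtype = part$labels),
                          csv_path, seed, hash)
  }
  if (!is.null(json_path)) {
    par <- part$params
    jsonlite::write_json(
      list(ids = ids, labels = part$labels, n_clusters = part$n_clusters,
           Q = part$Q, seed = part$seed, restart = part$restart,
           params = list(k = par$k, beta = as.list(par$beta),
                         gamma = as.list(par$gamma %||% list()),
                         gamma_scaled = as.list(par$gamma_scaled %||% list()))),
      json_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(part)
}

#' @rdname write_partition
#' @param path a partition CSV written by [write_partition()].
#' @export
read_partition_csv <- function(path) {
  df <- read_table_commented(path)
  stats::setNames(as.integer(df$subtype), df$id)
}

known_config_blocks <- c("paths", "seed", "log_level", "deviation",
                         "elastic_net", "hmll", "svm", "stats", "simulate")

#' Read a YAML run configuration
#'
#' Recognized top-level blocks: `paths` (features, phenotype, output),
#' `seed`, `log_level`, and the per-stage blocks `deviation`, `elastic_net`,
#' `hmll`, `svm`, `stats`, `simulate`. Unknown keys are rejected.
#'
#' @param path YAML file.
#' @return the configuration list (class `"run_config"`).
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  as_run_config(cfg)
}

#' @rdname read_run_config
#' @param cfg a plain configuration list.
#' @export
as_run_config <- function(cfg) {
  unknown <- setdiff(names(cfg), known_config_blocks)
  if (length(unknown)) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(cfg$seed)) cfg$seed <- 1L
  structure(cfg, class = c("run_config", "list"))
}

#' @rdname read_run_config
#' @export
write_run_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}
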