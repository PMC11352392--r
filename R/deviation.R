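#' Feature table container
#'
#' Bundles a subjects x features matrix (e.g. mean ALFF per atlas region)
#' with group labels and covariates. Feature values must be complete (no
#' missing entries).
#'
#' @param values numeric matrix, one row per subject, one column per feature.
#'   Row names are subject IDs (generated if absent).
#' @param group character/factor per subject, levels `"case"` and `"control"`.
#' @param covariates optional data.frame of per-subject covariates
#'   (e.g. `age`, `site`, clinical scores).
#' @return object of class `"feature_table"`.
#' @export
feature_table <- function(values, group, covariates = NULL) {
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("feature values must be numeric", call. = FALSE)
  if (anyNA(values) || any(!is.finite(values))) {
    stop("feature table contains missing or non-finite values", call. = FALSE)
  }
  if (is.null(rownames(values))) {
    rownames(values) <- sprintf("S%03d", seq_len(nrow(values)))
  }
  if (is.null(colnames(values))) {
    colnames(values) <- sprintf("R%03d", seq_len(ncol(values)))
  }
  group <- as.character(group)
  if (length(group) != nrow(values)) {
    stop("`group` must have one entry per subject", call. = FALSE)
  }
  bad <- setdiff(unique(group), c("case", "control"))
  if (length(bad)) {
    stop("unknown group label(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    if (nrow(covariates) != nrow(values)) {
      stop("`covariates` must have one row per subject", call. = FALSE)
    }
    rownames(covariates) <- rownames(values)
  }
  structure(list(values = values, group = group, covariates = covariates),
            class = "feature_table")
}

#' @exportS3Method base::print
print.feature_table <- function(x, ...) {
  cat("feature_table: ", nrow(x$values), " subjects x ", ncol(x$values),
      " features (", sum(x$group == "case"), " case / ",
      sum(x$group == "control"), " control)\n", sep = "")
  invisible(x)
}

#' Subset a feature table by group
#'
#' @param ft a [feature_table()].
#' @param group `"case"` or `"control"`.
#' @return the subjects x features matrix for that group.
#' @export
group_values <- function(ft, group = c("case", "control")) {
  stopifnot(inherits(ft, "feature_table"))
  group <- match.arg(group)
  ft$values[ft$group == group, , drop = FALSE]
}

#' Cosine deviation between two feature vectors
#'
#' `1 - (f . g) / (||f|| ||g||)`, the cosine distance; lies in `[0, 2]` and is
#' 0 exactly when the vectors are positively collinear.
#'
#' @param f,g numeric vectors of equal length with nonzero norm.
#' @return a single number in `[0, 2]`.
#' @examples
#' cosine_deviation(c(1, 2, 2), c(2, 1, 2))  # 1/9
#' @export
cosine_deviation <- function(f, g) {
  if (length(f) != length(g) || length(f) < 1L) {
    stop("vectors must have equal positive length", call. = FALSE)
  }
  if (any(!is.finite(f)) || any(!is.finite(g))) {
    stop("non-finite feature values", call. = FALSE)
  }
  nf <- sqrt(sum(f^2)); ng <- sqrt(sum(g^2))
  if (nf == 0 || ng == 0) {
    stop("cosine deviation undefined for a zero-norm vector", call. = FALSE)
  }
  d <- 1 - sum(f * g) / (nf * ng)
  min(max(d, 0), 2)  # clip rounding spill outside [0, 2]
}

#' Inter-individual deviation matrix
#'
#' For every case subject, the cosine deviation of its feature vector from
#' every control subject's feature vector: `X[i, j] = 1 - cos(case_i,
#' control_j)`. Row order follows the case subjects, column order the
#' controls. Optionally z-scores each feature column against the control
#' group first, or uses correlation distance (centring both vectors) instead
#' of plain cosine distance.
#'
#' @param cases,controls numeric matrices (subjects x features) with a shared
#'   feature dimension; row names are subject IDs. A [feature_table()] may be
#'   given as `cases`, in which case `controls` is ignored and the two groups
#'   are taken from the table.
#' @param zscore_controls if `TRUE`, each feature column (of both groups) is
#'   centred and scaled by the control-group mean and SD before the distance.
#' @param distance `"cosine"` (default) or `"correlation"` (centres each
#'   subject's vector before the cosine).
#' @return matrix of class `"deviation_matrix"` (`n_case x n_control`,
#'   entries in `[0, 2]`, dimnames = subject IDs).
#' @export
deviation_matrix <- function(cases, controls = NULL, zscore_controls = FALSE,
                             distance = c("cosine", "correlation")) {
  distance <- match.arg(distance)
  if (inherits(cases, "feature_table")) {
    controls <- group_values(cases, "control")
    cases <- group_values(cases, "case")
  }
  cases <- as.matrix(cases); controls <- as.matrix(controls)
  if (ncol(cases) != ncol(controls)) {
    stop("case and control feature dimensions differ", call. = FALSE)
  }
  if (nrow(cases) < 2L || nrow(controls) < 2L) {
    stop("need at least 2 subjects per group", call. = FALSE)
  }
  if (zscore_controls) {
    mu <- colMeans(controls)
    sd <- apply(controls, 2, stats::sd)
    sd[sd == 0] <- 1
    cases <- sweep(sweep(cases, 2, mu), 2, sd, "/")
    controls <- sweep(sweep(controls, 2, mu), 2, sd, "/")
  }
  if (distance == "correlation") {
    cases <- cases - rowMeans(cases)
    controls <- controls - rowMeans(controls)
  }
  nc <- sqrt(rowSums(cases^2))
  nt <- sqrt(rowSums(controls^2))
  if (any(nc == 0)) {
    stop("zero-norm case vector(s): ",
         paste(rownames(cases)[nc == 0], collapse = ", "), call. = FALSE)
  }
  if (any(nt == 0)) {
    stop("zero-norm control vector(s): ",
         paste(rownames(controls)[nt == 0], collapse = ", "), call. = FALSE)
  }
  X <- 1 - tcrossprod(cases / nc, controls / nt)
  X[X < 0] <- 0
  X[X > 2] <- 2
  dimnames(X) <- list(rownames(cases), rownames(controls))
  class(X) <- c("deviation_matrix", class(X))
  X
}
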