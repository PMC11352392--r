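#' Classification metrics from confusion counts
#'
#' `ACC = (TP + TN) / (TP + FN + TN + FP)`, `SEN = TP / (TP + FN)`,
#' `SPE = TN / (TN + FP)`.
#'
#' @param tp,fn,tn,fp nonnegative integer counts.
#' @return list with `acc`, `sen`, `spe`.
#' @examples
#' confusion_metrics(30, 10, 40, 20)  # acc 0.70, sen 0.75, spe 0.6667
#' @export
confusion_metrics <- function(tp, fn, tn, fp) {
  counts <- c(tp = tp, fn = fn, tn = tn, fp = fp)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("confusion counts must be nonnegative integers", call. = FALSE)
  }
  if (sum(counts) < 1) stop("empty confusion table", call. = FALSE)
  if (tp + fn == 0) stop("sensitivity undefined: no positives (TP + FN = 0)",
                         call. = FALSE)
  if (tn + fp == 0) stop("specificity undefined: no negatives (TN + FP = 0)",
                         call. = FALSE)
  list(acc = (tp + tn) / sum(counts), sen = tp / (tp + fn),
       spe = tn / (tn + fp))
}

#' Area under the ROC curve by rank statistic
#'
#' Mann-Whitney formulation on scores: the probability that a random
#' positive scores above a random negative (ties count 1/2).
#'
#' @param scores numeric decision values, higher = more positive.
#' @param positive logical vector, `TRUE` for the positive class.
#' @return AUC in `[0, 1]`.
#' @export
auc_rank <- function(scores, positive) {
  stopifnot(length(scores) == length(positive))
  np <- sum(positive); nn <- sum(!positive)
  if (np == 0 || nn == 0) stop("AUC undefined with a single class", call. = FALSE)
  r <- rank(scores)
  (sum(r[positive]) - np * (np + 1) / 2) / (np * nn)
}

#' Pairwise subtype separability by cross-validated RBF-SVM
#'
#' One binary RBF-SVM per unordered pair of subtypes, evaluated by stratified
#' `n_folds`-fold cross-validation on the given features. For every pair the
#' penalty `C` is selected from `C_grid` by pooled out-of-fold accuracy over
#' the same folds (a single CV loop, no nesting), and ACC / SEN / SPE are
#' computed from the pooled out-of-fold confusion table; AUC is the rank
#' statistic of the pooled out-of-fold decision scores. The positive class
#' of a pair is the lower-numbered subtype. The summary row is the
#' unweighted mean over pairs. Deterministic given `seed`.
#'
#' @param features numeric matrix, one row per subject.
#' @param z subtype labels (integers), one per row of `features`.
#' @param C_grid penalty grid (default `2^(-5:2)`; ties resolved toward the
#'   smaller `C`).
#' @param n_folds folds (default 10; shrunk with a warning when the smaller
#'   class of a pair has fewer members).
#' @param seed integer seed for the stratified fold assignment.
#' @param gamma RBF bandwidth, default `1 / (n_features * pooled feature
#'   variance)` of the pair's data.
#' @return list with `pairs` (data.frame: pair, acc, sen, spe, auc, C,
#'   n), `average` (unweighted means), `skipped` (character).
#' @export
pairwise_svm_cv <- function(features, z, C_grid = 2^(-5:2), n_folds = 10L,
                            seed = 1L, gamma = NULL) {
  features <- as.matrix(features)
  stopifnot(nrow(features) == length(z))
  subs <- sort(unique(z))
  rows <- list(); skipped <- character(0)
  C_grid <- sort(C_grid)
  for (ia in seq_along(subs)) for (ib in seq_along(subs)) {
    if (ib <= ia) next
    a <- subs[ia]; b <- subs[ib]
    sel <- which(z %in% c(a, b))
    ya <- z[sel] == a                   # positive class: lower-numbered
    if (min(sum(ya), sum(!ya)) < 2L) {
      skipped <- c(skipped, paste0(a, " vs ", b, ": a subtype has < 2 members"))
      next
    }
    nf <- n_folds
    if (min(sum(ya), sum(!ya)) < nf) {
      nf <- min(sum(ya), sum(!ya))
      warning("pair ", a, " vs ", b, ": folds shrunk to ", nf)
    }
    Xp <- features[sel, , drop = FALSE]
    fold <- integer(length(sel))
    with_seed(derive_seed(seed, paste0("svmcv-", a, "-", b)), {
      for (cls in list(which(ya), which(!ya))) {
        fold[cls[sample.int(length(cls))]] <- rep_len(seq_len(nf), length(cls))
      }
    })
    gma <- gamma %||%
      (1 / (ncol(Xp) * max(mean(apply(Xp, 2, stats::var)), .Machine$double.eps)))
    oof <- matrix(NA_real_, nrow = length(sel), ncol = length(C_grid))
    for (f in seq_len(nf)) {
      tr <- fold != f; te <- !tr
      for (ci in seq_along(C_grid)) {
        fit <- svm_rbf(Xp[tr, , drop = FALSE],
                       factor(ifelse(ya[tr], "pos", "neg"),
                              levels = c("pos", "neg")),
                       C = C_grid[ci], gamma = gma)
        oof[te, ci] <- predict(fit, Xp[te, , drop = FALSE], type = "decision")
      }
    }
    accs <- colMeans((oof >= 0) == ya)
    ci <- which.max(accs)               # which.max takes the first (smallest C)
    scores <- oof[, ci]
    tp <- sum(scores >= 0 & ya); fn <- sum(scores < 0 & ya)
    tn <- sum(scores < 0 & !ya); fp <- sum(scores >= 0 & !ya)
    met <- confusion_metrics(tp, fn, tn, fp)
    rows[[length(rows) + 1L]] <- data.frame(
      pair = paste0(a, " vs ", b), acc = met$acc, sen = met$sen,
      spe = met$spe, auc = auc_rank(scores, ya), C = C_grid[ci],
      n = length(sel))
  }
  pairs <- if (length(rows)) do.call(rbind, rows) else
    data.frame(pair = character(0), acc = numeric(0), sen = numeric(0),
               spe = numeric(0), auc = numeric(0), C = numeric(0),
               n = integer(0))
  avg <- if (nrow(pairs)) {
    data.frame(pair = "average", acc = mean(pairs$acc), sen = mean(pairs$sen),
               spe = mean(pairs$spe), auc = mean(pairs$auc), C = NA_real_,
               n = sum(pairs$n))
  } else NULL
  list(pairs = pairs, average = avg, skipped = skipped)
}

#' Covariate-adjusted two-group difference per feature
#'
#' Fits `value ~ group + covariates` per feature by least squares and reports
#' the group coefficient's t statistic and two-sided p value (group coded 1
#' for case). With no covariates this is exactly the classical equal-variance
#' two-sample t test. Categorical covariates (e.g. site) are expanded to
#' indicator columns; a rank-deficient design is an error naming the aliased
#' columns.
#'
#' @param y numeric matrix (subjects x features) or vector.
#' @param group per-subject labels, `"case"` / `"control"`.
#' @param covariates optional data.frame of per-subject covariates.
#' @return data.frame: `feature`, `estimate` (case minus control, adjusted),
#'   `t`, `p`, `direction` (`"case>control"` / `"case<control"` / `"none"`).
#' @export
adjusted_group_difference <- function(y, group, covariates = NULL) {
  y <- as.matrix(y)
  if (is.null(colnames(y))) colnames(y) <- sprintf("f%d", seq_len(ncol(y)))
  group <- as.character(group)
  stopifnot(length(group) == nrow(y), all(group %in% c("case", "control")))
  if (min(table(group)) < 3L) {
    stop("need at least 3 subjects per group", call. = FALSE)
  }
  df <- data.frame(.g = as.numeric(group == "case"))
  if (!is.null(covariates) && ncol(as.data.frame(covariates)) > 0L) {
    cov <- as.data.frame(covariates)
    for (nm in names(cov)) {
      if (is.character(cov[[nm]])) cov[[nm]] <- factor(cov[[nm]])
    }
    df <- cbind(df, cov)
  }
  X <- stats::model.matrix(~ ., data = df)
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    aliased <- colnames(X)[qx$pivot[(qx$rank + 1L):ncol(X)]]
    stop("rank-deficient design; aliased column(s): ",
         paste(aliased, collapse = ", "), call. = FALSE)
  }
  n <- nrow(X)
  dof <- n - qx$rank
  coefs <- qr.coef(qx, y)
  res <- y - X %*% coefs
  s2 <- colSums(res^2) / dof
  xtx_inv <- chol2inv(qr.R(qx))
  gi <- match(".g", colnames(X))
  se <- sqrt(xtx_inv[gi, gi] * s2)
  tval <- coefs[gi, ] / se
  pval <- 2 * stats::pt(abs(tval), df = dof, lower.tail = FALSE)
  data.frame(feature = colnames(y), estimate = coefs[gi, ], t = tval,
             p = pval,
             direction = ifelse(tval > 0, "case>control",
                                ifelse(tval < 0, "case<control", "none")),
             row.names = NULL)
}

#' Benjamini-Hochberg step-up FDR adjustment
#'
#' Adjusted values `q_(i) = min_{j >= i} p_(j) * m / j` (monotone by the
#' tail cumulative minimum, capped at 1), with rejection at `q <=
#' q_threshold`.
#'
#' @param pvals p values in `[0, 1]`.
#' @param q_threshold rejection level (default 0.05).
#' @return list with `q` (adjusted values, input order) and `reject`
#'   (logical).
#' @examples
#' fdr_bh(c(0.01, 0.02, 0.04, 0.05))$q  # 0.04 0.04 0.05 0.05
#' @export
fdr_bh <- function(pvals, q_threshold = 0.05) {
  if (any(!is.finite(pvals)) || any(pvals < 0) || any(pvals > 1)) {
    stop("p values must lie in [0, 1]", call. = FALSE)
  }
  m <- length(pvals)
  o <- order(pvals)
  q_sorted <- pmin(1, rev(cummin(rev(pvals[o] * m / seq_len(m)))))
  q <- numeric(m)
  q[o] <- q_sorted
  list(q = q, reject = q <= q_threshold)
}

#' Per-subtype difference maps against the control group
#'
#' For each subtype, runs [adjusted_group_difference()] of that subtype's
#' members against all controls over every feature, applies
#' Benjamini-Hochberg FDR within the comparison, and reports signed
#' significant features.
#'
#' @param ft a [feature_table()] containing both groups.
#' @param z subtype labels for the case subjects, in the order the cases
#'   appear in `ft`.
#' @param covariates character vector of covariate column names from
#'   `ft$covariates` to adjust for (default `age` and `site` when present).
#' @param q_threshold FDR level per comparison (default 0.05).
#' @return named list (one per subtype) of data.frames: `feature`,
#'   `estimate`, `t`, `p`, `q`, `direction`, `significant`. Subtypes with
#'   fewer than 3 members are skipped with a message.
#' @export
subtype_profile <- function(ft, z, covariates = NULL, q_threshold = 0.05) {
  stopifnot(inherits(ft, "feature_table"))
  is_case <- ft$group == "case"
  stopifnot(sum(is_case) == length(z))
  if (is.null(covariates)) {
    covariates <- intersect(c("age", "site"), names(ft$covariates))
  }
  ctrl_idx <- which(!is_case)
  case_idx <- which(is_case)
  out <- list()
  for (s in sort(unique(z))) {
    members <- case_idx[z == s]
    if (length(members) < 3L) {
      message("subtype ", s, " skipped: fewer than 3 members")
      next
    }
    idx <- c(members, ctrl_idx)
    covs <- if (length(covariates)) {
      ft$covariates[idx, covariates, drop = FALSE]
    }
    tab <- adjusted_group_difference(ft$values[idx, , drop = FALSE],
                                     ft$group[idx], covs)
    bh <- fdr_bh(tab$p, q_threshold)
    tab$q <- bh$q
    tab$significant <- bh$reject
    tab$direction[!tab$significant] <- "none"
    out[[paste0("subtype", s)]] <- tab
  }
  out
}
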