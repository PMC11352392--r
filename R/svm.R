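#' RBF-kernel support vector classifier
#'
#' A self-contained C-SVC with radial basis kernel
#' `K(x, z) = exp(-gamma ||x - z||^2)`, trained by sequential minimal
#' optimization with maximal-violating-pair working-set selection on the
#' standard dual. Used by [pairwise_svm_cv()]; exported so the optimizer can
#' be tested directly.
#'
#' @param x numeric matrix of training rows.
#' @param y two-class labels; the first factor level is the positive class.
#' @param C box constraint.
#' @param gamma kernel bandwidth; default `1 / (n_features * pooled feature
#'   variance)`.
#' @param tol KKT violation tolerance for the stopping rule.
#' @param max_iter cap on working-set iterations.
#' @return object of class `"svm_rbf"` (support coefficients `alpha * y`,
#'   intercept `b`, training rows, `gamma`, `levels`).
#' @export
svm_rbf <- function(x, y, C = 1, gamma = NULL, tol = 1e-3,
                    max_iter = 100000L) {
  x <- as.matrix(x)
  y <- factor(y)
  if (nlevels(y) != 2L) stop("svm_rbf needs exactly two classes", call. = FALSE)
  yy <- ifelse(y == levels(y)[1L], 1, -1)
  n <- nrow(x)
  if (is.null(gamma)) gamma <- 1 / (ncol(x) * max(mean(apply(x, 2, stats::var)),
                                                  .Machine$double.eps))
  K <- rbf_kernel(x, x, gamma)
  alpha <- numeric(n)
  grad <- rep(-1, n)                     # grad = Q alpha - 1, Q = (y y') * K
  it <- 0L
  repeat {
    it <- it + 1L
    vio <- -yy * grad
    up <- (yy > 0 & alpha < C - 1e-12) | (yy < 0 & alpha > 1e-12)
    lo <- (yy < 0 & alpha < C - 1e-12) | (yy > 0 & alpha > 1e-12)
    if (!any(up) || !any(lo)) break
    i <- which(up)[which.max(vio[up])]
    j <- which(lo)[which.min(vio[lo])]
    if (vio[i] - vio[j] <= tol || it > max_iter) break
    quad <- max(K[i, i] + K[j, j] - 2 * K[i, j], 1e-12)
    delta <- (vio[i] - vio[j]) / quad
    # box constraints on alpha_i + y_i delta and alpha_j - y_j delta
    dmax <- min(if (yy[i] > 0) C - alpha[i] else alpha[i],
                if (yy[j] > 0) alpha[j] else C - alpha[j])
    delta <- min(delta, dmax)
    if (delta <= 0) break
    dai <- yy[i] * delta
    daj <- -yy[j] * delta
    alpha[i] <- alpha[i] + dai
    alpha[j] <- alpha[j] + daj
    grad <- grad + (yy * K[, i]) * (yy[i] * dai) + (yy * K[, j]) * (yy[j] * daj)
  }
  if (it > max_iter) warning("SMO reached the iteration cap before the KKT gap closed")
  free <- alpha > 1e-8 & alpha < C - 1e-8
  b <- if (any(free)) mean(-yy[free] * grad[free]) else {
    vio <- -yy * grad
    up <- (yy > 0 & alpha < C - 1e-12) | (yy < 0 & alpha > 1e-12)
    lo <- (yy < 0 & alpha < C - 1e-12) | (yy > 0 & alpha > 1e-12)
    (max(vio[lo], -Inf) + min(vio[up], Inf)) / 2
  }
  if (!is.finite(b)) b <- 0
  structure(list(coefs = alpha * yy, b = b, x = x, gamma = gamma,
                 levels = levels(y), C = C, iterations = it),
            class = "svm_rbf")
}

rbf_kernel <- function(a, b, gamma) {
  an <- rowSums(a^2); bn <- rowSums(b^2)
  d2 <- outer(an, bn, "+") - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  exp(-gamma * d2)
}

#' @rdname svm_rbf
#' @param object fitted `"svm_rbf"` model.
#' @param newdata matrix of rows to score.
#' @param type `"decision"` (signed score; positive = first level) or
#'   `"class"`.
#' @param ... unused.
#' @export
predict.svm_rbf <- function(object, newdata, type = c("decision", "class"),
                            ...) {
  type <- match.arg(type)
  K <- rbf_kernel(as.matrix(newdata), object$x, object$gamma)
  f <- as.vector(K %*% object$coefs) + object$b
  if (type == "decision") f else
    factor(ifelse(f >= 0, object$levels[1L], object$levels[2L]),
           levels = object$levels)
}

# SMO dual objective, for oracle comparisons in tests
svm_dual_objective <- function(model, y) {
  yy <- ifelse(y == model$levels[1L], 1, -1)
  alpha <- model$coefs * yy
  K <- rbf_kernel(model$x, model$x, model$gamma)
  0.5 * as.numeric(t(alpha * yy) %*% K %*% (alpha * yy)) - sum(alpha)
}
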