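#' Construct a hypergraph
#'
#' A hypergraph `G = (V, E, w)` over vertices `1..n_vertices` with a weighted
#' multiset of hyperedges. Each hyperedge is a nonempty subset of the vertex
#' set; duplicated hyperedges may be represented either as repeated entries or
#' via an integer multiplicity (see [merge_duplicates()]). Hyperedge weights
#' default to 1, i.e. an identity weight matrix.
#'
#' Vertices are 1-based throughout the user-facing interface (and in the text
#' file format, see [read_hypergraph()]).
#'
#' @param edges list of integer vectors, each a nonempty set of vertex indices
#'   in `1..n_vertices`. Vertices within an edge are stored sorted and unique.
#' @param n_vertices number of vertices `N`.
#' @param weights optional numeric vector of nonnegative hyperedge weights
#'   `w(e_j)`; defaults to 1 for every hyperedge.
#' @param multiplicities optional positive integer vector `a_j`; defaults to 1.
#' @param labels optional character vector of vertex labels (e.g. subject IDs).
#' @return an object of class `"hypergraph"`.
#' @examples
#' g <- hypergraph(list(c(1, 2), c(1, 3)), n_vertices = 3)
#' incidence_matrix(g)
#' @export
hypergraph <- function(edges, n_vertices, weights = NULL,
                       multiplicities = NULL, labels = NULL) {
  if (!is.numeric(n_vertices) || length(n_vertices) != 1L || n_vertices < 0 ||
      n_vertices != round(n_vertices)) {
    stop("`n_vertices` must be a single nonnegative integer", call. = FALSE)
  }
  n_vertices <- as.integer(n_vertices)
  if (!is.list(edges)) stop("`edges` must be a list of vertex vectors", call. = FALSE)
  m <- length(edges)
  edges <- lapply(seq_len(m), function(j) {
    e <- edges[[j]]
    if (length(e) == 0L) {
      stop("hyperedge ", j, " is empty", call. = FALSE)
    }
    if (!is.numeric(e) || any(e != round(e))) {
      stop("hyperedge ", j, " has non-integer vertex indices", call. = FALSE)
    }
    e <- sort(unique(as.integer(e)))
    if (e[1L] < 1L || e[length(e)] > n_vertices) {
      stop("hyperedge ", j, " has vertex indices outside 1..", n_vertices,
           call. = FALSE)
    }
    e
  })
  if (is.null(weights)) weights <- rep(1, m)
  if (is.null(multiplicities)) multiplicities <- rep(1L, m)
  stopifnot(length(weights) == m, length(multiplicities) == m)
  if (any(!is.finite(weights)) || any(weights < 0)) {
    stop("hyperedge weights must be finite and nonnegative", call. = FALSE)
  }
  if (any(multiplicities < 1) || any(multiplicities != round(multiplicities))) {
    stop("multiplicities must be positive integers", call. = FALSE)
  }
  if (!is.null(labels) && length(labels) != n_vertices) {
    stop("`labels` must have one entry per vertex", call. = FALSE)
  }
  structure(
    list(n_vertices = n_vertices, edges = edges, weights = as.numeric(weights),
         multiplicities = as.integer(multiplicities), labels = labels),
    class = "hypergraph"
  )
}

#' @exportS3Method base::print
print.hypergraph <- function(x, ...) {
  cat("hypergraph: ", x$n_vertices, " vertices, ", length(x$edges),
      " hyperedges (total multiplicity ", sum(x$multiplicities), ")\n", sep = "")
  sz <- edge_sizes(x)
  if (length(sz)) {
    tab <- table(sz)
    cat("edge sizes: ", paste0(names(tab), ":", as.integer(tab), collapse = " "),
        "\n", sep = "")
  }
  invisible(x)
}

#' Hyperedge sizes
#'
#' @param g a [hypergraph()].
#' @return integer vector of hyperedge cardinalities `delta(e_j)`.
#' @export
edge_sizes <- function(g) {
  stopifnot(inherits(g, "hypergraph"))
  vapply(g$edges, length, integer(1))
}

#' Incidence matrix of a hypergraph
#'
#' Builds the binary `N x M` incidence matrix with `H[v, e] = 1` iff vertex
#' `v` belongs to hyperedge `e`.
#'
#' @param g a [hypergraph()].
#' @param sparse return a sparse `Matrix` (default) or a dense base matrix.
#' @return an `N x M` 0/1 matrix.
#' @export
incidence_matrix <- function(g, sparse = TRUE) {
  stopifnot(inherits(g, "hypergraph"))
  m <- length(g$edges)
  i <- unlist(g$edges, use.names = FALSE)
  j <- rep.int(seq_len(m), times = edge_sizes(g))
  H <- Matrix::sparseMatrix(i = i, j = j, x = 1,
                            dims = c(g$n_vertices, m))
  if (sparse) H else as.matrix(H)
}

#' Vertex and hyperedge degrees
#'
#' Vertex degree `d(v_i) = sum_j w(e_j) * a_j * H[i, j]` (hyperedge weight
#' times multiplicity, summed over incident hyperedges); hyperedge degree
#' `delta(e_j) = |e_j|`. Satisfies the handshake identity
#' `sum_i d(v_i) = sum_j w_j a_j delta(e_j)`.
#'
#' @param g a [hypergraph()].
#' @return a list of class `"degree_profile"` with components
#'   `vertex` (length `N`), `edge` (length `M`), and `k_max`
#'   (largest hyperedge size, 0 for an edgeless hypergraph).
#' @export
degrees <- function(g) {
  stopifnot(inherits(g, "hypergraph"))
  d <- numeric(g$n_vertices)
  wa <- g$weights * g$multiplicities
  for (j in seq_along(g$edges)) {
    e <- g$edges[[j]]
    d[e] <- d[e] + wa[j]
  }
  delta <- edge_sizes(g)
  structure(list(vertex = d, edge = delta,
                 k_max = if (length(delta)) max(delta) else 0L),
            class = "degree_profile")
}

#' Merge duplicated hyperedges
#'
#' Collapses hyperedges with identical vertex sets into a single hyperedge
#' whose multiplicity is the sum of the originals (weights must agree; the
#' merged weight is the common weight). Degrees are unchanged by merging.
#'
#' @param g a [hypergraph()].
#' @return a [hypergraph()] with distinct hyperedges and summed multiplicities.
#' @export
merge_duplicates <- function(g) {
  stopifnot(inherits(g, "hypergraph"))
  if (length(g$edges) <= 1L) return(g)
  key <- vapply(g$edges, function(e) paste(e, collapse = ","), character(1))
  if (!anyDuplicated(key)) return(g)
  grp <- split(seq_along(key), factor(key, levels = unique(key)))
  edges <- lapply(grp, function(idx) g$edges[[idx[1L]]])
  wts <- vapply(grp, function(idx) {
    w <- unique(g$weights[idx])
    if (length(w) > 1L) {
      # duplicated edge with differing weights: merge mass exactly by folding
      # the weighted multiplicity into an average weight
      sum(g$weights[idx] * g$multiplicities[idx]) / sum(g$multiplicities[idx])
    } else {
      w
    }
  }, numeric(1))
  mult <- vapply(grp, function(idx) sum(g$multiplicities[idx]), integer(1))
  hypergraph(unname(edges), g$n_vertices, weights = unname(wts),
             multiplicities = unname(mult), labels = g$labels)
}

#' Read / write the hypergraph text format
#'
#' One line per hyperedge: whitespace-separated 1-based vertex indices,
#' optionally followed by `w=<float>` and/or `a=<int>` tokens. The first line
#' is a header comment `# vertices=<N>` carrying the vertex count (vertices
#' may be isolated). Round-trips exactly.
#'
#' @param path file path.
#' @param g a [hypergraph()].
#' @return `read_hypergraph()` returns a [hypergraph()];
#'   `write_hypergraph()` returns `path` invisibly.
#' @export
read_hypergraph <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  n <- NA_integer_
  hdr <- grep("^#\\s*vertices=", lines, value = TRUE)
  if (length(hdr)) n <- as.integer(sub("^#\\s*vertices=", "", hdr[1L]))
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  edges <- list(); wts <- numeric(0); mult <- integer(0)
  for (ln in lines) {
    tok <- strsplit(ln, "\\s+")[[1L]]
    w <- 1; a <- 1L
    is_w <- grepl("^w=", tok); is_a <- grepl("^a=", tok)
    if (any(is_w)) w <- as.numeric(sub("^w=", "", tok[is_w][1L]))
    if (any(is_a)) a <- as.integer(sub("^a=", "", tok[is_a][1L]))
    v <- as.integer(tok[!is_w & !is_a])
    edges[[length(edges) + 1L]] <- v
    wts <- c(wts, w); mult <- c(mult, a)
  }
  if (is.na(n)) n <- if (length(edges)) max(unlist(edges)) else 0L
  hypergraph(edges, n, weights = wts, multiplicities = mult)
}

#' @rdname read_hypergraph
#' @export
write_hypergraph <- function(g, path) {
  stopifnot(inherits(g, "hypergraph"))
  lines <- c(paste0("# vertices=", g$n_vertices))
  for (j in seq_along(g$edges)) {
    ln <- paste(g$edges[[j]], collapse = " ")
    if (g$weights[j] != 1) ln <- paste0(ln, " w=", format(g$weights[j], digits = 17))
    if (g$multiplicities[j] != 1L) ln <- paste0(ln, " a=", g$multiplicities[j])
    lines <- c(lines, ln)
  }
  writeLines(lines, path)
  invisible(path)
}
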