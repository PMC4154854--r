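#' Coarse-grained RNA tree graphs
#'
#' A `rag_tree` is a labeled, unrooted, connected acyclic graph: the
#' RNA-As-Graphs (RAG) tree representation of an RNA secondary structure,
#' where every edge is a double-stranded helix and every vertex a
#' single-stranded element (hairpin loop, internal loop/bulge, junction, or
#' the 5'/3' exterior strand). Vertices are labeled in 5'-to-3' order of the
#' corresponding structural elements.
#'
#' @param edges edge list: a two-column data frame or matrix of vertex
#'   labels, or a flat even-length vector taken pairwise. Labels are 1-based
#'   integers.
#' @param n vertex count. Defaults to the maximum label found in `edges`.
#' @param name optional identifier carried along (e.g. `"6_2"`).
#'
#' @return An object of class `rag_tree` with fields `n` (vertex count),
#'   `vertices` (ordered integer labels), `edges` (two-column integer matrix,
#'   each row sorted), and `name`.
#'
#' @details Validation distinguishes the failure modes: labels out of range,
#' self-loops, duplicate edges, a cycle (`|E| > |V| - 1`), and
#' disconnectedness. Fragments produced by cutting a parent graph keep the
#' parent's vertex labels, so `vertices` need not be `1:n` in general;
#' `rag_tree()` itself always builds a graph on labels `1:n`.
#'
#' @examples
#' g <- rag_tree(data.frame(from = c(1, 2, 2, 4, 5), to = c(2, 3, 4, 5, 6)),
#'               name = "6_2")
#' g
#' @export
rag_tree <- function(edges, n = NULL, name = NULL) {
  em <- as_edge_matrix(edges)
  if (is.null(n)) n <- max(em)
  n <- as.integer(n)
  if (length(n) != 1L || is.na(n) || n < 2L)
    stop("`n` must be a single integer >= 2", call. = FALSE)
  if (any(em < 1L | em > n))
    stop("vertex label out of range 1..", n, call. = FALSE)
  new_rag_tree(seq_len(n), em, name = name)
}

# internal constructor: arbitrary (fragment) labels allowed
new_rag_tree <- function(vertices, edges, name = NULL) {
  vertices <- sort(unique(as.integer(vertices)))
  edges <- normalize_edges(edges)
  g <- structure(
    list(n = length(vertices), vertices = vertices, edges = edges, name = name),
    class = "rag_tree"
  )
  validate_rag_tree(g)
}

as_edge_matrix <- function(edges) {
  if (is.data.frame(edges)) edges <- as.matrix(edges[, 1:2])
  if (is.matrix(edges)) {
    if (ncol(edges) != 2L) stop("edge matrix must have two columns", call. = FALSE)
  } else {
    edges <- as.vector(edges)
    if (length(edges) %% 2L != 0L)
      stop("flat edge vector must have even length", call. = FALSE)
    edges <- matrix(edges, ncol = 2L, byrow = TRUE)
  }
  storage.mode(edges) <- "integer"
  if (anyNA(edges)) stop("edge labels must be integers", call. = FALSE)
  edges
}

normalize_edges <- function(em) {
  em <- as_edge_matrix(em)
  em <- cbind(pmin(em[, 1], em[, 2]), pmax(em[, 1], em[, 2]))
  em <- em[order(em[, 1], em[, 2]), , drop = FALSE]
  dimnames(em) <- list(NULL, c("from", "to"))
  em
}

validate_rag_tree <- function(g) {
  em <- g$edges
  if (g$n < 2L) stop("a RAG tree needs at least 2 vertices", call. = FALSE)
  if (any(em[, 1] == em[, 2])) stop("self-loop detected", call. = FALSE)
  if (anyDuplicated(paste(em[, 1], em[, 2]))) stop("duplicate edge detected", call. = FALSE)
  if (!all(em %in% g$vertices)) stop("edge endpoint is not a graph vertex", call. = FALSE)
  if (nrow(em) > g$n - 1L) stop("cycle detected: |E| > |V| - 1", call. = FALSE)
  if (nrow(em) < g$n - 1L) stop("graph is disconnected: |E| < |V| - 1", call. = FALSE)
  # |E| = |V| - 1: connected iff acyclic; check reachability from first vertex
  comp <- connected_components(g$vertices, em)
  if (length(comp) > 1L) stop("cycle detected: graph is disconnected with |E| = |V| - 1",
                              call. = FALSE)
  g
}

# adjacency list over positional indices 1..n
adjacency_list <- function(g) {
  idx <- match(g$edges, g$vertices)
  ei <- matrix(idx, ncol = 2L)
  adj <- vector("list", g$n)
  for (k in seq_len(nrow(ei))) {
    adj[[ei[k, 1]]] <- c(adj[[ei[k, 1]]], ei[k, 2])
    adj[[ei[k, 2]]] <- c(adj[[ei[k, 2]]], ei[k, 1])
  }
  adj
}

# components as list of label vectors
connected_components <- function(vertices, em) {
  n <- length(vertices)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  if (nrow(em) > 0) {
    ei <- matrix(match(em, vertices), ncol = 2L)
    for (k in seq_len(nrow(ei))) {
      a <- find(ei[k, 1]); b <- find(ei[k, 2])
      if (a != b) parent[a] <- b
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  unname(split(vertices, roots))
}

#' Vertex degrees of a RAG tree
#'
#' @param g a [rag_tree()].
#' @return named integer vector of degrees, in vertex-label order.
#' @export
rag_degree <- function(g) {
  stopifnot(inherits(g, "rag_tree"))
  d <- tabulate(match(g$edges, g$vertices), nbins = g$n)
  names(d) <- g$vertices
  d
}

#' Graph Laplacian L = D - A
#'
#' Builds the combinatorial Laplacian of a RAG tree: `D` is the diagonal
#' degree matrix and `A` the adjacency matrix, so the diagonal entry for
#' vertex i is its degree d(i), off-diagonal entries are -1 exactly on
#' edges, and every row sums to zero. `L` is symmetric positive
#' semidefinite; its smallest eigenvalue is 0 for any connected graph.
#'
#' @param g a [rag_tree()].
#' @return an `n x n` symmetric integer matrix with vertex labels as dimnames.
#' @examples
#' laplacian_matrix(rag_tree(c(1, 2)))
#' @export
laplacian_matrix <- function(g) {
  stopifnot(inherits(g, "rag_tree"))
  n <- g$n
  L <- matrix(0L, n, n, dimnames = list(g$vertices, g$vertices))
  ei <- matrix(match(g$edges, g$vertices), ncol = 2L)
  for (k in seq_len(nrow(ei))) {
    i <- ei[k, 1]; j <- ei[k, 2]
    L[i, j] <- L[i, j] - 1L
    L[j, i] <- L[j, i] - 1L
    L[i, i] <- L[i, i] + 1L
    L[j, j] <- L[j, j] + 1L
  }
  L
}

#' Laplacian spectrum and Fiedler pair of a RAG tree
#'
#' Computes the full eigendecomposition of the Laplacian `L = D - A` with a
#' dense symmetric solver. Eigenvalues are returned in ascending order
#' (lambda_1 = 0 <= lambda_2 <= ...); eigenvectors are orthonormal. The
#' second eigenvalue lambda_2 (the algebraic connectivity) is positive for
#' any connected graph and grows with topological compactness; its
#' eigenvector mu_2 (the Fiedler vector) sums to zero and carries the local
#' connectivity information used for spectral bisection.
#'
#' The sign of an eigenvector is arbitrary; `mu2` is oriented so that its
#' first component exceeding `tol` in magnitude is positive, making results
#' reproducible. When lambda_2 is (near-)degenerate — e.g. for star graphs —
#' the eigenvector is not unique up to sign and `degenerate` is set; the
#' flag is propagated into cut results as a reproducibility warning.
#'
#' @param g a [rag_tree()].
#' @param tol tolerance below which a component counts as zero when fixing
#'   the orientation (default 1e-9).
#' @param mult_tol gap below which lambda_2 and lambda_3 are flagged as
#'   degenerate (default 1e-8).
#' @return an object of class `rag_spectrum`: the graph, the Laplacian
#'   `matrix`, ascending `values`, orthonormal `vectors` (columns aligned
#'   with `values`), `lambda2`, the oriented unit-norm `mu2`, and the
#'   `degenerate` flag.
#' @examples
#' sp <- rag_spectrum(rag_example("6_1")$graph)
#' round(sp$lambda2, 2)
#' @export
rag_spectrum <- function(g, tol = 1e-9, mult_tol = 1e-8) {
  stopifnot(inherits(g, "rag_tree"))
  L <- laplacian_matrix(g)
  e <- eigen(L, symmetric = TRUE)
  ord <- rev(seq_len(g$n))          # eigen() returns descending values
  values <- e$values[ord]
  vectors <- e$vectors[, ord, drop = FALSE]
  mu2 <- orient_eigenvector(vectors[, 2], tol = tol)
  vectors[, 2] <- mu2
  structure(
    list(graph = g, matrix = L, values = values, vectors = vectors,
         lambda2 = values[2], mu2 = mu2,
         degenerate = g$n >= 3 && abs(values[3] - values[2]) < mult_tol),
    class = "rag_spectrum"
  )
}

# fix sign so the first component with |v_i| > tol is positive
orient_eigenvector <- function(v, tol = 1e-9) {
  i <- which(abs(v) > tol)
  if (length(i) && v[i[1]] < 0) v <- -v
  v
}

#' Fiedler pair (lambda_2, mu_2)
#'
#' Convenience accessor over [rag_spectrum()].
#'
#' @param g a [rag_tree()].
#' @return list with `lambda2` and the oriented unit-norm Fiedler vector
#'   `mu2` aligned with `g$vertices`.
#' @export
fiedler <- function(g) {
  sp <- rag_spectrum(g)
  list(lambda2 = sp$lambda2, mu2 = sp$mu2)
}

#' @export
print.rag_tree <- function(x, ...) {
  nm <- if (!is.null(x$name)) paste0(" '", x$name, "'") else ""
  cat("<rag_tree", nm, "> ", x$n, " vertices, ", nrow(x$edges), " edges\n", sep = "")
  cat("  vertices: ", paste(x$vertices, collapse = " "), "\n", sep = "")
  cat("  edges:    ",
      paste(paste0(x$edges[, 1], "-", x$edges[, 2]), collapse = " "), "\n", sep = "")
  invisible(x)
}

#' @export
print.rag_spectrum <- function(x, ...) {
  cat("<rag_spectrum> n = ", x$graph$n,
      ", lambda2 = ", format(x$lambda2, digits = 6),
      if (x$degenerate) " (degenerate)" else "", "\n", sep = "")
  cat("  mu2: ", paste(format(round(x$mu2, 3)), collapse = " "), "\n", sep = "")
  invisible(x)
}

#' @export
format.rag_tree <- function(x, ...) {
  paste0(x$n, " vertices: ", paste(paste0(x$edges[, 1], "-", x$edges[, 2]), collapse = " "))
}
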