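#' Label-invariant canonical form of a tree
#'
#' Encodes the tree as a string that is identical for two trees exactly when
#' they are isomorphic: the tree is rooted at its centroid (for bicentroidal
#' trees, at each of the two centroids, keeping the lexicographically
#' smaller string) and encoded recursively with children's encodings sorted
#' (the classic rooted-tree canonical form). Used for catalog membership,
#' deduplication during enumeration, and fragment identification.
#'
#' @param g a [rag_tree()].
#' @return a parenthesis-string canonical form.
#' @examples
#' canonical_form(rag_tree(c(1, 2, 2, 3))) == canonical_form(rag_tree(c(2, 1, 1, 3)))
#' @export
canonical_form <- function(g) {
  stopifnot(inherits(g, "rag_tree"))
  adj <- adjacency_list(g)
  cents <- centroids(adj, g$n)
  enc <- vapply(cents, function(r) ahu_encode(adj, r, 0L), character(1))
  sort(enc, method = "radix")[1]
}

# centroid(s): vertex indices minimizing the largest component left by removal
centroids <- function(adj, n) {
  if (n == 1L) return(1L)
  size <- integer(n)        # subtree sizes rooted at 1
  heaviest <- integer(n)    # largest subtree among children
  order <- integer(0)       # post-order via iterative DFS
  parent <- rep(0L, n)
  stack <- 1L; visited <- logical(n)
  while (length(stack)) {
    v <- stack[length(stack)]
    if (!visited[v]) {
      visited[v] <- TRUE
      for (w in adj[[v]]) if (w != parent[v]) { parent[w] <- v; stack <- c(stack, w) }
    } else {
      stack <- stack[-length(stack)]
      order <- c(order, v)
    }
  }
  for (v in order) {
    size[v] <- 1L
    for (w in adj[[v]]) if (w != parent[v]) {
      size[v] <- size[v] + size[w]
      heaviest[v] <- max(heaviest[v], size[w])
    }
  }
  maxcomp <- pmax(heaviest, n - size)
  which(maxcomp == min(maxcomp))
}

ahu_encode <- function(adj, v, parent) {
  kids <- adj[[v]][adj[[v]] != parent]
  if (!length(kids)) return("()")
  enc <- vapply(kids, function(w) ahu_encode(adj, w, v), character(1))
  paste0("(", paste(sort(enc, method = "radix"), collapse = ""), ")")
}

# ---- enumeration ----------------------------------------------------------

.tree_cache <- new.env(parent = emptyenv())

#' Enumerate non-isomorphic trees on n vertices
#'
#' Produces exactly one representative per isomorphism class, by inductive
#' leaf augmentation: every tree on n vertices arises by attaching a leaf to
#' some tree on n - 1 vertices, so candidates are generated by attaching a
#' new leaf to every vertex of every (n-1)-class representative and
#' deduplicated by [canonical_form()]. Counts match the free-tree sequence
#' 1, 1, 2, 3, 6, 11, 23, 47, 106, 235 for n = 2..11.
#'
#' @param n vertex count, 2..12.
#' @return list of `rag_tree` representatives (labels 1..n), ordered by
#'   canonical form.
#' @examples
#' length(enumerate_trees(6))  # 6 topologies on 6 vertices
#' @export
enumerate_trees <- function(n) {
  n <- as.integer(n)
  if (length(n) != 1L || is.na(n) || n < 2L || n > 12L)
    stop("`n` must be a single integer in 2..12", call. = FALSE)
  key <- as.character(n)
  if (!is.null(.tree_cache[[key]])) return(.tree_cache[[key]])
  if (n == 2L) {
    out <- list(rag_tree(c(1L, 2L), n = 2L))
  } else {
    prev <- enumerate_trees(n - 1L)
    seen <- character(0)
    out <- list()
    for (g in prev) {
      for (v in g$vertices) {
        cand <- rag_tree(rbind(g$edges, c(v, n)), n = n)
        cf <- canonical_form(cand)
        if (!(cf %in% seen)) {
          seen <- c(seen, cf)
          out <- c(out, list(cand))
        }
      }
    }
    out <- out[order(seen, method = "radix")]
  }
  .tree_cache[[key]] <- out
  out
}

#' Assign connectivity-ordered RAG identifiers
#'
#' Sorts one-per-class trees of a common vertex count by ascending algebraic
#' connectivity lambda_2 — the RAG convention in which the subscript ranks
#' topological complexity, from the path (rank 1, least compact) to the star
#' (most compact) — and assigns identifiers `"n_1"`, `"n_2"`, .... Ties in
#' lambda_2 beyond 1e-9 are broken by canonical form so the ordering is
#' deterministic.
#'
#' @param trees list of `rag_tree` with equal vertex counts, one per
#'   isomorphism class.
#' @return a catalog tibble (class `rag_catalog`): `rag_id`, `n`, `k`,
#'   `lambda2`, `canonical`, and a list-column `edges` of representative
#'   edge matrices.
#' @export
assign_rag_ids <- function(trees) {
  stopifnot(length(trees) >= 1L, all(vapply(trees, inherits, logical(1), "rag_tree")))
  ns <- vapply(trees, `[[`, integer(1), "n")
  if (length(unique(ns)) != 1L)
    stop("all trees must have the same vertex count", call. = FALSE)
  lam <- vapply(trees, function(g) rag_spectrum(g)$lambda2, numeric(1))
  can <- vapply(trees, canonical_form, character(1))
  if (anyDuplicated(can)) stop("duplicate topology supplied", call. = FALSE)
  ord <- order(lam)
  # stabilize near-ties (within 1e-9) by canonical string
  i <- 1L
  while (i < length(ord)) {
    j <- i
    while (j < length(ord) && lam[ord[j + 1]] - lam[ord[i]] < 1e-9) j <- j + 1L
    if (j > i) ord[i:j] <- ord[i:j][order(can[ord[i:j]], method = "radix")]
    i <- j + 1L
  }
  out <- tibble::tibble(
    rag_id = paste0(ns[1], "_", seq_along(ord)),
    n = ns[1],
    k = seq_along(ord),
    lambda2 = lam[ord],
    canonical = can[ord],
    edges = lapply(trees[ord], `[[`, "edges")
  )
  class(out) <- c("rag_catalog", class(out))
  out
}

#' Catalog of tree topologies up to a vertex count
#'
#' Enumerates and identifier-orders all tree topologies for each vertex
#' count in `2..n_max`.
#'
#' @param n_max largest vertex count (2..12).
#' @return a catalog tibble, see [assign_rag_ids()].
#' @examples
#' rag_catalog(6)
#' @export
rag_catalog <- function(n_max) {
  n_max <- as.integer(n_max)
  stopifnot(n_max >= 2L, n_max <= 12L)
  out <- dplyr::bind_rows(lapply(2:n_max, function(n) assign_rag_ids(enumerate_trees(n))))
  class(out) <- c("rag_catalog", class(out))
  out
}

#' Identify a graph's topology in a catalog
#'
#' Looks up the isomorphism class of `g` (via [canonical_form()], so the
#' result is invariant under any relabeling of the vertices) and returns its
#' RAG identifier.
#'
#' @param g a [rag_tree()].
#' @param catalog a catalog tibble from [rag_catalog()].
#' @return the `rag_id` string, or `NA_character_` if the topology is absent.
#' @examples
#' identify_graph(rag_example("6_5")$graph, rag_catalog(6))
#' @export
identify_graph <- function(g, catalog) {
  stopifnot(inherits(g, "rag_tree"))
  if (!g$n %in% catalog$n)
    stop("catalog does not cover graphs with ", g$n, " vertices", call. = FALSE)
  cf <- canonical_form(g)
  hit <- which(catalog$n == g$n & catalog$canonical == cf)
  if (length(hit)) catalog$rag_id[hit[1]] else NA_character_
}

#' Write / read a catalog as TSV
#'
#' The edge list is serialized as comma-separated `from-to` tokens so the
#' catalog round-trips through plain text.
#'
#' @param catalog a catalog tibble.
#' @param path file path.
#' @return `write_catalog` returns `path` invisibly; `read_catalog` returns
#'   the catalog tibble.
#' @export
write_catalog <- function(catalog, path) {
  flat <- dplyr::mutate(
    catalog,
    edges = vapply(.data$edges,
                   function(e) paste(paste0(e[, 1], "-", e[, 2]), collapse = ","),
                   character(1))
  )
  utils::write.table(flat, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_catalog
#' @export
read_catalog <- function(path) {
  flat <- utils::read.table(path, sep = "\t", header = TRUE,
                            colClasses = c("character", "integer", "integer",
                                           "numeric", "character", "character"))
  out <- tibble::as_tibble(flat)
  out$edges <- lapply(strsplit(out$edges, ","), function(tok) {
    normalize_edges(matrix(as.integer(unlist(strsplit(tok, "-"))), ncol = 2L, byrow = TRUE))
  })
  class(out) <- c("rag_catalog", class(out))
  out
}
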