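#' Is a graph a minimal RNA module?
#'
#' Minimal modules are the terminal fragments of the iterative
#' decomposition: star graphs, i.e. graphs with at most one vertex of degree
#' two or more. These cover the single edge (a hairpin stem with its loop
#' and dangling end) and the k-leaf star (a k-way junction).
#'
#' @param g a [rag_tree()].
#' @return `TRUE` iff `g` is a star.
#' @examples
#' is_minimal_module(rag_tree(c(1, 2)))                 # hairpin: TRUE
#' is_minimal_module(rag_example("5_2")$graph)          # junction + stem: FALSE
#' @export
is_minimal_module <- function(g) {
  stopifnot(inherits(g, "rag_tree"))
  sum(rag_degree(g) >= 2L) <= 1L
}

#' Iterative gap-cut decomposition of a RAG tree
#'
#' Applies [gap_cut()] plus [extract_fragments()] recursively,
#' breadth-first, until every fragment satisfies the stop predicate
#' (by default [is_minimal_module()]). Fragments keep the parent's vertex
#' labels throughout, so in overlap mode the leaves record exactly which
#' single-stranded elements the assembled modules share. Children of each
#' cut are ordered lexicographically by sorted vertex set, making the
#' partition tree fully deterministic.
#'
#' @param g a [rag_tree()].
#' @param stop_when predicate `function(rag_tree) -> logical`; a fragment
#'   satisfying it becomes a leaf. Use
#'   `catalog_stop(catalog)` to stop at catalog membership instead.
#' @param mode fragment extraction mode, `"overlap"` (default; fragments
#'   share the cut vertex, enabling assembly planning) or `"strict"`.
#' @return an object of class `rag_partition`: `root` (the input graph),
#'   `mode`, `nodes` (a list of records `id`, `parent`, `depth`, `graph`,
#'   `cut`, `shared_vertex`, `children`), `leaf_ids` (left-to-right frontier
#'   order), and `depth`.
#' @examples
#' pt <- decompose_graph(rag_example("6_2")$graph)
#' pt
#' @export
decompose_graph <- function(g, stop_when = is_minimal_module,
                            mode = c("overlap", "strict")) {
  mode <- match.arg(mode)
  stopifnot(inherits(g, "rag_tree"), is.function(stop_when))
  nodes <- list(new_pnode(1L, NA_integer_, 0L, g))
  queue <- 1L
  max_cuts <- g$n  # a tree is exhausted after < n cuts
  cuts <- 0L
  while (length(queue)) {
    id <- queue[1]; queue <- queue[-1]
    gi <- nodes[[id]]$graph
    if (isTRUE(stop_when(gi)) || gi$n < 2L) next
    if (cuts >= max_cuts) stop("decomposition did not terminate", call. = FALSE)
    cut <- gap_cut(gi)
    frags <- extract_fragments(gi, cut, mode = mode)
    cuts <- cuts + 1L
    kid_ids <- length(nodes) + seq_along(frags)
    for (j in seq_along(frags))
      nodes[[kid_ids[j]]] <- new_pnode(kid_ids[j], id, nodes[[id]]$depth + 1L, frags[[j]])
    nodes[[id]]$cut <- cut
    nodes[[id]]$children <- kid_ids
    nodes[[id]]$shared_vertex <- attr(frags, "shared_vertex") %||% NA_integer_
    queue <- c(queue, kid_ids)
  }
  new_rag_partition(g, mode, nodes)
}

new_pnode <- function(id, parent, depth, graph) {
  list(id = id, parent = parent, depth = depth, graph = graph,
       cut = NULL, children = integer(0), shared_vertex = NA_integer_)
}

new_rag_partition <- function(root, mode, nodes) {
  structure(
    list(root = root, mode = mode, nodes = nodes,
         leaf_ids = frontier_ids(nodes),
         depth = max(vapply(nodes, `[[`, integer(1), "depth"))),
    class = "rag_partition"
  )
}

# depth-first left-to-right leaf order
frontier_ids <- function(nodes, id = 1L) {
  kids <- nodes[[id]]$children
  if (!length(kids)) return(id)
  unlist(lapply(kids, function(k) frontier_ids(nodes, k)))
}

#' Leaf fragments of a partition tree
#'
#' @param pt a `rag_partition`.
#' @return list of `rag_tree` leaves in left-to-right frontier order.
#' @export
leaf_modules <- function(pt) {
  stopifnot(inherits(pt, "rag_partition"))
  lapply(pt$nodes[pt$leaf_ids], `[[`, "graph")
}

#' Stop predicate: fragment is an existing catalog topology
#'
#' Returns a predicate for [decompose_graph()] that stops when a fragment's
#' topology appears in the supplied catalog (the operational reading of
#' "until all substructured graphs correspond to existing RNAs" when a
#' census of existing topologies is available).
#'
#' @param catalog a catalog tibble from [rag_catalog()].
#' @return `function(rag_tree) -> logical`.
#' @export
catalog_stop <- function(catalog) {
  force(catalog)
  function(g) g$n %in% catalog$n && !is.na(identify_graph(g, catalog))
}

#' Rebuild a partition tree from recorded splits
#'
#' Replays a sequence of recorded bipartitions instead of computing spectral
#' cuts — used to regression-test the bookkeeping and the overlap
#' augmentation rule against decompositions recorded elsewhere. Each
#' recorded pair must be a bipartition of the vertex set of a current leaf;
#' leaves are matched by vertex-set equality.
#'
#' @param g the root [rag_tree()].
#' @param splits list of two-element lists/vectors: `list(part_a, part_b)`.
#' @param mode extraction mode, default `"overlap"`.
#' @return a `rag_partition`.
#' @examples
#' fx <- rag_example("10_19")
#' pt <- replay_splits(fx$graph, fx$recorded_splits)
#' vapply(leaf_modules(pt), function(g) g$n, integer(1))
#' @export
replay_splits <- function(g, splits, mode = c("overlap", "strict")) {
  mode <- match.arg(mode)
  stopifnot(inherits(g, "rag_tree"))
  nodes <- list(new_pnode(1L, NA_integer_, 0L, g))
  for (sp in splits) {
    pa <- as.integer(sp[[1]]); pb <- as.integer(sp[[2]])
    if (length(intersect(pa, pb)))
      stop("recorded parts overlap: {", paste(intersect(pa, pb), collapse = ","), "}",
           call. = FALSE)
    target <- union(pa, pb)
    leaf <- NULL
    for (id in frontier_ids(nodes))
      if (setequal(nodes[[id]]$graph$vertices, target)) { leaf <- id; break }
    if (is.null(leaf))
      stop("recorded split {", paste(pa, collapse = ","), "}/{",
           paste(pb, collapse = ","), "} matches no current fragment", call. = FALSE)
    gi <- nodes[[leaf]]$graph
    mu2 <- ifelse(gi$vertices %in% pa, -1, 1)  # synthetic components realizing the pair
    cut <- threshold_split(gi, mu2, 0, method = "replay")
    frags <- extract_fragments(gi, cut, mode = mode)
    kid_ids <- length(nodes) + seq_along(frags)
    for (j in seq_along(frags))
      nodes[[kid_ids[j]]] <- new_pnode(kid_ids[j], leaf, nodes[[leaf]]$depth + 1L, frags[[j]])
    nodes[[leaf]]$cut <- cut
    nodes[[leaf]]$children <- kid_ids
    nodes[[leaf]]$shared_vertex <- attr(frags, "shared_vertex") %||% NA_integer_
  }
  new_rag_partition(g, mode, nodes)
}

#' Hierarchical assembly plan from a partition tree
#'
#' Inverts an overlap-mode decomposition: the internal nodes of the
#' partition tree, taken deepest first, become merge steps. Each step joins
#' the two child fragments through their shared vertex (the duplicated
#' endpoint of the cut helix) and yields the parent fragment; executing all
#' steps rebuilds the root graph exactly. The biological reading: junctions
#' are connected to their neighbouring stems first, and the largest modules
#' are joined last.
#'
#' @param pt an overlap-mode `rag_partition`.
#' @param catalog optional catalog tibble from [rag_catalog()]; when
#'   supplied, fragment topologies are identified and reported as RAG IDs.
#' @return a tibble with one row per merge step: `step`, `shared_vertex`,
#'   `left`, `right`, `product` (list-columns of vertex labels), and, with a
#'   catalog, `left_id`, `right_id`, `product_id`.
#' @examples
#' fx <- rag_example("10_19")
#' assembly_plan(replay_splits(fx$graph, fx$recorded_splits))
#' @export
assembly_plan <- function(pt, catalog = NULL) {
  stopifnot(inherits(pt, "rag_partition"))
  if (pt$mode != "overlap")
    stop("assembly planning needs an overlap-mode partition tree ",
         "(strict fragments share no vertex)", call. = FALSE)
  internal <- purrr::keep(pt$nodes, ~ length(.x$children) > 0)
  if (!length(internal)) {
    return(tibble::tibble(step = integer(0), shared_vertex = integer(0),
                          left = list(), right = list(), product = list()))
  }
  # reverse breadth-first = deepest first; ids are assigned in BFS order
  internal <- internal[order(vapply(internal, `[[`, integer(1), "id"),
                             decreasing = TRUE)]
  steps <- purrr::imap(internal, function(nd, k) {
    kids <- pt$nodes[nd$children]
    tibble::tibble(
      step = k,
      shared_vertex = nd$shared_vertex,
      left = list(kids[[1]]$graph$vertices),
      right = list(kids[[2]]$graph$vertices),
      product = list(nd$graph$vertices),
      left_graph = list(kids[[1]]$graph),
      right_graph = list(kids[[2]]$graph),
      product_graph = list(nd$graph)
    )
  })
  plan <- dplyr::bind_rows(steps)
  if (!is.null(catalog)) {
    ident <- function(g) if (g$n %in% catalog$n) identify_graph(g, catalog) else NA_character_
    plan <- dplyr::mutate(
      plan,
      left_id = purrr::map_chr(.data$left_graph, ident),
      right_id = purrr::map_chr(.data$right_graph, ident),
      product_id = purrr::map_chr(.data$product_graph, ident)
    )
  }
  plan
}

#' Execute an assembly plan
#'
#' Merges the leaf fragments of an overlap-mode partition tree step by step
#' (vertex sets united, edge sets disjointly united through the shared
#' vertex) and returns the reconstructed graph. Used to verify the
#' round-trip identity: the reconstruction equals the root label-for-label.
#'
#' @param pt an overlap-mode `rag_partition`.
#' @return the reconstructed `rag_tree`.
#' @export
assemble <- function(pt) {
  stopifnot(inherits(pt, "rag_partition"))
  if (pt$mode != "overlap")
    stop("assembly needs an overlap-mode partition tree", call. = FALSE)
  pool <- lapply(pt$nodes[pt$leaf_ids], `[[`, "graph")
  ids <- pt$leaf_ids
  internal <- purrr::keep(pt$nodes, ~ length(.x$children) > 0)
  internal <- internal[order(vapply(internal, `[[`, integer(1), "id"),
                             decreasing = TRUE)]
  for (nd in internal) {
    sel <- match(nd$children, ids)
    left <- pool[[sel[1]]]; right <- pool[[sel[2]]]
    shared <- intersect(left$vertices, right$vertices)
    if (length(shared) != 1L)
      stop("fragments share ", length(shared), " vertices; expected exactly 1",
           call. = FALSE)
    merged <- new_rag_tree(union(left$vertices, right$vertices),
                           rbind(left$edges, right$edges), name = nd$graph$name)
    pool <- c(pool[-sel], list(merged))
    ids <- c(ids[-sel], nd$id)
  }
  stopifnot(length(pool) == 1L)
  pool[[1]]
}

#' DOT export of a partition tree
#'
#' Renders the binary decomposition as Graphviz DOT source (for
#' documentation figures); nodes are fragments labeled by their vertex sets.
#'
#' @param pt a `rag_partition`.
#' @param path optional file to write to.
#' @return the DOT source as a character string (invisibly when `path` is
#'   given).
#' @export
partition_dot <- function(pt, path = NULL) {
  stopifnot(inherits(pt, "rag_partition"))
  lab <- function(nd) paste0("{", paste(nd$graph$vertices, collapse = ","), "}")
  lines <- c("digraph partition {", "  node [shape=box];")
  for (nd in pt$nodes) {
    lines <- c(lines, sprintf('  n%d [label="%s"];', nd$id, lab(nd)))
    for (k in nd$children) lines <- c(lines, sprintf("  n%d -> n%d;", nd$id, k))
  }
  dot <- paste(c(lines, "}"), collapse = "\n")
  if (!is.null(path)) { writeLines(dot, path); return(invisible(dot)) }
  dot
}

#' @export
print.rag_partition <- function(x, ...) {
  leaves <- leaf_modules(x)
  cat("<rag_partition> mode = ", x$mode, ", depth = ", x$depth,
      ", ", length(leaves), " leaves\n", sep = "")
  for (lf in leaves)
    cat("  leaf {", paste(lf$vertices, collapse = ","), "}\n", sep = "")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
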