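#' Spectral bisection of a RAG tree at a splitting value
#'
#' Splits the vertex set into two disjoint parts using the components
#' nu_i of the Fiedler vector: `part_a = {i : nu_i <= s}` and
#' `part_b = {i : nu_i > s}`. This is the primitive behind the median, sign,
#' and gap cuts. Components exactly equal to `s` fall in `part_a`.
#'
#' @param g a [rag_tree()].
#' @param mu2 Fiedler components aligned with `g$vertices`. Taken as given
#'   (no re-orientation); the named cuts canonicalize orientation before
#'   calling this.
#' @param s splitting value, strictly between `min(mu2)` and `max(mu2)`
#'   (otherwise one part would be empty).
#' @param method label recorded on the result (`"median"`, `"sign"`,
#'   `"gap"`, ...).
#' @param gap_width for the gap cut, the width of the selected gap.
#' @param degenerate logical: lambda_2 was (near-)degenerate, so the cut may
#'   not be reproducible across solvers.
#' @return an object of class `rag_cut` with fields `method`, `s`, `mu2`,
#'   `part_a`, `part_b` (vertex-label sets), `cut_edges` (two-column matrix
#'   of edges with one endpoint in each part), `gap_width`,
#'   `degenerate_warning`, and `multi_cut` (more than one cut edge).
#' @export
threshold_split <- function(g, mu2, s, method = "threshold",
                            gap_width = NA_real_, degenerate = FALSE) {
  stopifnot(inherits(g, "rag_tree"), length(mu2) == g$n)
  in_a <- mu2 <= s
  if (all(in_a) || !any(in_a))
    stop("splitting value s = ", format(s),
         " leaves one part empty; s must lie strictly inside the component range",
         call. = FALSE)
  part_a <- g$vertices[in_a]
  part_b <- g$vertices[!in_a]
  a_has <- matrix(g$edges %in% part_a, ncol = 2L)
  crossing <- xor(a_has[, 1], a_has[, 2])
  cut_edges <- g$edges[crossing, , drop = FALSE]
  structure(
    list(graph = g, method = method, s = s, mu2 = mu2,
         part_a = part_a, part_b = part_b,
         cut_edges = cut_edges, gap_width = gap_width,
         degenerate_warning = degenerate,
         multi_cut = nrow(cut_edges) > 1L),
    class = "rag_cut"
  )
}

cut_spectrum <- function(g, mu2) {
  if (is.null(mu2)) {
    sp <- rag_spectrum(g)
    list(mu2 = sp$mu2, degenerate = sp$degenerate)
  } else {
    stopifnot(length(mu2) == g$n)
    # canonical orientation makes all cuts invariant to the sign of the input
    list(mu2 = orient_eigenvector(mu2), degenerate = FALSE)
  }
}

#' Median, sign, and gap cuts
#'
#' The three spectral bisection rules. Each computes (or accepts) the
#' Fiedler vector, canonicalizes its orientation (first nonzero component
#' positive), picks a splitting value `s`, and applies the membership rule
#' `part_a = {i : nu_i <= s}`:
#'
#' * **median cut** — `s` is the median of the components: for odd n the
#'   central sorted component (which then falls in `part_a`), for even n the
#'   mean of the two central components. Tends to produce two parts of equal
#'   size.
#' * **sign cut** — `s = 0`; negative components are separated from positive
#'   ones, zero components joining the `<= 0` side.
#' * **gap cut** — components are sorted ascending, the difference of every
#'   two neighbours (the "gap") is computed, and `s` is the midpoint of the
#'   largest gap. Ties in gap width (within 1e-9) break toward the gap at
#'   smaller values. Tends to separate topologically distinct subgraphs
#'   (e.g. a junction from a linear stem) and is the rule used for the
#'   iterative decomposition.
#'
#' Since reported parts are unordered pairs and the orientation is
#' canonicalized, all three cuts are invariant under a sign flip of the
#' eigenvector.
#'
#' @param g a [rag_tree()].
#' @param mu2 optional Fiedler components aligned with `g$vertices`;
#'   computed from `g` when omitted.
#' @return a `rag_cut` (see [threshold_split()]); for the gap cut,
#'   `gap_width` records the selected gap.
#' @examples
#' g <- rag_example("6_5")$graph
#' sign_cut(g)$part_b   # the 4-way junction {1,2,3,6}
#' gap_cut(g)$part_a    # the 2-vertex linear arm {4,5}
#' @export
median_cut <- function(g, mu2 = NULL) {
  cs <- cut_spectrum(g, mu2)
  v <- sort(cs$mu2)
  n <- length(v)
  if (max(v) - min(v) < 1e-12)
    stop("all Fiedler components are equal; cannot cut", call. = FALSE)
  s <- if (n %% 2L == 1L) v[(n + 1L) %/% 2L] else mean(v[n / 2 + c(0L, 1L)])
  threshold_split(g, cs$mu2, s, method = "median", degenerate = cs$degenerate)
}

#' @rdname median_cut
#' @export
sign_cut <- function(g, mu2 = NULL) {
  cs <- cut_spectrum(g, mu2)
  threshold_split(g, cs$mu2, 0, method = "sign", degenerate = cs$degenerate)
}

#' @rdname median_cut
#' @export
gap_cut <- function(g, mu2 = NULL) {
  cs <- cut_spectrum(g, mu2)
  v <- sort(cs$mu2)
  gaps <- diff(v)
  k <- which(gaps > max(gaps) - 1e-9)[1]   # tie -> gap at smaller values
  s <- (v[k] + v[k + 1]) / 2
  threshold_split(g, cs$mu2, s, method = "gap",
                  gap_width = gaps[k], degenerate = cs$degenerate)
}

#' Extract the fragment subgraphs of a cut
#'
#' Turns a bisection into RNA-module subgraphs, preserving the parent's
#' vertex labels.
#'
#' * **strict** mode drops the cut edges and returns the induced subgraph of
#'   each part. If a part is internally disconnected (possible for median
#'   cuts of branched trees, where several edges cross the cut), its
#'   connected components are returned with a multi-cut warning.
#' * **overlap** mode models the biological situation in which the cut helix
#'   belongs to one of the two modules: the single cut edge is retained in
#'   exactly one fragment together with a duplicate of its opposite
#'   endpoint, so the two fragments share exactly one vertex and their edge
#'   sets partition the parent's edge set. Which side keeps the helix is
#'   decided by the augmentation rule: (i) a side whose induced subgraph has
#'   no edge is augmented (it would otherwise not be a graph); (ii)
#'   otherwise the side whose cut endpoint has the higher degree in the
#'   parent; (iii) on ties, the side containing the parent's maximum-degree
#'   vertex; (iv) on further ties, the side containing the smallest label.
#'   Overlap mode refuses cuts with more than one cut edge, where the
#'   shared-vertex semantics is undefined.
#'
#' @param g the parent [rag_tree()].
#' @param cut a `rag_cut` produced from `g`.
#' @param mode `"overlap"` (default, used by the iterative decomposition) or
#'   `"strict"`.
#' @return a list of `rag_tree` fragments (two in overlap mode; two or more
#'   in strict mode if the cut severs several edges), ordered
#'   lexicographically by sorted vertex set, with attribute
#'   `"shared_vertex"` in overlap mode.
#' @examples
#' g <- rag_example("6_2")$graph
#' extract_fragments(g, gap_cut(g), mode = "strict")
#' @export
extract_fragments <- function(g, cut, mode = c("overlap", "strict")) {
  mode <- match.arg(mode)
  stopifnot(inherits(g, "rag_tree"), inherits(cut, "rag_cut"))
  parts <- list(cut$part_a, cut$part_b)
  induced <- lapply(parts, function(p) {
    keep <- matrix(g$edges %in% p, ncol = 2L)
    g$edges[keep[, 1] & keep[, 2], , drop = FALSE]
  })

  if (mode == "strict") {
    frags <- list()
    for (i in 1:2) {
      comps <- connected_components(parts[[i]], induced[[i]])
      if (length(comps) > 1L)
        warning("multi-edge cut: part {", paste(parts[[i]], collapse = ","),
                "} is disconnected; returning its connected components",
                call. = FALSE)
      for (cm in comps) {
        keep <- matrix(induced[[i]] %in% cm, ncol = 2L)
        frags <- c(frags, list(fragment_tree(cm, induced[[i]][keep[, 1] & keep[, 2], ,
                                                              drop = FALSE], g$name)))
      }
    }
    return(order_fragments(frags))
  }

  if (cut$multi_cut)
    stop("overlap extraction needs a single cut edge; this cut severs ",
         nrow(cut$cut_edges), call. = FALSE)
  u <- unname(cut$cut_edges[1, 1]); v <- unname(cut$cut_edges[1, 2])
  end_a <- if (u %in% parts[[1]]) u else v    # cut endpoint inside part_a
  end_b <- if (end_a == u) v else u
  aug <- overlap_side(g, parts, induced, end_a, end_b)
  other <- 3L - aug
  ends <- c(end_a, end_b)
  frags <- vector("list", 2L)
  frags[[aug]] <- fragment_tree(c(parts[[aug]], ends[other]),
                                rbind(induced[[aug]], cut$cut_edges), g$name)
  frags[[other]] <- fragment_tree(parts[[other]], induced[[other]], g$name)
  frags <- order_fragments(frags)
  attr(frags, "shared_vertex") <- ends[other]
  frags
}

# which side (1 = part_a, 2 = part_b) keeps the cut edge
overlap_side <- function(g, parts, induced, end_a, end_b) {
  empty <- vapply(induced, nrow, integer(1)) == 0L
  if (xor(empty[1], empty[2])) return(which(empty))
  deg <- rag_degree(g)
  da <- deg[as.character(end_a)]; db <- deg[as.character(end_b)]
  if (da != db) return(if (da > db) 1L else 2L)
  mx <- g$vertices[deg == max(deg)]
  in_a <- mx %in% parts[[1]]
  if (all(in_a)) return(1L)
  if (!any(in_a)) return(2L)
  if (min(g$vertices) %in% parts[[1]]) 1L else 2L
}

fragment_tree <- function(vertices, edges, name = NULL) {
  if (length(vertices) == 1L) {
    # single isolated vertex (strict mode only): not a valid tree; keep as a
    # degenerate record so bookkeeping can report it
    return(structure(list(n = 1L, vertices = as.integer(vertices),
                          edges = normalize_edges(matrix(integer(0), ncol = 2L)),
                          name = name),
                     class = "rag_tree"))
  }
  new_rag_tree(vertices, edges, name = name)
}

order_fragments <- function(frags) {
  keys <- vapply(frags, function(f) paste(sprintf("%09d", f$vertices), collapse = ""),
                 character(1))
  frags[order(keys)]
}

#' @export
print.rag_cut <- function(x, ...) {
  cat("<rag_cut> method = ", x$method, ", s = ", format(x$s, digits = 4), "\n", sep = "")
  cat("  parts: {", paste(x$part_a, collapse = ","), "} / {",
      paste(x$part_b, collapse = ","), "}\n", sep = "")
  if (nrow(x$cut_edges))
    cat("  cut edges: ",
        paste(paste0(x$cut_edges[, 1], "-", x$cut_edges[, 2]), collapse = " "), "\n", sep = "")
  if (!is.na(x$gap_width)) cat("  gap width: ", format(x$gap_width, digits = 4), "\n", sep = "")
  if (x$degenerate_warning)
    cat("  warning: lambda2 is degenerate; cut may not be reproducible\n")
  invisible(x)
}

# unordered comparison helper used in tests and identification
same_partition <- function(cut, set1, set2) {
  (setequal(cut$part_a, set1) && setequal(cut$part_b, set2)) ||
    (setequal(cut$part_a, set2) && setequal(cut$part_b, set1))
}
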