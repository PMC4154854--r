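#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL

#' Tidy a Laplacian spectrum
#'
#' @param x a [rag_spectrum()].
#' @param ... unused.
#' @return `tidy()`: a tibble with one row per vertex (`vertex`, `degree`,
#'   `mu2`); `glance()`: a one-row tibble with `n`, `n_edges`, `lambda2`,
#'   `degenerate`.
#' @export
tidy.rag_spectrum <- function(x, ...) {
  tibble::tibble(vertex = x$graph$vertices,
                 degree = unname(rag_degree(x$graph)),
                 mu2 = x$mu2)
}

#' @rdname tidy.rag_spectrum
#' @export
glance.rag_spectrum <- function(x, ...) {
  tibble::tibble(n = x$graph$n, n_edges = nrow(x$graph$edges),
                 lambda2 = x$lambda2, degenerate = x$degenerate)
}

#' Tidy a spectral cut
#'
#' @param x a `rag_cut` from [median_cut()], [sign_cut()], [gap_cut()], or
#'   [threshold_split()].
#' @param ... unused.
#' @return `tidy()`: one row per vertex with its Fiedler component and part
#'   membership; `glance()`: one row with `method`, `s`, `gap_width`,
#'   `n_cut_edges`, `multi_cut`, `degenerate_warning`.
#' @export
tidy.rag_cut <- function(x, ...) {
  tibble::tibble(vertex = x$graph$vertices,
                 mu2 = x$mu2,
                 part = ifelse(x$graph$vertices %in% x$part_a, "a", "b"))
}

#' @rdname tidy.rag_cut
#' @export
glance.rag_cut <- function(x, ...) {
  tibble::tibble(method = x$method, s = x$s, gap_width = x$gap_width,
                 n_cut_edges = nrow(x$cut_edges), multi_cut = x$multi_cut,
                 degenerate_warning = x$degenerate_warning)
}

#' Tidy a partition tree
#'
#' @param x a `rag_partition` from [decompose_graph()] or [replay_splits()].
#' @param ... unused.
#' @return `tidy()`: one row per node (`id`, `parent`, `depth`, `is_leaf`,
#'   `n_vertices`, `shared_vertex`, list-column `vertices`); `glance()`: one
#'   row with `mode`, `depth`, `n_nodes`, `n_leaves`.
#' @export
tidy.rag_partition <- function(x, ...) {
  tibble::tibble(
    id = vapply(x$nodes, `[[`, integer(1), "id"),
    parent = vapply(x$nodes, `[[`, integer(1), "parent"),
    depth = vapply(x$nodes, `[[`, integer(1), "depth"),
    is_leaf = vapply(x$nodes, function(nd) length(nd$children) == 0L, logical(1)),
    n_vertices = vapply(x$nodes, function(nd) nd$graph$n, integer(1)),
    shared_vertex = vapply(x$nodes, `[[`, integer(1), "shared_vertex"),
    vertices = lapply(x$nodes, function(nd) nd$graph$vertices)
  )
}

#' @rdname tidy.rag_partition
#' @export
glance.rag_partition <- function(x, ...) {
  tibble::tibble(mode = x$mode, depth = x$depth, n_nodes = length(x$nodes),
                 n_leaves = length(x$leaf_ids))
}

#' Plot Fiedler components of a spectrum or cut
#'
#' For a spectrum, plots the Fiedler component of each vertex in 5'-to-3'
#' label order, colored by sign. For a cut, plots the sorted components with
#' the splitting value `s` as a horizontal line, colored by part — the
#' visual form of the median/sign/gap rules. For a partition tree, draws the
#' binary decomposition with fragments as labeled nodes.
#'
#' @param object a `rag_spectrum`, `rag_cut`, or `rag_partition`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.rag_spectrum <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$vertex), y = .data$mu2,
                                   fill = .data$mu2 > 0)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::labs(
      x = "vertex (5' to 3')", y = expression(mu[2]~component),
      title = sprintf("lambda2 = %.3f%s", object$lambda2,
                      if (object$degenerate) " (degenerate)" else "")) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.rag_spectrum
#' @export
autoplot.rag_cut <- function(object, ...) {
  df <- tidy(object)
  df <- df[order(df$mu2), ]
  df$rank <- seq_len(nrow(df))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rank, y = .data$mu2,
                                   color = .data$part)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_hline(yintercept = object$s, linetype = 2) +
    ggplot2::scale_x_continuous(breaks = df$rank, labels = df$vertex) +
    ggplot2::labs(x = "vertex, sorted by component", y = expression(nu[i]),
                  color = "part",
                  title = sprintf("%s cut, s = %.3f", object$method, object$s)) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.rag_spectrum
#' @export
autoplot.rag_partition <- function(object, ...) {
  nodes <- tidy(object)
  # x = mean leaf rank below each node
  leaf_rank <- stats::setNames(seq_along(object$leaf_ids), object$leaf_ids)
  xpos <- numeric(nrow(nodes))
  for (id in rev(nodes$id)) {
    kids <- which(nodes$parent == id)
    xpos[id] <- if (length(kids)) mean(xpos[nodes$id[kids]])
                else leaf_rank[[as.character(id)]]
  }
  nodes$x <- xpos
  nodes$label <- vapply(nodes$vertices, function(v) paste(v, collapse = ","), character(1))
  seg <- nodes[!is.na(nodes$parent), ]
  seg$px <- nodes$x[seg$parent]
  seg$pd <- nodes$depth[seg$parent]
  ggplot2::ggplot(nodes, ggplot2::aes(x = .data$x, y = -.data$depth)) +
    ggplot2::geom_segment(data = seg,
                          ggplot2::aes(xend = .data$px, yend = -.data$pd)) +
    ggplot2::geom_label(ggplot2::aes(label = .data$label), size = 3) +
    ggplot2::labs(x = NULL, y = "depth",
                  title = sprintf("%s-mode decomposition", object$mode)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}
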