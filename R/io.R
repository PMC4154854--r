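#' Read and write edge-list files
#'
#' Plain-text edge lists: one edge per line as two whitespace-separated
#' 1-based integer labels; lines starting with `#` are comments; an optional
#' header line `n=<int>` fixes the vertex count (otherwise the maximum label
#' is used).
#'
#' @param path file path.
#' @param name optional graph name to attach.
#' @return `read_edgelist` returns a [rag_tree()]; `write_edgelist` returns
#'   `path` invisibly.
#' @export
read_edgelist <- function(path, name = NULL) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  n <- NULL
  is_header <- grepl("^n\\s*=\\s*[0-9]+$", lines)
  if (any(is_header)) {
    n <- as.integer(sub("^n\\s*=\\s*", "", lines[which(is_header)[1]]))
    lines <- lines[!is_header]
  }
  if (!length(lines)) stop("no edges in ", path, call. = FALSE)
  tok <- strsplit(lines, "\\s+")
  if (!all(lengths(tok) == 2L))
    stop("each edge line must contain exactly two labels", call. = FALSE)
  em <- matrix(as.integer(unlist(tok)), ncol = 2L, byrow = TRUE)
  rag_tree(em, n = n, name = name)
}

#' @rdname read_edgelist
#' @param g a [rag_tree()].
#' @export
write_edgelist <- function(g, path) {
  stopifnot(inherits(g, "rag_tree"))
  lines <- c(if (!is.null(g$name)) paste("#", g$name),
             paste0("n=", max(g$vertices)),
             paste(g$edges[, 1], g$edges[, 2]))
  writeLines(lines, path)
  invisible(path)
}
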