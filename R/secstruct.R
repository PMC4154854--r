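#' Parse an RNA secondary structure
#'
#' Reads a pseudoknot-free secondary structure from dot-bracket, CT, or
#' BPSEQ text. Dot-bracket supports `()` pairs only (tree graphs need no
#' higher bracket orders); CT and BPSEQ follow their standard 1-based column
#' layouts. Any crossing pair — including higher-order brackets such as
#' `[]` — raises an explicit pseudoknot error naming the crossing pairs,
#' since the tree-graph representation is limited to pseudoknot-free
#' structures.
#'
#' @param x a file path, or the text itself (a single string possibly with
#'   newlines, or a character vector of lines).
#' @param format one of `"dotbracket"`, `"ct"`, `"bpseq"`.
#' @return an object of class `rag_ss`: `sequence` (residue letters or
#'   `NULL`), `pairs` (two-column matrix of 1-based indices, i < j), and
#'   `length` (residue count).
#' @examples
#' parse_structure("((((....))))")
#' @export
parse_structure <- function(x, format = c("dotbracket", "ct", "bpseq")) {
  format <- match.arg(format)
  lines <- structure_lines(x)
  ss <- switch(format,
               dotbracket = parse_dotbracket(lines),
               ct = parse_ct(lines),
               bpseq = parse_bpseq(lines))
  check_pairs(ss)
  ss
}

structure_lines <- function(x) {
  if (length(x) == 1L && !grepl("\n", x) && file.exists(x)) x <- readLines(x)
  x <- unlist(strsplit(x, "\n"))
  x[nzchar(trimws(x))]
}

new_rag_ss <- function(pairs, length, sequence = NULL) {
  pairs <- if (length(pairs)) {
    pm <- matrix(as.integer(pairs), ncol = 2L)
    pm <- cbind(pmin(pm[, 1], pm[, 2]), pmax(pm[, 1], pm[, 2]))
    pm[order(pm[, 1]), , drop = FALSE]
  } else matrix(integer(0), ncol = 2L)
  structure(list(sequence = sequence, pairs = pairs, length = as.integer(length)),
            class = "rag_ss")
}

check_pairs <- function(ss) {
  p <- ss$pairs
  if (!nrow(p)) return(invisible(ss))
  if (any(p < 1L | p > ss$length))
    stop("paired index outside 1..", ss$length, call. = FALSE)
  if (anyDuplicated(as.vector(p)))
    stop("a residue participates in more than one base pair", call. = FALSE)
  for (a in seq_len(nrow(p))) for (b in seq_len(nrow(p))) {
    if (p[a, 1] < p[b, 1] && p[b, 1] < p[a, 2] && p[a, 2] < p[b, 2])
      stop("pseudoknot: pairs (", p[a, 1], ",", p[a, 2], ") and (",
           p[b, 1], ",", p[b, 2], ") cross", call. = FALSE)
  }
  invisible(ss)
}

parse_dotbracket <- function(lines) {
  lines <- lines[!startsWith(trimws(lines), ">")]
  lines <- vapply(lines, trimws, character(1), USE.NAMES = FALSE)
  is_struct <- grepl("^[()\\[\\]{}<>.]+$", lines, perl = TRUE)
  is_seq <- grepl("^[A-Za-z]+$", lines)
  struct <- lines[is_struct & !is_seq]
  if (length(struct) != 1L)
    stop("expected exactly one dot-bracket structure line", call. = FALSE)
  seq <- if (any(is_seq)) toupper(lines[is_seq][1]) else NULL
  ch <- strsplit(struct, "")[[1]]
  if (any(ch %in% c("[", "]", "{", "}", "<", ">"))) {
    stop("pseudoknot: higher-order brackets ('[', '{', '<') are not representable ",
         "as a tree graph", call. = FALSE)
  }
  stack <- integer(0)
  pairs <- matrix(integer(0), ncol = 2L)
  for (i in seq_along(ch)) {
    if (ch[i] == "(") stack <- c(stack, i)
    else if (ch[i] == ")") {
      if (!length(stack)) stop("unbalanced brackets: unmatched ')' at position ", i,
                               call. = FALSE)
      pairs <- rbind(pairs, c(stack[length(stack)], i))
      stack <- stack[-length(stack)]
    }
  }
  if (length(stack)) stop("unbalanced brackets: unmatched '(' at position ",
                          stack[length(stack)], call. = FALSE)
  if (!is.null(seq) && nchar(seq) != length(ch))
    stop("sequence and structure lengths differ", call. = FALSE)
  new_rag_ss(pairs, length(ch), seq)
}

parse_ct <- function(lines) {
  header <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  n <- suppressWarnings(as.integer(header[1]))
  if (is.na(n)) stop("CT header must start with the residue count", call. = FALSE)
  body <- lines[-1]
  if (length(body) < n) stop("CT file truncated: expected ", n, " residue lines",
                             call. = FALSE)
  fields <- strsplit(trimws(body[seq_len(n)]), "\\s+")
  idx <- vapply(fields, function(f) as.integer(f[1]), integer(1))
  base <- vapply(fields, `[`, character(1), 2)
  pair <- vapply(fields, function(f) as.integer(f[5]), integer(1))
  if (!identical(idx, seq_len(n))) stop("CT indices must run 1..n", call. = FALSE)
  ct_bpseq_pairs(pair, n, toupper(paste(base, collapse = "")), "CT")
}

parse_bpseq <- function(lines) {
  lines <- lines[!startsWith(trimws(lines), "#")]
  fields <- strsplit(trimws(lines), "\\s+")
  if (!all(lengths(fields) == 3L))
    stop("BPSEQ lines must have three columns: index base pair", call. = FALSE)
  idx <- vapply(fields, function(f) as.integer(f[1]), integer(1))
  base <- vapply(fields, `[`, character(1), 2)
  pair <- vapply(fields, function(f) as.integer(f[3]), integer(1))
  n <- length(idx)
  if (!identical(idx, seq_len(n))) stop("BPSEQ indices must run 1..n", call. = FALSE)
  ct_bpseq_pairs(pair, n, toupper(paste(base, collapse = "")), "BPSEQ")
}

ct_bpseq_pairs <- function(pair, n, seq, what) {
  if (any(pair < 0L | pair > n)) stop(what, " pair column out of range", call. = FALSE)
  has <- which(pair > 0L)
  bad <- has[pair[pair[has]] != has]
  if (length(bad))
    stop(what, " pair columns inconsistent at residue ", bad[1],
         ": ", bad[1], " -> ", pair[bad[1]], " but ", pair[bad[1]], " -> ",
         pair[pair[bad[1]]], call. = FALSE)
  keep <- has[has < pair[has]]
  new_rag_ss(cbind(keep, pair[keep]), n, if (nzchar(seq)) seq else NULL)
}

#' Render a structure back to dot-bracket
#'
#' @param ss a [parse_structure()] result.
#' @return a dot-bracket string.
#' @export
to_dotbracket <- function(ss) {
  stopifnot(inherits(ss, "rag_ss"))
  ch <- rep(".", ss$length)
  ch[ss$pairs[, 1]] <- "("
  ch[ss$pairs[, 2]] <- ")"
  paste(ch, collapse = "")
}

# ---- helices ---------------------------------------------------------------

#' Find helices (edge-generating stems)
#'
#' A helix is a double-stranded stem with more than one base pair. Maximal
#' runs of stacked pairs ((i,j), (i+1,j-1), ...) are located, then:
#'
#' * runs separated only by a single-residue bulge on one strand are merged
#'   into one stem — a lone unmatched nucleotide does not qualify as a
#'   vertex-generating bulge (a bulge needs more than one unmatched
#'   nucleotide or one unstable base pair);
#' * when the sequence is available, annotated pairs that are not
#'   Watson-Crick or wobble (AU, GC, GU) are treated as unpaired first (the
#'   operational reading of "one unstable base pair" interrupting a stem);
#' * merged stems with fewer than two pairs in total (isolated pairs) are
#'   discarded and their residues treated as unpaired.
#'
#' @param ss a [parse_structure()] result.
#' @return list of helices; each has `pairs` (matrix), `outer` and `inner`
#'   closing pairs, and `npairs`.
#' @examples
#' length(find_helices(parse_structure("((.((....))))")))  # merged: one stem
#' @export
find_helices <- function(ss) {
  stopifnot(inherits(ss, "rag_ss"))
  p <- ss$pairs
  if (!is.null(ss$sequence)) {
    letters2 <- function(k) {
      a <- substr(ss$sequence, p[k, 1], p[k, 1])
      b <- substr(ss$sequence, p[k, 2], p[k, 2])
      a <- sub("T", "U", a); b <- sub("T", "U", b)
      paste0(sort(c(a, b)), collapse = "")
    }
    if (nrow(p)) {
      ok <- vapply(seq_len(nrow(p)), function(k) letters2(k) %in% c("AU", "CG", "GU"),
                   logical(1))
      p <- p[ok, , drop = FALSE]
    }
  }
  if (!nrow(p)) return(list())
  p <- p[order(p[, 1]), , drop = FALSE]
  # maximal stacked runs
  runs <- list(); cur <- p[1, , drop = FALSE]
  for (k in seq_len(nrow(p))[-1]) {
    last <- cur[nrow(cur), ]
    if (p[k, 1] == last[1] + 1L && p[k, 2] == last[2] - 1L) {
      cur <- rbind(cur, p[k, ])
    } else {
      runs <- c(runs, list(cur)); cur <- p[k, , drop = FALSE]
    }
  }
  runs <- c(runs, list(cur))
  # merge across 1x0 / 0x1 bulges: run B directly nested in run A with a
  # single unmatched residue on exactly one strand
  merged <- merge_stems(runs)
  merged <- merged[vapply(merged, function(m) sum(vapply(m, nrow, integer(1))), integer(1)) >= 2L]
  lapply(merged, function(m) {
    pm <- do.call(rbind, m)
    pm <- pm[order(pm[, 1]), , drop = FALSE]
    list(pairs = pm, outer = pm[1, ], inner = pm[nrow(pm), ], npairs = nrow(pm))
  })
}

merge_stems <- function(runs) {
  k <- length(runs)
  follows <- function(a, b) {   # b directly nested in a across a 1-nt bulge
    ia <- a[nrow(a), ]; ob <- b[1, ]
    (ob[1] == ia[1] + 2L && ob[2] == ia[2] - 1L) ||
      (ob[1] == ia[1] + 1L && ob[2] == ia[2] - 2L)
  }
  parent <- seq_len(k)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  if (k > 1) for (a in seq_len(k)) for (b in seq_len(k)) {
    if (a != b && follows(runs[[a]], runs[[b]])) parent[find(b)] <- find(a)
  }
  groups <- unname(split(seq_len(k), vapply(seq_len(k), find, integer(1))))
  lapply(groups, function(ix) runs[ix])
}

# ---- elements and conversion ----------------------------------------------

# nesting: parent of each helix = tightest enclosing helix (0 = exterior)
helix_parents <- function(helices) {
  h <- length(helices)
  parent_of <- integer(h)
  if (h) for (i in seq_len(h)) {
    best <- 0L; span <- Inf
    for (j in seq_len(h)) {
      if (i == j) next
      if (helices[[j]]$inner[1] < helices[[i]]$outer[1] &&
          helices[[i]]$outer[2] < helices[[j]]$inner[2]) {
        w <- helices[[j]]$inner[2] - helices[[j]]$inner[1]
        if (w < span) { span <- w; best <- j }
      }
    }
    parent_of[i] <- best
  }
  parent_of
}

#' Classify vertex-generating structural elements
#'
#' Every helix generates an edge; every other region generates exactly one
#' vertex: the 5'/3' exterior strand (always one element, even with no
#' unpaired exterior residues — a lone hairpin is the two-vertex graph),
#' and, per helix, the loop it closes — a hairpin loop (no inner helices),
#' an internal loop or qualifying bulge (one inner helix), or a k-way
#' junction (two or more inner helices).
#'
#' @param ss a [parse_structure()] result.
#' @param helices from [find_helices()]; recomputed when omitted.
#' @return a tibble: `vertex` (1-based 5'-to-3' label), `kind`, `first_pos`
#'   (ordering key), `n_unpaired`, and `residues` (list-column of unpaired
#'   residue indices in the element).
#' @export
classify_elements <- function(ss, helices = NULL) {
  stopifnot(inherits(ss, "rag_ss"))
  helices <- helices %||% find_helices(ss)
  h <- length(helices)
  parent_of <- helix_parents(helices)
  helix_res <- if (h) sort(unlist(lapply(helices, function(x) as.vector(x$pairs)))) else integer(0)
  children <- function(i) which(parent_of == i)
  region_unpaired <- function(lo, hi, kids) {
    if (hi < lo) return(integer(0))
    res <- lo:hi
    for (kk in kids) res <- setdiff(res, helices[[kk]]$outer[1]:helices[[kk]]$outer[2])
    setdiff(res, helix_res)
  }
  rows <- list()
  ext_kids <- which(parent_of == 0L)
  rows[[1]] <- list(kind = "exterior", first_pos = 0,
                    residues = region_unpaired(1L, ss$length, ext_kids))
  if (h) for (i in seq_len(h)) {
    kids <- children(i)
    kind <- if (length(kids) == 0L) "hairpin_loop"
            else if (length(kids) == 1L) "internal_or_bulge"
            else "junction"
    rows[[length(rows) + 1]] <- list(
      kind = kind, first_pos = helices[[i]]$inner[1], helix = i,
      residues = region_unpaired(helices[[i]]$inner[1] + 1L,
                                 helices[[i]]$inner[2] - 1L, kids))
  }
  ord <- order(vapply(rows, `[[`, numeric(1), "first_pos"))
  rows <- rows[ord]
  tibble::tibble(
    vertex = seq_along(rows),
    kind = vapply(rows, `[[`, character(1), "kind"),
    first_pos = vapply(rows, `[[`, numeric(1), "first_pos"),
    n_unpaired = vapply(rows, function(r) length(r$residues), integer(1)),
    residues = lapply(rows, `[[`, "residues"),
    helix = vapply(rows, function(r) r$helix %||% NA_integer_, integer(1))
  )
}

#' Convert a secondary structure to its RAG tree graph
#'
#' Applies the RNA-As-Graphs rules: helices (stems of more than one base
#' pair, after bulge merging — see [find_helices()]) become edges;
#' single-stranded elements (hairpin loops, qualifying internal
#' loops/bulges, junctions, and the exterior strand) become vertices,
#' numbered in 5'-to-3' order of each element's first residue. Each helix
#' joins the element containing its outer closing pair to the loop it
#' closes. Nested structures always yield a tree.
#'
#' @param ss a [parse_structure()] result, or text accepted by
#'   [parse_structure()] (dot-bracket assumed).
#' @return a [rag_tree()].
#' @examples
#' to_rag_tree("((((....))))")  # hairpin + dangling end: the 2-vertex graph
#' @export
to_rag_tree <- function(ss) {
  if (!inherits(ss, "rag_ss")) ss <- parse_structure(ss, "dotbracket")
  helices <- find_helices(ss)
  if (!length(helices))
    stop("structure has no helix (no stem with more than one base pair); ",
         "no graph to build", call. = FALSE)
  el <- classify_elements(ss, helices)
  # vertex of the loop closed by helix i, and of the region containing it
  loop_vertex <- function(i) el$vertex[match(i, el$helix)]
  h <- length(helices)
  parent_of <- helix_parents(helices)
  ext_vertex <- el$vertex[el$kind == "exterior"]
  edges <- t(vapply(seq_len(h), function(i) {
    up <- if (parent_of[i] == 0L) ext_vertex else loop_vertex(parent_of[i])
    c(up, loop_vertex(i))
  }, integer(2)))
  rag_tree(edges, n = nrow(el))
}

#' @export
print.rag_ss <- function(x, ...) {
  cat("<rag_ss> ", x$length, " residues, ", nrow(x$pairs), " base pairs\n", sep = "")
  cat("  ", to_dotbracket(x), "\n", sep = "")
  if (!is.null(x$sequence)) cat("  ", x$sequence, "\n", sep = "")
  invisible(x)
}
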