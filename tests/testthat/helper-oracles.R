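# Shared fixtures-in-code and independent oracles for the test suite.

path_graph <- function(n) rag_tree(cbind(1:(n - 1), 2:n), n = n)
star_graph <- function(n) rag_tree(cbind(1L, 2:n), n = n)

# Independent lambda2 oracle: bisection on the characteristic polynomial of
# L - lambda I via Sylvester inertia (the number of negative pivots of the
# symmetric elimination equals the number of eigenvalues below lambda).
# Never touches eigen().
lambda2_bisect <- function(g, tol = 1e-10) {
  L <- laplacian_matrix(g)
  n <- nrow(L)
  count_below <- function(lam) {
    A <- L - diag(lam, n)
    neg <- 0L
    for (k in seq_len(n)) {
      d <- A[k, k]
      if (abs(d) < 1e-12) return(count_below(lam + 1e-9))
      if (d < 0) neg <- neg + 1L
      if (k < n) {
        rng <- (k + 1):n
        A[rng, rng] <- A[rng, rng] - tcrossprod(A[rng, k]) / d
      }
    }
    neg
  }
  lo <- 1e-9                      # above lambda1 = 0
  hi <- 2 * max(diag(L)) + 1      # Gershgorin bound
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (count_below(mid) >= 2L) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}

# Exhaustive labeled-tree generation from every Prufer sequence (feasible
# n <= 7); returns the list of rag_tree objects.
all_prufer_trees <- function(n) {
  if (n == 2) return(list(rag_tree(c(1, 2))))
  seqs <- as.matrix(do.call(expand.grid, rep(list(seq_len(n)), n - 2)))
  lapply(seq_len(nrow(seqs)), function(i) prufer_to_tree(seqs[i, ], n))
}

# Brute-force isomorphism by trying every vertex permutation (n <= 7).
iso_brute <- function(g1, g2) {
  if (g1$n != g2$n) return(FALSE)
  key <- function(em) paste(sort(paste(pmin(em[, 1], em[, 2]),
                                       pmax(em[, 1], em[, 2]))), collapse = ";")
  e2 <- key(g2$edges)
  perms <- function(v) if (length(v) == 1) list(v) else
    do.call(c, lapply(seq_along(v), function(i)
      lapply(perms(v[-i]), function(p) c(v[i], p))))
  for (p in perms(seq_len(g1$n))) {
    em <- matrix(p[g1$edges], ncol = 2)
    if (key(em) == e2) return(TRUE)
  }
  FALSE
}

# Random pseudoknot-free dot-bracket structure: recursive composition of
# helices (2-3 stacked pairs) over loops with >= 2 unpaired residues, so no
# bulge merging kicks in and helices map 1:1 to edges.
random_nested_db <- function(depth = 3) {
  dots <- function(lo, hi) strrep(".", sample(lo:hi, 1))
  elem <- function(d) {
    k <- if (d <= 0) 0L else sample(0:3, 1, prob = c(0.25, 0.4, 0.2, 0.15))
    if (k == 0L) return(dots(3, 5))
    kids <- replicate(k, helix(d - 1))
    paste0(dots(2, 3), paste(kids, collapse = dots(2, 3)), dots(2, 3))
  }
  helix <- function(d) {
    h <- sample(2:3, 1)
    paste0(strrep("(", h), elem(d), strrep(")", h))
  }
  repeat {
    s <- elem(depth)
    if (grepl("\\(", s)) return(s)
  }
}

# unordered comparison of a cut against two vertex sets
same_pair <- function(cut, s1, s2) ragcut:::same_partition(cut, s1, s2)

partition_pair <- function(cut) {
  p <- list(sort(cut$part_a), sort(cut$part_b))
  p[order(vapply(p, function(v) paste(sprintf("%09d", v), collapse = ""), character(1)))]
}
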