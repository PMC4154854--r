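test_that("minimal modules are exactly the stars", {
  expect_true(is_minimal_module(rag_tree(c(1, 2))))          # hairpin module
  expect_true(is_minimal_module(star_graph(4)))              # 3-way junction
  expect_true(is_minimal_module(star_graph(6)))              # 5-way junction
  expect_true(is_minimal_module(path_graph(3)))              # P3 is a 2-star
  expect_false(is_minimal_module(rag_example("5_2")$graph))  # junction + stem
  expect_false(is_minimal_module(path_graph(4)))
})

test_that("decomposition stops immediately on minimal modules", {
  pt <- decompose_graph(rag_tree(c(1, 2)))
  expect_equal(pt$depth, 0)
  expect_length(leaf_modules(pt), 1)
  expect_equal(nrow(assembly_plan(pt)), 0)
})

test_that("decomposing P4 gives one cut into two hairpin modules", {
  pt <- decompose_graph(path_graph(4), mode = "strict")
  expect_equal(pt$depth, 1)
  leaves <- leaf_modules(pt)
  expect_length(leaves, 2)
  expect_true(all(vapply(leaves, function(g) g$n == 2, logical(1))))
})

test_that("replaying the recorded 10_19 splits rebuilds the published decomposition", {
  fx <- rag_example("10_19")
  pt <- replay_splits(fx$graph, fx$recorded_splits)
  leaves <- leaf_modules(pt)
  expect_length(leaves, 5)
  expect_true(all(vapply(leaves, is_minimal_module, logical(1))))

  catalog <- rag_catalog(6)
  ids <- vapply(leaves, identify_graph, character(1), catalog = catalog)
  expect_equal(sort(ids), sort(c("2_1", "4_2", "4_2", "2_1", "2_1")))

  vsets <- lapply(leaves, `[[`, "vertices")
  for (expected in list(c(3, 4), c(1, 2, 3, 5), c(1, 6, 7, 8), c(8, 9), c(9, 10)))
    expect_true(any(vapply(vsets, setequal, logical(1), expected)),
                label = paste("leaf {", paste(expected, collapse = ","), "}"))

  # first split: 5_2 and 6_2 connected by vertex 1
  first_kids <- pt$nodes[pt$nodes[[1]]$children]
  expect_true(setequal(intersect(first_kids[[1]]$graph$vertices,
                                 first_kids[[2]]$graph$vertices), 1))
})

test_that("replay rejects malformed recorded splits", {
  fx <- rag_example("10_19")
  expect_error(replay_splits(fx$graph, list(list(1:4, 4:10))), "overlap")
  expect_error(replay_splits(fx$graph, list(list(1:3, 6:10))), "matches no")
  pt0 <- replay_splits(fx$graph, list())
  expect_length(leaf_modules(pt0), 1)
})

test_that("the 10_19 assembly plan merges deepest first, through the shared vertices", {
  fx <- rag_example("10_19")
  pt <- replay_splits(fx$graph, fx$recorded_splits)
  plan <- assembly_plan(pt, catalog = rag_catalog(6))
  expect_equal(nrow(plan), 4)
  expect_equal(plan$shared_vertex[1], 8)                    # 4_2 + 2_1 -> 5_2
  expect_equal(plan$shared_vertex[nrow(plan)], 1)           # 5_2 + 6_2 -> 10_19
  expect_equal(sort(c(plan$left_id[1], plan$right_id[1])), c("2_1", "4_2"))
  expect_equal(plan$product_id[1], "5_2")
  final <- plan[nrow(plan), ]
  expect_equal(sort(c(final$left_id, final$right_id)), c("5_2", "6_2"))
  expect_setequal(final$product[[1]], 1:10)

  rebuilt <- assemble(pt)
  expect_identical(rebuilt$edges, fx$graph$edges)
})

test_that("assembly planning refuses strict-mode trees", {
  pt <- decompose_graph(path_graph(6), mode = "strict")
  expect_error(assembly_plan(pt), "overlap")
  expect_error(assemble(pt), "overlap")
})

test_that("overlap decomposition round-trips on random trees", {
  set.seed(23)
  for (rep in 1:40) {
    g <- random_tree(sample(5:14, 1))
    pt <- tryCatch(decompose_graph(g), error = function(e) e)
    if (inherits(pt, "error")) {
      expect_match(conditionMessage(pt), "single cut edge")  # multi-cut refusal
      next
    }
    rebuilt <- assemble(pt)
    expect_identical(rebuilt$edges, g$edges)
    expect_identical(rebuilt$vertices, g$vertices)
    # leaf edge sets partition the root edge set
    leaf_edges <- lapply(leaf_modules(pt), function(f) paste(f$edges[, 1], f$edges[, 2]))
    expect_equal(sort(unlist(leaf_edges)), sort(paste(g$edges[, 1], g$edges[, 2])))
    expect_equal(sum(lengths(leaf_edges)), nrow(g$edges))
    # every leaf satisfies the stop predicate; every fragment shrank
    expect_true(all(vapply(leaf_modules(pt), is_minimal_module, logical(1))))
    for (nd in pt$nodes) {
      if (is.na(nd$parent)) next
      expect_lt(nrow(nd$graph$edges), nrow(pt$nodes[[nd$parent]]$graph$edges))
    }
  }
})

test_that("catalog-membership stop predicate terminates decomposition earlier", {
  catalog <- rag_catalog(6)
  g <- rag_example("10_19")$graph
  pt <- decompose_graph(g, stop_when = catalog_stop(catalog))
  expect_true(all(vapply(leaf_modules(pt),
                         function(f) !is.na(identify_graph(f, catalog)),
                         logical(1))))
  expect_lte(pt$depth, decompose_graph(g)$depth)
})

test_that("partition trees tidy into a node table and export DOT", {
  fx <- rag_example("10_19")
  pt <- replay_splits(fx$graph, fx$recorded_splits)
  tab <- tidy(pt)
  expect_equal(nrow(tab), 9)  # 4 internal nodes + 5 leaves
  expect_equal(sum(tab$is_leaf), 5)
  expect_true(all(tab$depth[tab$is_leaf] >= 1))
  expect_equal(glance(pt)$n_leaves, 5)
  dot <- partition_dot(pt)
  expect_match(dot, "digraph")
  expect_equal(length(gregexpr("->", dot)[[1]]), 8)  # binary tree edges
})
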