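test_that("build_compatible handles the textbook cases", {
  u <- c("a", "b", "c", "d")
  tr <- build_compatible(list(rooted_split(c("a", "b"), c("c", "d")),
                              rooted_split(c("a", "b", "c"), "d")), u)
  expect_true(trees_isomorphic(tr, parse_newick("(((a,b),c),d);")))
  # mutually conflicting splits are unbuildable
  expect_null(build_compatible(list(rooted_split(c("a", "b"), "c"),
                                    rooted_split(c("b", "c"), "a")),
                               c("a", "b", "c")))
  # no constraints: a star
  star <- build_compatible(list(), c("a", "b", "c"))
  expect_true(trees_isomorphic(star, parse_newick("(a,b,c);")))
  expect_error(build_compatible(list(rooted_split(c("a", "zz"), "c")), u),
               "outside the universe")
})

test_that("build_compatible equals triplet BUILD on random split sets", {
  # the oracle decomposes every split into all implied triplets and runs
  # Aho's original algorithm; success/failure and the displayed-triplet set
  # must agree in every case
  set.seed(71)
  leaves6 <- paste0("x", 1:6)
  for (i in 1:400) {
    n_leaf <- sample(4:6, 1)
    u <- leaves6[seq_len(n_leaf)]
    n_split <- sample(1:6, 1)
    splits <- replicate(n_split, {
      k <- sample(3:n_leaf, 1)
      picked <- sample(u, k)
      ni <- sample(2:(k - 1L), 1)
      rooted_split(picked[seq_len(ni)], picked[-seq_len(ni)])
    }, simplify = FALSE)
    triplets <- unlist(lapply(splits, function(s)
      split_to_triplets(s$include, s$exclude)), recursive = FALSE)
    oracle <- aho_build(triplets, u)
    mine <- build_compatible(splits, u)
    expect_identical(is.null(mine), is.null(oracle))
    if (!is.null(mine)) {
      expect_identical(
        triplet_key(displayed_triplets(node_clusters(mine), triplets)),
        triplet_key(displayed_triplets(oracle, triplets)))
      # and every displayed triplet is there: the splits themselves hold
      for (s in splits) expect_true(tree_displays(mine, s))
    }
  }
})

test_that("greedy ranked incorporation accepts by rank and reports rejects", {
  res <- consistent_splits_from_ranked_list(
    list(rooted_split(c("a", "b"), "c"), rooted_split(c("b", "c"), "a")),
    c("a", "b", "c"))
  expect_equal(res$accepted, 1L)
  expect_equal(res$rejected, 2L)
  expect_true(tree_displays(res$tree, rooted_split(c("a", "b"), "c")))

  # three pairwise-compatible but jointly incompatible splits: the two
  # highest ranked win, whatever the rotation of the ranking (instance found
  # by brute-force search over 5-leaf splits against the exhaustive
  # tree-enumeration oracle)
  u <- c("a", "b", "c", "d", "e")
  s1 <- rooted_split(c("b", "c"), c("d", "e"))
  s2 <- rooted_split(c("b", "e"), "a")
  s3 <- rooted_split(c("a", "c"), c("b", "d", "e"))
  expect_null(build_compatible(list(s1, s2, s3), u))
  for (pair in list(c(1, 2), c(1, 3), c(2, 3))) {
    expect_false(is.null(build_compatible(list(s1, s2, s3)[pair], u)))
  }
  for (ord in list(c(1, 2, 3), c(2, 3, 1), c(3, 1, 2))) {
    res <- consistent_splits_from_ranked_list(list(s1, s2, s3)[ord], u)
    expect_equal(res$accepted, c(1L, 2L))
    expect_equal(res$rejected, 3L)
  }
})

test_that("all splits of the highest-ranked tree are accepted", {
  set.seed(83)
  for (i in 1:25) {
    t1 <- random_test_tree(sample(4:9, 1))
    t2 <- random_test_tree(n_leaves <- length(leaf_labels(t1)),
                           labels = leaf_labels(t1))
    ranked <- ranked_split_list(list(first = t1, second = t2))
    res <- consistent_splits_from_ranked_list(ranked, leaf_labels(t1))
    expect_true(all(res$table$accepted[res$table$tree_id == "first"]))
  }
})

test_that("solve_subproblem labels the root and explains every exclusion", {
  tax <- micro_taxonomy()
  cl <- clean_input_trees(micro_trees(), tax)
  map <- compute_exemplars(cl$trees, tax)
  ex <- lapply(cl$trees, exemplify_tree, map = map)
  sampled <- unique(unlist(lapply(ex, leaf_labels)))
  taxp <- prune_taxonomy_to_sampled(tax, sampled)
  sps <- build_subproblems(ex, taxp)
  sol <- solve_subproblem(sps$ott2)
  expect_equal(sol$label[sol$root], "ott2")
  expect_setequal(leaf_labels(sol), sps$ott2$universe)
  # rank-1 splits displayed; each rejected split conflicts with the solution
  for (s in tree_splits(sps$ott2$trees$tree1))
    expect_true(tree_displays(sol, s))
  rej <- attr(sol, "rejections")
  expect_true(all(rej$reason == "conflict"))
  ranked <- ranked_split_list(c(sps$ott2$trees, list(taxonomy = sps$ott2$taxonomy)))
  for (k in which(ranked$meta$node_id %in% rej$node_id &
                  ranked$meta$tree_id %in% rej$tree_id))
    expect_true(tree_conflicts(sol, ranked$splits[[k]]))

  # a subproblem with only the taxonomy slice returns the slice shape
  sp_only <- sps$ott1
  sp_only$trees <- list()
  sol2 <- solve_subproblem(sp_only)
  expect_true(trees_isomorphic(suppress_knuckles(sol2),
                               suppress_knuckles(sp_only$taxonomy)))
})

test_that("unconstrained taxa float to the root-most permissible node", {
  # two inputs with partial overlap: taxon e never co-occurs with a, so its
  # grouping (b,c|e) is satisfiable with e attached at the root, and that is
  # where BUILD leaves it
  t1 <- parse_newick("((a,b),c);")
  t2 <- parse_newick("((b,c),e);")
  ranked <- ranked_split_list(list(t1 = t1, t2 = t2))
  res <- consistent_splits_from_ranked_list(ranked, c("a", "b", "c", "e"))
  expect_true(all(res$table$accepted))
  tr <- res$tree
  cls <- lapply(node_clusters(tr), sort)
  expect_true(list(c("a", "b")) %in% cls)
  expect_true(list(c("a", "b", "c")) %in% cls)
  # e was NOT tucked beside (b,c): both input groupings display anyway
  expect_false(list(c("b", "c")) %in% cls)
  expect_true(e_at_root <- "e" %in% tr$label[tr$children[[tr$root]]])
  for (s in ranked$splits) expect_true(tree_displays(tr, s))
})
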