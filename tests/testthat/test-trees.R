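test_that("Newick parsing handles the dialect and rejects malformed input", {
  tr <- parse_newick("((a,b),c);")
  expect_s3_class(tr, "rooted_tree")
  expect_equal(sort(leaf_labels(tr)), c("a", "b", "c"))
  expect_length(tr$children[[tr$root]], 2L)

  # degenerate degree-two chain is preserved
  chain <- parse_newick("(a);")
  expect_equal(n_leaves(chain), 1L)
  expect_length(chain$children[[chain$root]], 1L)

  # underscores are literal, internal labels and branch lengths tolerated
  tr2 <- parse_newick("((a_x:1.2,b)n1:0.1,c)root;")
  expect_true("a_x" %in% leaf_labels(tr2))
  expect_equal(tr2$label[tr2$root], "root")

  expect_error(parse_newick("((a,b),c"), "unbalanced")
  expect_error(parse_newick("((a,b),a);"), "a")
  expect_silent(parse_newick("((a,b),a);", allow_duplicates = TRUE))
})

test_that("write/parse round trip is the identity up to isomorphism", {
  set.seed(101)
  for (i in 1:100) {
    tr <- random_test_tree(sample(2:12, 1))
    re <- parse_newick(write_newick(tr))
    expect_true(trees_isomorphic(tr, re, use_internal_labels = TRUE))
  }
})

test_that("parser agrees with ape on plain binary trees", {
  skip_if_not_installed("ape")
  set.seed(7)
  for (i in 1:20) {
    ap <- ape::rtree(sample(4:15, 1), br = NULL)
    txt <- ape::write.tree(ap)
    mine <- parse_newick(txt)
    expect_equal(sort(leaf_labels(mine)), sort(ap$tip.label))
    # my writer's output reparses in ape to the same topology
    ap2 <- ape::read.tree(text = write_newick(mine))
    expect_true(ape::all.equal.phylo(ap, ap2, use.edge.length = FALSE))
  }
})

test_that("split_of_edge matches the definition on every edge", {
  tr <- parse_newick("((a,b),c);")
  ab <- which(vapply(seq_along(tr$parent), function(v)
    setequal(node_clusters(tr)[[v]], c("a", "b")), logical(1)))
  s <- split_of_edge(tr, ab)
  expect_equal(s$include, c("a", "b"))
  expect_equal(s$exclude, "c")
  leaf_a <- which(tr$label == "a")
  sa <- split_of_edge(tr, leaf_a)
  expect_equal(sa$include, "a")
  expect_equal(sort(sa$exclude), c("b", "c"))
  expect_error(split_of_edge(tr, tr$root), "root")

  # include and exclude partition the leaf set, for every edge of random trees
  set.seed(11)
  for (i in 1:20) {
    rt <- random_test_tree(sample(3:10, 1))
    for (v in setdiff(seq_along(rt$parent), rt$root)) {
      s <- split_of_edge(rt, v)
      expect_setequal(c(s$include, s$exclude), leaf_labels(rt))
      expect_length(intersect(s$include, s$exclude), 0L)
    }
  }
})

test_that("display and conflict follow the rooted-split calculus", {
  A <- rooted_split(c("a", "b", "e"), c("c", "d"))
  B <- rooted_split(c("a", "b"), "c")
  expect_true(split_displays(A, B))
  expect_true(split_displays(A, A))   # reflexive
  expect_false(split_displays(rooted_split(c("a", "b"), c("c", "d")),
                              rooted_split(c("a", "c"), "d")))

  expect_true(split_conflicts(rooted_split(c("a", "b"), c("c", "d")),
                              rooted_split(c("b", "c"), c("a", "d"))))
  # nested-outside arrangement: root-side rule makes them compatible
  expect_false(split_conflicts(rooted_split(c("a", "b"), c("c", "d")),
                               rooted_split(c("c", "d"), c("a", "b"))))
})

test_that("display implies compatibility and conflict is symmetric", {
  set.seed(23)
  taxa <- letters[1:6]
  rand_split <- function() {
    n <- sample(2:5, 1)
    picked <- sample(taxa, n)
    ni <- sample(seq_len(n - 1L), 1)
    rooted_split(picked[seq_len(ni)], picked[-seq_len(ni)])
  }
  for (i in 1:300) {
    A <- rand_split(); B <- rand_split()
    if (split_displays(A, B)) expect_false(split_conflicts(A, B))
    expect_identical(split_conflicts(A, B), split_conflicts(B, A))
  }
})

test_that("tree-level display/conflict quantify over edges; polytomies are soft", {
  S <- parse_newick("((a,b),c);")
  expect_true(tree_displays(S, rooted_split(c("a", "b"), "c")))
  star <- parse_newick("(a,b,c,d);")
  expect_false(tree_displays(star, rooted_split(c("a", "b"), "c")))
  expect_false(tree_conflicts(star, rooted_split(c("a", "b"), "c")))

  # agreement with brute-force edge enumeration on random trees
  set.seed(31)
  for (i in 1:30) {
    rt <- random_test_tree(sample(4:8, 1), labels = letters[1:8])
    pick <- sample(leaf_labels(rt), 4)
    sp <- rooted_split(pick[1:2], pick[3:4])
    edges <- tree_splits(rt, nontrivial_only = FALSE)
    expect_identical(tree_displays(rt, sp),
                     any(vapply(edges, split_displays, logical(1), b = sp)))
    expect_identical(tree_conflicts(rt, sp),
                     any(vapply(edges, split_conflicts, logical(1), b = sp)))
  }
})

test_that("supported_edge detects loss of displayed splits under contraction", {
  S <- parse_newick("((a,b),c);")
  ab <- which(vapply(seq_along(S$parent), function(v)
    setequal(node_clusters(S)[[v]], c("a", "b")), logical(1)))
  expect_true(supported_edge(S, ab, list(rooted_split(c("a", "b"), "c"))))
  expect_false(supported_edge(S, ab, list()))
})

test_that("induce_tree keeps tips, MRCA and partial ancestors with chains", {
  S <- parse_newick("(((a,b),c),d);")
  ind <- induce_tree(S, c("a", "d"))
  expect_setequal(leaf_labels(ind), c("a", "d"))
  # the a-path passes through two retained degree-one ancestors
  expect_equal(length(ind$parent), 5L)
  expect_equal(sum(lengths(ind$children) == 1L), 2L)

  # all leaves: the tree itself
  ind2 <- induce_tree(S, leaf_labels(S))
  expect_true(trees_isomorphic(S, ind2))
  expect_equal(attr(ind2, "node_map"), preorder(S))

  expect_error(induce_tree(S, c("a", "zz")), "zz")

  # suppressing degree-one nodes equals the standard restriction
  set.seed(43)
  for (i in 1:25) {
    rt <- random_test_tree(sample(5:10, 1))
    keep <- sample(leaf_labels(rt), sample(2:4, 1))
    a <- suppress_knuckles(induce_tree(rt, keep))
    b <- suppress_knuckles(keep_leaf_set(rt, keep))
    expect_true(trees_isomorphic(a, b))
  }
})
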