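test_that("grafting merges solutions at shared taxon labels", {
  inner <- parse_newick("((ott31,ott32),ott41)ott2;")
  outer <- parse_newick("(ott2,(ott71,ott81))ott1;")
  g <- graft_solutions(list(outer, inner))
  expect_true(trees_isomorphic(
    g, parse_newick("(((ott31,ott32),ott41)ott2,(ott71,ott81))ott1;"),
    use_internal_labels = TRUE))
  # a single solution grafts to itself
  expect_true(trees_isomorphic(graft_solutions(list(inner)), inner,
                               use_internal_labels = TRUE))
  # two solutions claiming the same root taxon
  expect_error(graft_solutions(list(inner, inner)), "two solutions")
  # a root with no matching leaf anywhere
  stray <- parse_newick("(ott91,ott92)ott9;")
  expect_error(graft_solutions(list(outer, inner, stray)), "top-level|never")
})

test_that("grafted leaves equal the pruned taxonomy's terminals", {
  for (seed in 21:24) {
    fx <- generate_fixture(n_taxa = 18, n_trees = 3, seed = seed)
    r <- run_synthesis(list(taxonomy = fx$taxonomy, trees = fx$trees,
                            prune_flags = fx$prune_flags))
    expect_setequal(leaf_labels(r$grafted), leaf_labels(r$pruned_taxonomy))
    # re-slicing the graft at solution roots recovers each solution
    for (nm in names(r$solutions)) {
      v <- synthtree:::node_by_label(r$grafted, nm)
      resliced <- subtree_at(r$grafted, v)
      # cut below nested solution roots
      others <- setdiff(names(r$solutions), nm)
      keep <- rep(TRUE, length(resliced$parent))
      for (o in others) {
        w <- which(!is.na(resliced$label) & resliced$label == o)
        if (length(w))
          keep[setdiff(preorder(resliced, w), w)] <- FALSE
      }
      resliced <- synthtree:::compact_tree(resliced, keep)
      expect_true(trees_isomorphic(resliced, r$solutions[[nm]],
                                   use_internal_labels = TRUE))
    }
  }
})

test_that("unpruning reattaches unsampled taxa; broken taxa attach at the MRCA", {
  tax <- broken_taxonomy()
  g <- broken_grafted()
  out <- unprune_taxa(g, tax)
  # full leaf set restored
  expect_setequal(leaf_labels(out), terminal_taxa(tax))
  # R is broken: R4, R5, R6 attach at MRCA(R1,R2,R3) -- the node that also
  # contains x1 -- NOT at the root taxon N
  m <- mrca_node(out, match(c("ott21", "ott22", "ott23"), out$label))
  kids <- out$label[out$children[[m]]]
  expect_true(all(c("ott24", "ott25", "ott26") %in% kids))
  expect_true(setequal(
    intersect(node_clusters(out)[[m]], paste0("ott", c(21:26, 31))),
    paste0("ott", c(21:26, 31))))
  expect_equal(attr(out, "broken_taxa")$taxon, "ott2")
  # broken taxa appear as no node; X and Y are reinstated as monotypic
  expect_false("ott2" %in% out$label)
  x <- synthtree:::node_by_label(out, "ott3")
  expect_equal(out$label[out$children[[x]]], "ott31")

  # the alternative: attach at the least inclusive unbroken ancestor (N)
  alt <- unprune_taxa(g, tax, broken_attach = "ancestor")
  expect_true(all(c("ott24", "ott25", "ott26") %in%
                    alt$label[alt$children[[alt$root]]]))

  # nothing pruned: identity modulo monotypic insertions
  full <- unprune_taxa(out, tax)
  expect_true(trees_isomorphic(full, out))
})

test_that("node naming matches taxa by cluster and mrca-names the rest", {
  tax <- micro_taxonomy()
  tr <- parse_newick("(((ott31,ott32),(ott41,ott51)),(ott71,ott81));")
  named <- name_nodes(tr, tax)
  expect_false(anyNA(named$label))
  a <- which(vapply(node_clusters(named), setequal, logical(1),
                    c("ott31", "ott32")))
  expect_equal(named$label[a], "ott3")       # taxon A's cluster
  # {b1,c1} matches no taxon: smallest descendant uid 41 and the smallest
  # uid designating this node as the mrca, 51
  bc <- which(vapply(node_clusters(named), setequal, logical(1),
                     c("ott41", "ott51")))
  expect_equal(named$label[bc], "mrcaott41ott51")
  # the root spans only part of Life's terminals, so it is mrca-named too
  expect_equal(named$label[named$root], "mrcaott31ott71")

  # names are invariant under branch rotation
  rot <- parse_newick("((ott81,ott71),((ott51,ott41),(ott32,ott31)));")
  named2 <- name_nodes(rot, tax)
  key <- function(tr) {
    cl <- lapply(node_clusters(tr), sort)
    stats::setNames(tr$label, vapply(cl, paste, character(1), collapse = ","))
  }
  k1 <- key(named); k2 <- key(named2)
  expect_identical(k1[order(names(k1))], k2[order(names(k2))])
})

test_that("every unbroken multi-terminal taxon surfaces as a named node", {
  for (seed in 31:34) {
    fx <- generate_fixture(n_taxa = 16, n_trees = 3, seed = seed)
    r <- run_synthesis(list(taxonomy = fx$taxonomy, trees = fx$trees,
                            prune_flags = fx$prune_flags))
    tt <- r$taxonomy$tree
    cl_t <- node_clusters(tt)
    cl_s <- lapply(node_clusters(r$labelled), sort)
    keys <- vapply(cl_s, paste, character(1), collapse = ",")
    broken <- attr(r$labelled, "broken_taxa")
    for (v in which(lengths(tt$children) > 0)) {
      lab <- tt$label[v]
      want <- paste(sort(cl_t[[v]]), collapse = ",")
      if (lab %in% broken$taxon) {
        expect_false(lab %in% r$labelled$label)
      } else {
        hit <- which(r$labelled$label == lab)
        expect_length(hit, 1L)
        expect_equal(keys[hit], want)
      }
    }
  }
})
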