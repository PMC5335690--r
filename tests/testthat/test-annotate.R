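test_that("an input identical to the summary restriction is pure support", {
  tax <- micro_taxonomy()
  summary <- name_nodes(
    parse_newick("(((ott31,ott32),(ott41,ott51)),(ott71,ott81));"), tax)
  input <- parse_newick("(((ott31,ott32),(ott41,ott51)),(ott71,ott81));")
  doc <- annotate_summary(summary, list(t1 = input))
  counts <- annotation_counts(doc)
  expect_equal(counts$conflicts_with, 0L)
  expect_equal(counts$resolved_by, 0L)
  expect_equal(counts$resolves, 0L)
  # every internal non-root input node supports some summary node
  expect_equal(counts$supported_by, 4L)
  expect_equal(counts$terminal, 6L)
})

test_that("classification distinguishes terminal, partial path and support", {
  tax <- micro_taxonomy()
  # summary has extra leaves relative to the input, creating degree-one
  # chains in the induced tree
  summary <- name_nodes(
    parse_newick("(((ott31,ott32),((ott41,ott42),ott51)),(ott71,ott81));"),
    tax)
  input <- parse_newick("((ott41,ott51),ott71);")
  doc <- annotate_summary(summary, list(t1 = input))
  per_cat <- function(category) {
    names(Filter(function(rec) category %in% names(rec), doc$nodes))
  }
  # the input cherry (ott41,ott51) restricts both the ABCD-side node and the
  # ((b1,b2),c1) node to the same bipartition: a two-edge path, so both
  # summary nodes are partial_path_of and neither is supported_by
  expect_length(per_cat("partial_path_of"), 2L)
  expect_length(per_cat("supported_by"), 0L)
  # terminal annotations land on the tip paths, including degree-one chains
  expect_true(all(c("ott41", "ott51", "ott71", "ott4") %in%
                    per_cat("terminal")))
  # a cherry displayed by exactly one summary node is plain support
  doc2 <- annotate_summary(summary, list(t1 = parse_newick(
    "((ott31,ott32),ott41);")))
  expect_equal(per_cat <- names(Filter(function(rec)
    "supported_by" %in% names(rec), doc2$nodes)), "ott3")
})

test_that("conflicting input edges are listed against the summary nodes", {
  tax <- micro_taxonomy()
  summary <- name_nodes(
    parse_newick("(((ott31,ott32),(ott41,ott42)),ott51);"), tax)
  input <- parse_newick("((ott32,ott41),(ott31,ott51));")
  doc <- annotate_summary(summary, list(t1 = input))
  expect_gt(annotation_counts(doc)$conflicts_with, 0L)
  # the split-level predicate agrees in both directions
  for (x_name in names(doc$nodes)) {
    rec <- doc$nodes[[x_name]]
    if (!"conflicts_with" %in% names(rec)) next
    v <- synthtree:::node_by_label(summary, x_name)
    L <- leaf_labels(input)
    I_x <- intersect(node_clusters(summary)[[v]], L)
    xs <- rooted_split(I_x, setdiff(L, I_x))
    for (nid in rec$conflicts_with$t1) {
      j <- which(input$node_id == nid)
      expect_true(split_conflicts(xs, split_of_edge(input, j)))
    }
  }
})

test_that("a star input's root resolves a resolved summary grouping", {
  tax <- micro_taxonomy()
  summary <- name_nodes(parse_newick("((ott31,ott32),ott41,ott51);"), tax)
  star <- parse_newick("(ott31,ott32,ott41,ott51);")
  doc <- annotate_summary(summary, list(t1 = star))
  rec <- doc$nodes[["ott3"]]   # the (a1,a2) grouping
  expect_true("resolves" %in% names(rec))
  expect_equal(rec$resolves$t1, star$node_id[star$root])
  # and conversely a resolvable summary polytomy is flagged resolved_by
  summary2 <- name_nodes(parse_newick("(ott31,ott32,ott41,ott51);"), tax)
  input2 <- parse_newick("((ott31,ott32),(ott41,ott51));")
  doc2 <- annotate_summary(summary2, list(t1 = input2))
  expect_gt(annotation_counts(doc2)$resolved_by, 0L)
})

test_that("categories are mutually exclusive per node pair", {
  displayed_cats <- c("supported_by", "partial_path_of", "terminal")
  for (seed in 41:44) {
    fx <- generate_fixture(n_taxa = 14, n_trees = 3, seed = seed)
    r <- run_synthesis(list(taxonomy = fx$taxonomy, trees = fx$trees,
                            prune_flags = fx$prune_flags))
    for (rec in r$annotation$nodes) {
      for (tid in unique(unlist(lapply(rec, names)))) {
        seen <- lapply(rec, function(bytree) bytree[[tid]])
        in_displayed <- unlist(seen[displayed_cats])
        expect_equal(anyDuplicated(in_displayed), 0L)
        expect_length(intersect(unlist(seen["conflicts_with"]),
                                c(in_displayed,
                                  unlist(seen["resolves"]))), 0L)
      }
    }
  }
})

test_that("annotation of a synthesis against its own inputs never resolves", {
  for (seed in 51:56) {
    fx <- generate_fixture(n_taxa = 20, n_trees = 4, seed = seed)
    r <- run_synthesis(list(taxonomy = fx$taxonomy, trees = fx$trees,
                            prune_flags = fx$prune_flags))
    expect_equal(annotation_counts(r$annotation)$resolved_by, 0L)
    # every accepted non-trivial split's source node shows up in a
    # displayed-path category of some summary node
    accepted <- unlist(lapply(r$annotation$nodes, function(rec)
      lapply(rec[c("supported_by", "partial_path_of", "terminal")],
             unlist)), use.names = FALSE)
    for (tid in names(r$exemplified)) {
      for (s in tree_splits(r$exemplified[[tid]]))
        expect_true(tree_displays(r$labelled, s) ||
                      tree_conflicts(r$labelled, s))
    }
  }
})
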