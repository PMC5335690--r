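# Independent oracles used by the test suite. These deliberately avoid the
# package's own code paths: trees are enumerated as bitmask cluster sets and
# BUILD is re-implemented directly from rooted triplets.

# --- exhaustive rooted-tree enumeration (bitmask clusters) -------------------
# A rooted binary tree over leaves {1..n} (bits 1,2,4,...) is represented by
# the set of its non-root clusters (every non-root node, terminal edges
# included). all_rooted_trees(n) returns a list of integer vectors.
all_rooted_trees <- function(n) {
  trees <- list(integer(0))  # single-leaf tree: no edges
  for (k in 2:n) {
    bit <- bitwShiftL(1L, k - 1L)
    full <- bitwShiftL(1L, k - 1L) - 1L  # mask of leaves 1..k-1
    out <- list()
    for (tr in trees) {
      # attach above the root
      out[[length(out) + 1L]] <- c(tr, full, bit)
      # attach above each existing non-root node with cluster c
      for (c_ in tr) {
        gains <- bitwAnd(tr, c_) == c_ & tr != c_  # strict superset clusters
        nt <- ifelse(gains, bitwOr(tr, bit), tr)
        out[[length(out) + 1L]] <- c(as.integer(nt), bitwOr(c_, bit), bit)
      }
    }
    trees <- out
  }
  trees
}

# does some tree in `trees` display both splits (given as include/exclude
# bitmasks)? Root sides implicitly contain the root.
oracle_compatible <- function(trees, iA, eA, iB, eB) {
  for (tr in trees) {
    okA <- any(bitwAnd(tr, iA) == iA & bitwAnd(tr, eA) == 0L)
    okB <- any(bitwAnd(tr, iB) == iB & bitwAnd(tr, eB) == 0L)
    if (okA && okB) return(TRUE)
  }
  FALSE
}

# --- classic Aho BUILD over rooted triplets ----------------------------------
# triplets: list of c(a, b, c) meaning the rooted triplet ab|c.
# Returns the list of clusters of the built tree, or NULL if incompatible.
aho_build <- function(triplets, leaves) {
  build <- function(leaves) {
    if (length(leaves) == 1L) return(list())
    act <- Filter(function(t) all(t %in% leaves), triplets)
    comp <- stats::setNames(leaves, leaves)  # union-find over leaf names
    find <- function(x) { while (comp[[x]] != x) x <- comp[[x]]; x }
    for (t in act) {
      ra <- find(t[1]); rb <- find(t[2])
      if (ra != rb) comp[[ra]] <- rb
    }
    roots <- vapply(leaves, find, character(1))
    groups <- split(leaves, roots)
    if (length(groups) == 1L && length(act) > 0L) return(NULL)
    out <- list()
    for (g in groups) {
      sub <- build(g)
      if (is.null(sub) && length(g) > 1L) return(NULL)
      out <- c(out, list(sort(g)), sub)
    }
    out
  }
  res <- build(leaves)
  if (is.null(res)) NULL else
    unique(Filter(function(cl) length(cl) < length(leaves), res))
}

# all rooted triplets ab|c implied by a split (include | exclude)
split_to_triplets <- function(include, exclude) {
  out <- list()
  if (length(include) < 2L || !length(exclude)) return(out)
  pairs <- utils::combn(sort(include), 2L, simplify = FALSE)
  for (p in pairs) for (z in exclude)
    out[[length(out) + 1L]] <- c(p, z)
  out
}

# triplets displayed by a tree given as a cluster list (character vectors)
displayed_triplets <- function(clusters, triplets) {
  Filter(function(t) {
    any(vapply(clusters, function(cl)
      all(t[1:2] %in% cl) && !(t[3] %in% cl), logical(1)))
  }, triplets)
}

triplet_key <- function(triplets) {
  sort(vapply(triplets, function(t)
    paste(c(sort(t[1:2]), t[3]), collapse = "|"), character(1)))
}

# --- exhaustive polytomy resolutions -----------------------------------------
# all binary refinements of a rooted_tree, as lists of label clusters;
# used as the ground-truth for soft-polytomy contestedness.
all_resolutions_clusters <- function(tr) {
  # local recursive resolution over nested lists of leaf-label sets
  as_nested <- function(v) {
    kids <- tr$children[[v]]
    if (!length(kids)) return(tr$label[v])
    lapply(kids, as_nested)
  }
  # every binary tree over a set of child subtrees
  groupings <- function(items) {
    if (length(items) == 1L) return(list(items[[1]]))
    if (length(items) == 2L) return(list(list(items[[1]], items[[2]])))
    out <- list()
    # split items into two non-empty parts (first item fixed to part 1)
    rest <- items[-1]
    n <- length(rest)
    for (mask in 0:(2^n - 2)) {
      part1 <- items[1]
      part2 <- list()
      for (i in seq_len(n)) {
        if (bitwAnd(mask, bitwShiftL(1L, i - 1L)) > 0L)
          part1 <- c(part1, rest[i]) else part2 <- c(part2, rest[i])
      }
      if (!length(part2)) next
      for (l in groupings(part1)) for (r in groupings(part2))
        out[[length(out) + 1L]] <- list(l, r)
    }
    out
  }
  resolve <- function(node) {
    if (!is.list(node)) return(list(node))
    kid_opts <- lapply(node, resolve)  # each: list of alternatives
    combos <- list(list())
    for (opts in kid_opts) {
      combos <- unlist(lapply(combos, function(cm)
        lapply(opts, function(o) c(cm, list(o)))), recursive = FALSE)
    }
    unlist(lapply(combos, groupings), recursive = FALSE)
  }
  leafset <- function(node) {
    if (!is.list(node)) return(node)
    unlist(lapply(node, leafset))
  }
  clusters_of <- function(node, acc = list()) {
    if (!is.list(node)) return(list(node))
    res <- list(sort(leafset(node)))
    for (k in node) res <- c(res, clusters_of(k))
    res
  }
  lapply(resolve(as_nested(tr$root)), clusters_of)
}

# --- shared random tree generator (seeded by the caller) ---------------------
random_test_tree <- function(n_leaves, labels = paste0("t", seq_len(n_leaves))) {
  stopifnot(n_leaves >= 2L)
  parent <- c(0L, 1L, 1L)
  nl <- 2L
  while (nl < n_leaves) {
    at <- sample(2:length(parent), 1L)
    np <- length(parent) + 1L
    parent <- c(parent, parent[at], np)
    parent[at] <- np
    nl <- nl + 1L
  }
  tr <- rooted_tree(parent)
  lv <- tree_leaves(tr)
  tr$label[lv] <- sample(labels, length(lv))
  tr
}
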