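# -- rooted splits -------------------------------------------------------------
#
# Cutting an edge of a rooted tree bi-partitions its leaves into the cluster
# (include side, away from the root) and the root side (exclude). The root
# side implicitly contains the root, so two splits whose exclude sets are
# disjoint are still considered to share the root: the exclude/exclude
# intersection cell is treated as always non-empty.

#' Construct a rooted split
#'
#' @param include taxon IDs on the far side of the cut edge (the cluster);
#'   must be non-empty.
#' @param exclude taxon IDs on the root side; may be empty (the root side is
#'   implicitly non-empty because it contains the root).
#' @return an object of class `rooted_split`
#' @export
rooted_split <- function(include, exclude = character(0)) {
  include <- sort(unique(as.character(include)))
  exclude <- sort(unique(as.character(exclude)))
  if (!length(include)) stop("a rooted split needs a non-empty include set")
  if (length(intersect(include, exclude)))
    stop("include and exclude must be disjoint")
  structure(list(include = include, exclude = exclude), class = "rooted_split")
}

#' @export
print.rooted_split <- function(x, ...) {
  cat("{", paste(x$include, collapse = ","), "}|*{",
      paste(x$exclude, collapse = ","), "}\n", sep = "")
  invisible(x)
}

#' Is a split phylogenetically trivial?
#'
#' A split with fewer than two included taxa, or with nothing on the root
#' side, carries no grouping information (a two-leaf tree says nothing) and
#' is excluded from all compatibility bookkeeping.
#' @param s a `rooted_split`
#' @export
is_trivial_split <- function(s) {
  length(s$include) < 2L || length(s$exclude) < 1L
}

#' Does split A display split B?
#'
#' `A` displays `B` when `B`'s include set lies inside `A`'s include set and
#' `B`'s exclude set inside `A`'s exclude set. The leaf universes of the two
#' splits may differ. Display is reflexive and implies compatibility.
#' @param a,b `rooted_split` objects
#' @export
split_displays <- function(a, b) {
  all(b$include %in% a$include) && all(b$exclude %in% a$exclude)
}

#' Do two rooted splits conflict?
#'
#' Conflict holds when all three of `A1∩B1`, `A1∩B2` and `A2∩B1`
#' are non-empty; the fourth cell (`A2∩B2`) is treated as always
#' non-empty, because both root sides implicitly contain the root. Two splits
#' conflict exactly when no rooted tree can display both.
#' @param a,b `rooted_split` objects
#' @export
split_conflicts <- function(a, b) {
  any(a$include %in% b$include) &&
    any(a$include %in% b$exclude) &&
    any(a$exclude %in% b$include)
}

#' The rooted split induced by the edge above a node
#'
#' @param tr a `rooted_tree`
#' @param node a non-root node; the cut edge is the one joining it to its
#'   parent.
#' @return a `rooted_split` with include = leaf labels below `node` and
#'   exclude = the remaining leaf labels of the tree.
#' @export
split_of_edge <- function(tr, node) {
  if (node == tr$root) stop("the root has no edge above it: no split defined")
  cl <- node_clusters(tr)
  rooted_split(cl[[node]], setdiff(cl[[tr$root]], cl[[node]]))
}

#' All edge splits of a tree
#'
#' @param tr a `rooted_tree`
#' @param nontrivial_only drop splits with fewer than 2 included leaves or an
#'   empty exclude set (see [is_trivial_split()]).
#' @return a list of `rooted_split`s; names are the node ids of the tipward
#'   endpoint of each edge, attribute `nodes` carries the node indices.
#' @export
tree_splits <- function(tr, nontrivial_only = TRUE) {
  cl <- node_clusters(tr)
  all_leaves <- cl[[tr$root]]
  nodes <- setdiff(seq_along(tr$parent), tr$root)
  out <- list(); keep_nodes <- integer(0)
  for (v in nodes) {
    s <- rooted_split(cl[[v]], setdiff(all_leaves, cl[[v]]))
    if (nontrivial_only && is_trivial_split(s)) next
    out[[length(out) + 1L]] <- s
    keep_nodes <- c(keep_nodes, v)
  }
  names(out) <- tr$node_id[keep_nodes]
  attr(out, "nodes") <- keep_nodes
  out
}

#' Does a tree display / conflict with a rooted split?
#'
#' Existential quantification of [split_displays()] (respectively
#' [split_conflicts()]) over all edge splits of the tree. A star tree
#' displays no non-trivial split and conflicts with none: its polytomy is
#' soft.
#' @param tr a `rooted_tree`
#' @param s a `rooted_split`
#' @export
tree_displays <- function(tr, s) {
  cl <- node_clusters(tr)
  all_leaves <- cl[[tr$root]]
  for (v in seq_along(tr$parent)) {
    if (v == tr$root) next
    if (all(s$include %in% cl[[v]]) && !any(s$exclude %in% cl[[v]]))
      return(TRUE)
  }
  FALSE
}

#' @rdname tree_displays
#' @export
tree_conflicts <- function(tr, s) {
  cl <- node_clusters(tr)
  for (v in seq_along(tr$parent)) {
    if (v == tr$root) next
    inc <- cl[[v]]
    if (any(inc %in% s$include) && any(inc %in% s$exclude) &&
        any(s$include %in% setdiff(cl[[tr$root]], inc)))
      return(TRUE)
  }
  FALSE
}

#' Is a summary edge supported by some input split?
#'
#' Edge `k` (named by its tipward node) is supported when at least one input
#' split is displayed by the tree but would no longer be displayed after
#' contracting `k`. Unsupported edges are exactly the ones the synthesis goals
#' forbid.
#' @param tr a `rooted_tree`
#' @param node non-root internal node naming the edge
#' @param splits list of `rooted_split`s from the input trees
#' @export
supported_edge <- function(tr, node, splits) {
  if (!length(splits)) return(FALSE)
  contracted <- contract_edge(tr, node)
  for (s in splits) {
    if (tree_displays(tr, s) && !tree_displays(contracted, s)) return(TRUE)
  }
  FALSE
}

#' Induce the subtree spanned by a leaf subset
#'
#' Returns the summary tree restricted to `leaves`: exactly the tips mapped
#' to those labels, their MRCA (which becomes the root), and every node
#' ancestral to some but not all of them. Out-degree-one chains are retained
#' -- they are what distinguishes `partial_path_of` from `supported_by` in
#' the annotation. The `node_map` attribute maps induced node indices back to
#' the source tree.
#' @param tr a `rooted_tree`
#' @param leaves leaf labels, at least 2, all present in `tr`
#' @return a `rooted_tree` with attribute `node_map`
#' @export
induce_tree <- function(tr, leaves) {
  leaves <- unique(as.character(leaves))
  if (length(leaves) < 2L) stop("need at least 2 leaves to induce a tree")
  missing <- setdiff(leaves, leaf_labels(tr))
  if (length(missing))
    stop("leaves not in tree: ", paste(missing, collapse = ", "))
  lf <- is_leaf(tr)
  cnt <- integer(length(tr$parent))
  hit <- lf & tr$label %in% leaves
  for (v in postorder(tr)) {
    cnt[v] <- if (lf[v]) as.integer(hit[v]) else sum(cnt[tr$children[[v]]])
  }
  m <- length(leaves)
  mrca <- mrca_node(tr, which(hit))
  keep <- cnt > 0L & (cnt < m | seq_along(cnt) == mrca)
  keep[mrca] <- TRUE
  compact_tree(tr, keep, new_root = mrca)
}
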