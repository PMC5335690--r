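# -- subproblem decomposition at uncontested taxa ------------------------------
#
# A taxon is contested by an input tree when it cannot be monophyletic in any
# resolution of that tree's polytomies (soft-polytomy semantics). Taxa
# contested by no tree are safe cut points: the synthesis problem splits into
# one subproblem per uncontested taxon, each a slice of the taxonomy plus the
# corresponding slices of every relevant input tree.

#' Does an input tree contest a taxon?
#'
#' Equivalent to "no resolution of the tree's polytomies displays the taxon's
#' monophyly": true iff the taxon's split over the tree's leaves conflicts
#' with at least one edge split of the tree. A star tree contests nothing --
#' a taxon is not contested merely because it is not displayed.
#'
#' @param t a taxon label (or uid) in the pruned taxonomy
#' @param tr an exemplified `rooted_tree`
#' @param taxp the pruned taxonomy (a `rooted_tree`, e.g. from
#'   [prune_taxonomy_to_sampled()])
#' @export
is_contested <- function(t, tr, taxp) {
  lab <- if (is.numeric(t)) ott_label(t) else as.character(t)
  below <- node_clusters(taxp)[[node_by_label(taxp, lab)]]
  universe <- leaf_labels(tr)
  inc <- intersect(universe, below)
  if (length(inc) < 2L || length(inc) == length(universe)) return(FALSE)
  tree_conflicts(tr, rooted_split(inc, setdiff(universe, inc)))
}

#' Taxa contested by no input tree
#'
#' @param trees list of exemplified `rooted_tree`s
#' @param taxp the pruned taxonomy tree
#' @return character vector of uncontested non-terminal taxon labels (the
#'   root is always included; with no input trees every taxon is
#'   uncontested). Monotonicity: adding a tree that contests `x` removes `x`
#'   from this set -- the curation lever for breaking bad monophyly
#'   constraints.
#' @export
uncontested_taxa <- function(trees, taxp) {
  internal <- which(!is_leaf(taxp))
  cl <- node_clusters(taxp)
  leaf_sets <- lapply(trees, leaf_labels)
  split_sets <- lapply(trees, tree_splits)
  out <- character(0)
  for (v in internal) {
    below <- cl[[v]]
    contested <- FALSE
    for (i in seq_along(trees)) {
      inc <- intersect(leaf_sets[[i]], below)
      if (length(inc) < 2L || length(inc) == length(leaf_sets[[i]])) next
      exc <- setdiff(leaf_sets[[i]], inc)
      for (s in split_sets[[i]]) {
        if (any(s$include %in% inc) && any(s$include %in% exc) &&
            any(s$exclude %in% inc)) { contested <- TRUE; break }
      }
      if (contested) break
    }
    if (!contested) out <- c(out, taxp$label[v])
  }
  unique(c(taxp$label[taxp$root], out))
}

#' Decompose the synthesis problem at uncontested taxa
#'
#' Every uncontested taxon whose slice spans at least two leaves becomes the
#' root of a subproblem; its leaf universe is the set of maximal
#' slice-point/terminal taxa properly below it. Uncontested taxa that head a
#' monotypic chain (a single-leaf slice) are not used as cut points -- they
#' stay as degree-two labelled nodes inside the enclosing taxonomy slice and
#' are reinstated during unpruning. Each non-root slice point therefore
#' occurs as a leaf in exactly one subproblem and as the root of one other.
#'
#' Input trees are sliced by replacing, for every slice point `u` in the
#' universe, the tips belonging to `u` with a single leaf labelled `u`: at
#' `v = MRCA` of those tips every child subtree is provably pure (entirely
#' inside or outside `u`; an impure child violates uncontestedness and is an
#' internal error); the pure children are removed and one leaf `u` is
#' attached at `v`, or `v` itself becomes the leaf when all its leaves
#' belong to `u`. Slices with fewer than 3 leaves carry no grouping
#' information and are dropped from the subproblem (counted in
#' `n_dropped_slices`).
#'
#' @param trees named list of exemplified `rooted_tree`s, in rank order
#' @param taxp the pruned taxonomy tree
#' @return list of `subproblem` objects, in preorder of the taxonomy; each
#'   has `root_taxon`, `universe`, `trees` (named list, rank order),
#'   `taxonomy` (the taxonomy slice, lowest rank), and `n_dropped_slices`.
#' @export
build_subproblems <- function(trees, taxp) {
  if (is.null(names(trees)) || !all(nzchar(names(trees))))
    names(trees) <- paste0("tree", seq_along(trees))
  unc <- uncontested_taxa(trees, taxp)
  lf <- is_leaf(taxp)
  is_unc <- !lf & !is.na(taxp$label) & taxp$label %in% unc
  slice_point <- rep(FALSE, length(taxp$parent))
  universe_of <- vector("list", length(taxp$parent))
  # leaves of the slice rooted at an internal node, stopping at slice points
  slice_leaves <- function(v) {
    out <- character(0)
    for (k in taxp$children[[v]]) {
      out <- c(out, if (lf[k] || slice_point[k]) taxp$label[k]
               else slice_leaves(k))
    }
    out
  }
  for (v in postorder(taxp)) {
    if (lf[v] || !is_unc[v]) next
    u <- slice_leaves(v)
    if (length(u) >= 2L || v == taxp$root) {
      slice_point[v] <- TRUE
      universe_of[[v]] <- u
    }
  }
  slice_point[taxp$root] <- TRUE
  cl <- node_clusters(taxp)
  out <- list()
  for (v in preorder(taxp)) {
    if (!slice_point[v]) next
    universe <- universe_of[[v]] %||% slice_leaves(v)
    sliced <- list()
    dropped <- 0L
    for (id in names(trees)) {
      sl <- slice_input_tree(trees[[id]], taxp, v, universe, cl)
      if (is.null(sl)) next
      if (n_leaves(sl) < 3L) { dropped <- dropped + 1L; next }
      sliced[[id]] <- sl
    }
    out[[taxp$label[v]]] <- structure(
      list(root_taxon = taxp$label[v], universe = universe,
           trees = sliced, taxonomy = taxonomy_slice(taxp, v, universe),
           n_dropped_slices = dropped),
      class = "subproblem")
  }
  out
}

#' @export
print.subproblem <- function(x, ...) {
  cat("subproblem", x$root_taxon, "-", length(x$universe), "tips,",
      length(x$trees), "input slice(s) + taxonomy\n")
  invisible(x)
}

# the taxonomy between a slice root and its universe: descend from v but do
# not enter slice-point descendants or universe leaves
taxonomy_slice <- function(taxp, v, universe) {
  keep <- rep(FALSE, length(taxp$parent))
  walk <- v
  while (length(walk)) {
    w <- walk[[length(walk)]]; walk <- walk[-length(walk)]
    keep[w] <- TRUE
    if (w != v && !is.na(taxp$label[w]) && taxp$label[w] %in% universe) next
    walk <- c(walk, taxp$children[[w]])
  }
  compact_tree(taxp, keep, new_root = v)
}

# slice one input tree for the subproblem rooted at taxonomy node v
slice_input_tree <- function(tr, taxp, v, universe, cl) {
  relevant <- intersect(leaf_labels(tr), cl[[v]])
  if (!length(relevant)) return(NULL)
  for (u in universe) {
    un <- node_by_label(taxp, u)
    if (is_leaf(taxp)[un]) next
    u_tips <- which(is_leaf(tr) & tr$label %in% cl[[un]])
    if (!length(u_tips)) next
    if (length(u_tips) == 1L) {
      tr$label[u_tips] <- u
      next
    }
    m <- mrca_node(tr, u_tips)
    kid_cl <- node_clusters(tr)
    inside <- vapply(tr$children[[m]], function(k) {
      n_in <- sum(kid_cl[[k]] %in% cl[[un]])
      if (n_in > 0L && n_in < length(kid_cl[[k]]))
        stop("internal error: impure child subtree under uncontested taxon ",
             u, " (violates the uncontestedness lemma)")
      n_in > 0L
    }, logical(1))
    if (all(inside)) {
      # the MRCA itself becomes the leaf u
      keep <- rep(TRUE, length(tr$parent))
      keep[setdiff(preorder(tr, m), m)] <- FALSE
      tr <- compact_tree(tr, keep)
      tr$label[node_which_was(tr, m)] <- u
    } else {
      # remove the pure children, hang one leaf u at the MRCA
      drop_nodes <- unlist(lapply(tr$children[[m]][inside],
                                  function(k) preorder(tr, k)))
      keep <- rep(TRUE, length(tr$parent))
      keep[drop_nodes] <- FALSE
      old_m <- m
      tr2 <- compact_tree(tr, keep)
      m2 <- match(old_m, attr(tr2, "node_map"))
      tr <- add_leaf_child(tr2, m2, u)
    }
  }
  present <- intersect(universe, leaf_labels(tr))
  if (length(present) < 2L) return(NULL)
  suppress_knuckles(keep_leaf_set(tr, present))
}

node_which_was <- function(tr, old_idx) match(old_idx, attr(tr, "node_map"))

add_leaf_child <- function(tr, node, lab) {
  parent <- c(tr$parent, node)
  label <- c(tr$label, lab)
  rooted_tree(parent, label, node_id = c(tr$node_id, lab))
}
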