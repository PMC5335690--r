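# -- subproblem solution: greedy ranked splits + modified BUILD ----------------

#' Build a rooted tree displaying a set of rooted splits
#'
#' The BUILD algorithm generalized from rooted triplets to arbitrary rooted
#' splits: at the current leaf set, the include sets of the active splits
#' (at least two included leaves present and at least one excluded leaf
#' present) are connected in a graph whose connected components become the
#' children; a single component with an active split means the splits are
#' jointly incompatible. With triplet inputs this recovers the original
#' BUILD algorithm, and with larger splits the result is the same as if each
#' were decomposed into all implied triplets. The output is as unresolved as
#' the splits allow: leaves without constraints fall out as polytomy
#' children at the root-most permissible node.
#'
#' @param splits list of `rooted_split`s; trivial splits (see
#'   [is_trivial_split()]) are ignored. Split universes may be subsets of
#'   `leaves`.
#' @param leaves character vector: the full leaf universe of the output tree
#' @return a `rooted_tree` on `leaves` displaying every split, or `NULL`
#'   when the splits are jointly incompatible
#' @export
build_compatible <- function(splits, leaves) {
  leaves <- as.character(leaves)
  if (anyDuplicated(leaves)) stop("duplicate leaves in universe")
  enc <- encode_splits(splits, leaves)
  res <- .build_compatible_cpp(enc$inc, enc$exc, length(leaves))
  if (!res$success) return(NULL)
  parent_to_tree(res$parent, leaves)
}

encode_splits <- function(splits, leaves) {
  inc <- vector("list", length(splits))
  exc <- vector("list", length(splits))
  keep <- logical(length(splits))
  for (i in seq_along(splits)) {
    s <- splits[[i]]
    if (is_trivial_split(s)) next
    ii <- match(s$include, leaves); ee <- match(s$exclude, leaves)
    if (anyNA(ii) || anyNA(ee))
      stop("split references leaves outside the universe: ",
           paste(setdiff(c(s$include, s$exclude), leaves), collapse = ", "))
    inc[[i]] <- ii - 1L; exc[[i]] <- ee - 1L
    keep[i] <- TRUE
  }
  list(inc = inc[keep], exc = exc[keep], keep = keep)
}

# parent vector from the C++ side: entries 1..L are leaves, 0 marks the root
parent_to_tree <- function(parent, leaves) {
  n <- length(parent)
  label <- c(leaves, rep(NA_character_, n - length(leaves)))
  rooted_tree(parent, label)
}

#' Greedy incorporation of a ranked split list
#'
#' Iterates over the splits in rank order, accepting each candidate iff the
#' already-accepted set plus the candidate is jointly buildable. Every
#' rejected split therefore conflicts with the accepted set as a whole,
#' which is what makes each exclusion reportable. All splits of the
#' highest-ranked tree are always accepted (a single tree is
#' self-compatible).
#'
#' @param ranked a `ranked_splits` object from [ranked_split_list()], or a
#'   plain list of `rooted_split`s in rank order
#' @param leaves the full leaf universe
#' @return list with `accepted` / `rejected` (row indices into the ranked
#'   list), `table` (the ranked list with an `accepted` column), and `tree`
#'   (the BUILD tree over the accepted set)
#' @export
consistent_splits_from_ranked_list <- function(ranked, leaves) {
  if (!inherits(ranked, "ranked_splits")) ranked <- ranked_split_list(ranked)
  splits <- ranked$splits
  enc <- encode_splits(splits, leaves)
  res <- .consistent_splits_cpp(enc$inc, enc$exc, length(leaves))
  accepted_flag <- logical(length(splits))
  accepted_flag[which(enc$keep)] <- res$accepted
  # trivial splits are always displayable; mark them accepted for reporting
  accepted_flag[!enc$keep] <- TRUE
  tree <- if (res$tree$success) parent_to_tree(res$tree$parent, leaves) else NULL
  ranked$meta$accepted <- accepted_flag
  list(accepted = which(accepted_flag), rejected = which(!accepted_flag),
       table = ranked$meta, tree = tree)
}

#' Assemble a ranked split list from sliced trees
#'
#' Ranks follow the input-tree order with the taxonomy slice last; within a
#' tree, splits are taken in one fixed post-order traversal (children before
#' parents, left-to-right in parsed order). Trivial splits are skipped.
#'
#' @param trees named list of `rooted_tree`s in rank order, or a plain list
#'   of `rooted_split`s
#' @return a `ranked_splits` object: `splits` (list of `rooted_split`) and
#'   `meta` (data.frame: rank, tree_id, node_id)
#' @export
ranked_split_list <- function(trees) {
  if (length(trees) && inherits(trees[[1]], "rooted_split")) {
    meta <- data.frame(rank = seq_along(trees),
                       tree_id = NA_character_,
                       node_id = paste0("s", seq_along(trees)))
    return(structure(list(splits = trees, meta = meta),
                     class = "ranked_splits"))
  }
  if (is.null(names(trees)) || !all(nzchar(names(trees))))
    names(trees) <- paste0("tree", seq_along(trees))
  splits <- list(); rank <- integer(0); tid <- character(0); nid <- character(0)
  for (i in seq_along(trees)) {
    tr <- trees[[i]]
    cl <- node_clusters(tr)
    all_leaves <- cl[[tr$root]]
    for (v in postorder(tr)) {
      if (v == tr$root || !length(tr$children[[v]])) next
      s <- rooted_split(cl[[v]], setdiff(all_leaves, cl[[v]]))
      if (is_trivial_split(s)) next
      splits[[length(splits) + 1L]] <- s
      rank <- c(rank, i); tid <- c(tid, names(trees)[i])
      nid <- c(nid, tr$node_id[v])
    }
  }
  structure(list(splits = splits,
                 meta = data.frame(rank = rank, tree_id = tid, node_id = nid)),
            class = "ranked_splits")
}

#' Solve one subproblem
#'
#' Collects the ranked splits of the subproblem's sliced trees (taxonomy
#' slice last), runs the greedy incorporation, and builds the solution tree
#' over the subproblem's leaf universe; its root is labelled with the
#' subproblem's root taxon. A subproblem holding only the taxonomy slice
#' solves to the slice itself (possibly multifurcating).
#'
#' @param sp a `subproblem` from [build_subproblems()]
#' @return a `rooted_tree`; attribute `rejections` is a data.frame (rank,
#'   tree_id, node_id, reason) of the splits excluded by conflict
#' @export
solve_subproblem <- function(sp) {
  if (length(sp$universe) == 1L) {
    # degenerate slice: a labelled root above the single leaf
    tree <- rooted_tree(c(0L, 1L), c(sp$root_taxon, sp$universe))
    attr(tree, "rejections") <- data.frame(
      rank = integer(0), tree_id = character(0), node_id = character(0),
      reason = character(0))
    attr(tree, "n_splits") <- 0L
    return(tree)
  }
  ranked_trees <- c(sp$trees, list(taxonomy = sp$taxonomy))
  ranked <- ranked_split_list(ranked_trees)
  res <- consistent_splits_from_ranked_list(ranked, sp$universe)
  tree <- res$tree
  if (is.null(tree)) stop("internal error: accepted split set not buildable")
  tree$label[tree$root] <- sp$root_taxon
  rej <- res$table[!res$table$accepted, c("rank", "tree_id", "node_id")]
  rej$reason <- if (nrow(rej)) "conflict" else character(0)
  attr(tree, "rejections") <- rej
  attr(tree, "n_splits") <- nrow(res$table)
  tree
}
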