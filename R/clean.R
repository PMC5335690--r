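# -- cleaning raw input trees --------------------------------------------------
#
# Raw curated trees arrive rooted, with an optional ingroup annotation and
# tips that may be unmapped, stale (forwarded ids), duplicated, or mapped to
# nested taxa. Cleaning turns each into a tree whose tips map one-to-one onto
# valid, pairwise non-nested taxa, and logs every pruned tip with a reason.

#' Prune a tree down to its ingroup
#'
#' Outgroup-based rooting asserts ingroup monophyly but leaves the outgroup
#' branching uncertain, so everything outside the curator-annotated ingroup
#' node is discarded. Without an ingroup marker the tree is returned
#' unchanged.
#' @param tr a `rooted_tree`, possibly with `$ingroup` set
#' @return the subtree rooted at the ingroup node
#' @export
prune_to_ingroup <- function(tr) {
  if (is.na(tr$ingroup)) return(tr)
  if (!length(tr$children[[tr$ingroup]]))
    stop("ingroup marker on a leaf: no phylogenetic content")
  if (tr$ingroup == tr$root) return(tr)
  subtree_at(tr, tr$ingroup)
}

#' Drop unmapped tips and update forwarded ids
#'
#' Tips whose label is not an `ott<uid>` id are unmapped and removed. Mapped
#' ids are passed through [forward_id()]; tips forwarding to an invalid or
#' flag-pruned id are removed too. Degree-one chains created by the pruning
#' are suppressed. The original tip identifier is retained as the node id, so
#' later tie-breaks are over the pre-forwarding labels.
#'
#' @param tr a `rooted_tree`
#' @param tax a flag-cleaned [taxonomy()]
#' @return the relabelled, pruned tree with attribute `removed`: a
#'   data.frame of (tip, reason). The tree may end up with fewer than 2
#'   leaves; the caller decides whether to drop it from the run.
#' @export
prune_unmapped_and_forward <- function(tr, tax) {
  lv <- tree_leaves(tr)
  removed <- list()
  keep_label <- character(0)
  for (v in lv) {
    lab <- tr$label[v]
    uid <- ott_uid(lab)
    if (is.na(uid)) {
      removed[[length(removed) + 1L]] <- c(lab, "unmapped")
      tr$label[v] <- NA_character_
      next
    }
    live <- forward_id(tax, uid)
    if (is.na(live)) {
      removed[[length(removed) + 1L]] <- c(lab, "invalid_or_pruned_id")
      tr$label[v] <- NA_character_
      next
    }
    tr$label[v] <- ott_label(live)
  }
  keep <- lv[!is.na(tr$label[lv])]
  if (!length(keep)) return(NULL)  # every tip was unmapped/invalid
  out <- suppress_knuckles(keep_leaf_set_nodes(tr, keep))
  attr(out, "removed") <- removed_df(removed)
  out
}

removed_df <- function(removed) {
  if (!length(removed))
    return(data.frame(tip = character(0), reason = character(0)))
  data.frame(tip = vapply(removed, `[`, character(1), 1),
             reason = vapply(removed, `[`, character(1), 2))
}

# keep_leaf_set by node index (labels may be duplicated mid-cleaning)
keep_leaf_set_nodes <- function(tr, keep_nodes) {
  keep <- rep(FALSE, length(tr$parent))
  keep[keep_nodes] <- TRUE
  for (v in postorder(tr)) {
    kids <- tr$children[[v]]
    if (length(kids)) keep[v] <- any(keep[kids])
  }
  keep[tr$root] <- TRUE
  compact_tree(tr, keep)
}

#' Enforce unique, non-nested tip taxa
#'
#' Two repairs, in order:
#' * nested pairs: when one tip's taxon is an ancestor of another tip's
#'   taxon, the tip mapped to the higher-level taxon is pruned and the lower
#'   one kept;
#' * duplicates: among tips mapped to the same taxon, the curator-chosen
#'   exemplar is kept if one was recorded; otherwise the tip whose original
#'   identifier (the node id, i.e. the pre-forwarding label string) is
#'   lexicographically lowest -- arbitrary, but repeatable.
#'
#' @param tr a `rooted_tree` whose tips are all valid taxa
#' @param tax a flag-cleaned [taxonomy()]
#' @param exemplar_choice optional named character vector: taxon label ->
#'   node id of the curator-chosen tip
#' @return the pruned tree, with attribute `removed` as in
#'   [prune_unmapped_and_forward()]
#' @export
resolve_duplicate_and_nested_tips <- function(tr, tax, exemplar_choice = NULL) {
  removed <- list()
  repeat {
    lv <- tree_leaves(tr)
    labs <- tr$label[lv]
    # nested: a tip is pruned when a *descendant* taxon is also a tip
    tax_nodes <- match(labs, tax$tree$label)
    if (anyNA(tax_nodes))
      stop("tip(s) not in taxonomy: ",
           paste(labs[is.na(tax_nodes)], collapse = ", "))
    drop <- logical(length(lv))
    for (i in seq_along(lv)) {
      strictly_below <- setdiff(
        tax$tree$label[postorder(tax$tree, tax_nodes[i])], labs[i])
      if (any(labs %in% strictly_below)) {
        drop[i] <- TRUE
        removed[[length(removed) + 1L]] <- c(labs[i], "nested_above_other_tip")
      }
    }
    if (!any(drop)) break
    tr <- suppress_knuckles(keep_leaf_set_nodes(tr, lv[!drop]))
  }
  # duplicates
  lv <- tree_leaves(tr)
  labs <- tr$label[lv]
  drop <- logical(length(lv))
  for (lab in unique(labs[duplicated(labs)])) {
    grp <- lv[labs == lab]
    chosen <- NULL
    if (!is.null(exemplar_choice) && lab %in% names(exemplar_choice)) {
      chosen <- grp[tr$node_id[grp] == exemplar_choice[[lab]]]
    }
    if (!length(chosen)) {
      ids <- tr$node_id[grp]
      chosen <- grp[order(ids, grp)][1]
    }
    for (v in setdiff(grp, chosen[1])) {
      drop[lv == v] <- TRUE
      removed[[length(removed) + 1L]] <- c(lab, "duplicate_tip")
    }
  }
  if (any(drop)) tr <- suppress_knuckles(keep_leaf_set_nodes(tr, lv[!drop]))
  attr(tr, "removed") <- removed_df(removed)
  tr
}

#' Clean a collection of raw input trees
#'
#' Applies, per tree and in this order: ingroup pruning, unmapped-tip
#' pruning with id forwarding, then duplicate/nested-tip resolution. Trees
#' reduced below 3 leaves are excluded from synthesis but retained in the
#' log. Cleaning is deterministic.
#'
#' @param trees named list of `rooted_tree` (names are tree ids; unnamed
#'   lists get `tree1`, `tree2`, ...; order is the ranking, highest first)
#' @param tax a flag-cleaned [taxonomy()]
#' @param exemplar_choices optional named list (tree id -> exemplar_choice
#'   vector, see [resolve_duplicate_and_nested_tips()])
#' @return list with `trees` (the cleaned, retained trees, original order)
#'   and `log` (data.frame: tree_id, tip, reason; reason `tree_dropped` rows
#'   record trees excluded entirely)
#' @export
clean_input_trees <- function(trees, tax, exemplar_choices = NULL) {
  if (length(trees) &&
      (is.null(names(trees)) || !all(nzchar(names(trees)))))
    names(trees) <- paste0("tree", seq_along(trees))
  out <- list()
  log <- list()
  note <- function(id, df) {
    if (nrow(df)) log[[length(log) + 1L]] <<- cbind(tree_id = id, df)
  }
  for (id in names(trees)) {
    tr <- prune_to_ingroup(trees[[id]])
    tr <- prune_unmapped_and_forward(tr, tax)
    note(id, attr(tr, "removed") %||% removed_df(list()))
    if (!is.null(tr) && n_leaves(tr) >= 2L) {
      tr <- resolve_duplicate_and_nested_tips(tr, tax,
                                              exemplar_choices[[id]])
      note(id, attr(tr, "removed"))
    }
    if (is.null(tr) || n_leaves(tr) < 3L) {
      note(id, data.frame(tip = NA_character_, reason = "tree_dropped"))
      next
    }
    attr(tr, "removed") <- NULL
    out[[id]] <- tr
  }
  log <- if (length(log)) do.call(rbind, log) else
    data.frame(tree_id = character(0), tip = character(0),
               reason = character(0))
  list(trees = out, log = log)
}
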