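# -- exemplifying higher-taxon tips --------------------------------------------
#
# A tip mapped to a genus or family is ambiguous: it may be chimeric data, an
# unidentified species, or shorthand. Rather than let that ambiguity
# propagate, every higher-taxon tip is replaced by terminal-taxon exemplars,
# chosen once and applied identically in every tree; attaching the exemplars
# and then collapsing the former tip edge avoids smuggling in a monophyly
# claim the source tree never tested.

#' Compute the global exemplar map for higher-taxon tips
#'
#' For every higher (non-terminal) taxon appearing as a tip in any tree, the
#' exemplars are all of its terminal descendants sampled as tips in any input
#' tree. When no member is sampled anywhere, one terminal descendant is
#' chosen arbitrarily but deterministically: the one with the numerically
#' smallest uid.
#'
#' @param trees list of cleaned `rooted_tree`s
#' @param tax a flag-cleaned [taxonomy()]
#' @return named list, higher-taxon label -> character vector of terminal
#'   exemplar labels (sorted by uid)
#' @export
compute_exemplars <- function(trees, tax) {
  terminals <- terminal_taxa(tax)
  tips <- unique(unlist(lapply(trees, leaf_labels), use.names = FALSE))
  sampled_terminals <- intersect(tips, terminals)
  higher <- setdiff(tips, terminals)
  cl <- node_clusters(tax$tree)
  map <- list()
  for (h in higher) {
    below <- cl[[node_by_label(tax$tree, h)]]
    if (!length(below)) stop("taxon ", h, " has no terminal descendants")
    ex <- intersect(below, sampled_terminals)
    if (!length(ex)) ex <- below[which.min(ott_uid(below))]
    map[[h]] <- ex[order(ott_uid(ex))]
  }
  map
}

#' Replace higher-taxon tips by their exemplars
#'
#' Each higher-taxon tip is removed and its exemplars are attached as
#' children of the former tip's parent -- i.e. the exemplars are attached
#' below the tip and the tip edge is then collapsed, so
#' `((A,B),c)` becomes `((a1,a2,b1,b2),c)` and no monophyly claim about `A`
#' or `B` is introduced. New exemplar tips inherit the replaced tip's node
#' id, so annotations can cite the original curated node. Applying the map
#' to a tree with only terminal tips is the identity.
#'
#' @param tr a cleaned `rooted_tree`
#' @param map an exemplar map from [compute_exemplars()]
#' @return the exemplified tree
#' @export
exemplify_tree <- function(tr, map) {
  hits <- which(is_leaf(tr) & tr$label %in% names(map))
  if (!length(hits)) return(tr)
  existing <- leaf_labels(tr)
  parent <- tr$parent; label <- tr$label; node_id <- tr$node_id
  for (v in hits) {
    ex <- map[[label[v]]]
    clash <- intersect(ex, existing)
    if (length(clash))
      stop("exemplar(s) ", paste(clash, collapse = ", "),
           " for tip ", label[v], " collide with existing tips")
    p <- parent[v]
    if (p == 0L) stop("cannot exemplify a root tip")
    # first exemplar reuses the tip node; the rest are new children of p
    label[v] <- ex[1]
    if (length(ex) > 1L) {
      parent <- c(parent, rep(p, length(ex) - 1L))
      label <- c(label, ex[-1])
      node_id <- c(node_id, rep(node_id[v], length(ex) - 1L))
    }
    existing <- c(existing, ex)
  }
  rooted_tree(parent, label, node_id = node_id)
}

#' Prune the taxonomy to the sampled terminal taxa
#'
#' Produces the pruned taxonomy: only terminal taxa present in at least one
#' exemplified input survive as leaves; internal taxa are retained whenever
#' they keep at least one sampled descendant, so monotypic chains survive as
#' degree-two nodes. The removed tips are recorded for the later unpruning
#' step.
#'
#' @param tax a flag-cleaned [taxonomy()]
#' @param sampled character vector of sampled terminal-taxon labels
#' @return a `rooted_tree` (the pruned taxonomy) with attribute
#'   `pruned_tips`: the terminal labels that were removed
#' @export
prune_taxonomy_to_sampled <- function(tax, sampled) {
  sampled <- unique(as.character(sampled))
  if (!length(sampled)) stop("no sampled taxa: nothing to synthesize")
  terminals <- terminal_taxa(tax)
  bad <- setdiff(sampled, terminals)
  if (length(bad))
    stop("sampled labels are not terminal taxa: ",
         paste(bad, collapse = ", "))
  out <- keep_leaf_set(tax$tree, sampled)
  attr(out, "pruned_tips") <- setdiff(terminals, sampled)
  out
}
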