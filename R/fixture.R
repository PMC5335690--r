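# -- synthetic study-condition generator ---------------------------------------
#
# Emulates the shape of real synthesis inputs: a nested taxonomy with some
# flagged (questionable) subtrees and id forwards, plus ranked input trees
# that subsample the terminal taxa, are variously resolved, disagree with
# the taxonomy (SPR perturbations creating contested taxa), map some tips to
# higher taxa, carry duplicated/unmapped/stale tips, and sometimes have an
# outgroup with an annotated ingroup node.

#' Generate a synthetic taxonomy plus ranked input trees
#'
#' @param n_taxa number of (unflagged) terminal taxa, at least 4
#' @param n_trees number of ranked input trees
#' @param leaf_sampling_prob probability each terminal taxon is sampled by a
#'   given tree
#' @param polytomy_prob probability an internal tree edge is collapsed into
#'   a polytomy
#' @param n_spr_moves subtree-prune-regraft perturbations per tree (0 =
#'   every tree is compatible with the taxonomy)
#' @param higher_taxon_tip_prob probability a tip is relabelled to its
#'   parent higher taxon (when no other tip falls inside it)
#' @param outgroup_prob probability a tree gets an outgroup plus ingroup
#'   annotation
#' @param seed integer seed fixing all randomness
#' @return list with `taxonomy` (a [taxonomy()] carrying flags and
#'   forwards), `trees` (named list of `rooted_tree`, rank order),
#'   `prune_flags` (the flag set the run should prune), and `params`
#' @export
generate_fixture <- function(n_taxa = 32, n_trees = 5,
                             leaf_sampling_prob = 0.6, polytomy_prob = 0.2,
                             n_spr_moves = 1, higher_taxon_tip_prob = 0.15,
                             outgroup_prob = 0.3, seed) {
  if (n_taxa < 4) stop("n_taxa must be at least 4")
  stopifnot(leaf_sampling_prob > 0, leaf_sampling_prob <= 1,
            polytomy_prob >= 0, polytomy_prob <= 1, n_trees >= 1)
  params <- list(n_taxa = n_taxa, n_trees = n_trees,
                 leaf_sampling_prob = leaf_sampling_prob,
                 polytomy_prob = polytomy_prob, n_spr_moves = n_spr_moves,
                 higher_taxon_tip_prob = higher_taxon_tip_prob,
                 outgroup_prob = outgroup_prob, seed = seed)
  withr::with_seed(seed, {
    tax <- random_taxonomy(n_taxa)
    clean <- prune_flagged(tax, c("unplaced", "barren"))
    # one fully resolved "true" refinement of the taxonomy underlies every
    # input tree, as it would for real studies of the same organisms;
    # SPR perturbation is what introduces genuine conflict
    truth <- clean$tree
    truth$label[!is_leaf(truth)] <- NA_character_
    truth <- resolve_polytomies_random(truth)
    trees <- list()
    for (i in seq_len(n_trees)) {
      trees[[paste0("tree", i)]] <- random_input_tree(
        truth, clean, tax, leaf_sampling_prob, polytomy_prob, n_spr_moves,
        higher_taxon_tip_prob, outgroup_prob)
    }
    list(taxonomy = tax, trees = trees,
         prune_flags = c("unplaced", "barren"), params = params)
  })
}

# random rooted taxonomy over n terminal taxa, with flagged extras
random_taxonomy <- function(n) {
  # grow a binary tree by random leaf attachment, then collapse some edges
  parent <- c(0L, 1L, 1L)
  for (k in seq_len(n - 2L)) {
    at <- sample(2:length(parent), 1L)
    # insert new internal node above `at`, new leaf beside it
    np <- length(parent) + 1L
    parent <- c(parent, parent[at], np)
    parent[at] <- np
  }
  tr <- rooted_tree(parent)
  # collapse ~30% of internal edges into multifurcations (taxonomies are bushy)
  tr <- collapse_random_edges(tr, 0.3)
  n_all <- length(tr$parent)
  uid <- sample(n_all) * 10L            # spaced so flagged extras can slot in
  tr$label <- ott_label(uid)
  # flagged subtrees: a couple of questionable taxa with terminal children
  leaves <- tree_leaves(tr)
  parent_uid <- rep(NA_integer_, n_all)
  parent_uid[tr$parent != 0L] <- uid[tr$parent[tr$parent != 0L]]
  records <- data.frame(
    uid = uid,
    parent_uid = parent_uid,
    name = paste0("taxon_", uid),
    rank = ifelse(lengths(tr$children) == 0L, "species", "clade"),
    flags = "")
  next_uid <- max(uid) + 10L
  for (k in 1:2) {
    host <- uid[sample(setdiff(which(!is_leaf(tr)), tr$root), 1L)]
    flag <- sample(c("unplaced", "barren"), 1L)
    fuid <- next_uid; next_uid <- next_uid + 10L
    records <- rbind(records,
      data.frame(uid = fuid, parent_uid = host,
                 name = paste0("dubious_", fuid), rank = "clade",
                 flags = flag),
      data.frame(uid = next_uid, parent_uid = fuid,
                 name = paste0("dubious_sp_", next_uid), rank = "species",
                 flags = ""))
    next_uid <- next_uid + 10L
  }
  # forwards: two retired ids pointing at live terminals, one at a flagged taxon
  live <- ott_uid(tr$label[leaves])
  forwards <- data.frame(
    old_uid = next_uid + c(1L, 2L, 3L),
    new_uid = c(sample(live, 2L), records$uid[nzchar(records$flags)][1]))
  taxonomy(records, forwards)
}

random_input_tree <- function(truth, clean, tax, leaf_sampling_prob,
                              polytomy_prob, n_spr_moves,
                              higher_taxon_tip_prob, outgroup_prob) {
  terminals <- terminal_taxa(clean)
  repeat {
    sampled <- terminals[stats::runif(length(terminals)) < leaf_sampling_prob]
    if (length(sampled) >= 4L) break
  }
  tr <- suppress_knuckles(keep_leaf_set(truth, sampled))
  for (k in seq_len(n_spr_moves)) tr <- random_spr(tr)
  tr <- collapse_random_edges(tr, polytomy_prob)  # soften into polytomies
  tr <- relabel_higher_taxa(tr, clean, higher_taxon_tip_prob)
  tr <- add_dirty_tips(tr, tax)
  if (stats::runif(1) < outgroup_prob) tr <- add_outgroup(tr, clean)
  tr
}

collapse_random_edges <- function(tr, p) {
  if (p <= 0) return(tr)
  ids <- tr$node_id[setdiff(which(!is_leaf(tr)), tr$root)]
  ids <- ids[stats::runif(length(ids)) < p]
  for (id in ids) {
    v <- which(tr$node_id == id)
    if (length(v) == 1L && v != tr$root && length(tr$children[[v]]) > 0L)
      tr <- contract_edge(tr, v)
  }
  tr
}

fresh_node_id <- function(tr, base) {
  id <- base
  while (id %in% tr$node_id) id <- paste0(id, "x")
  id
}

resolve_polytomies_random <- function(tr) {
  repeat {
    poly <- which(lengths(tr$children) > 2L)
    if (!length(poly)) return(tr)
    v <- poly[1]
    kids <- tr$children[[v]]
    pick <- sample(kids, 2L)
    # new node groups two random children under v
    parent <- c(tr$parent, v)
    nn <- length(parent)
    parent[pick] <- nn
    tr <- rooted_tree(parent, c(tr$label, NA_character_),
                      node_id = c(tr$node_id, fresh_node_id(tr, paste0("node", nn))))
  }
}

random_spr <- function(tr) {
  n <- length(tr$parent)
  cand <- setdiff(seq_len(n), c(tr$root, tr$children[[tr$root]]))
  if (!length(cand)) return(tr)
  v <- if (length(cand) == 1L) cand else sample(cand, 1L)
  below <- preorder(tr, v)
  dest <- setdiff(seq_len(n), c(below, tr$root, tr$parent[v]))
  if (!length(dest)) return(tr)
  u <- if (length(dest) == 1L) dest else sample(dest, 1L)
  # detach v, insert a new node above u, put v there
  parent <- tr$parent
  nn <- n + 1L
  parent <- c(parent, parent[u])
  parent[u] <- nn
  parent[v] <- nn
  tr2 <- rooted_tree(parent, c(tr$label, NA_character_),
                     node_id = c(tr$node_id, fresh_node_id(tr, paste0("node", nn))))
  suppress_knuckles(tr2)
}

relabel_higher_taxa <- function(tr, clean, p) {
  if (p <= 0) return(tr)
  cl <- node_clusters(clean$tree)
  for (v in tree_leaves(tr)) {
    if (stats::runif(1) >= p) next
    tnode <- match(tr$label[v], clean$tree$label)
    if (is.na(tnode)) next
    pnode <- clean$tree$parent[tnode]
    if (pnode == 0L || pnode == clean$tree$root) next
    plab <- clean$tree$label[pnode]
    others <- setdiff(leaf_labels(tr), tr$label[v])
    if (any(others %in% cl[[pnode]]) || plab %in% others) next
    tr$label[v] <- plab
  }
  tr
}

add_dirty_tips <- function(tr, tax) {
  # stale id: relabel a tip to a retired uid that forwards back to it
  fw <- tax$forwards
  hit <- which(ott_label(fw) %in% leaf_labels(tr))
  if (length(hit) && stats::runif(1) < 0.5) {
    old <- names(fw)[hit[1]]
    v <- which(tr$label == ott_label(fw[[hit[1]]]))[1]
    tr$label[v] <- ott_label(old)
  }
  if (stats::runif(1) < 0.15) {  # duplicate tip
    v <- sample(tree_leaves(tr), 1L)
    tr <- rooted_tree(c(tr$parent, tr$parent[v]),
                      c(tr$label, tr$label[v]),
                      node_id = c(tr$node_id, paste0(tr$node_id[v], "_dup")))
  }
  if (stats::runif(1) < 0.15) {  # unmapped tip
    v <- sample(setdiff(seq_along(tr$parent), tr$root), 1L)
    tr <- rooted_tree(c(tr$parent, tr$parent[v]),
                      c(tr$label, "unmapped_tip"),
                      node_id = c(tr$node_id, "unmapped_tip"))
  }
  tr
}

add_outgroup <- function(tr, clean) {
  outs <- setdiff(terminal_taxa(clean), leaf_labels(tr))
  if (!length(outs)) return(tr)
  og <- if (length(outs) == 1L) outs else sample(outs, 1L)
  n <- length(tr$parent)
  parent <- c(tr$parent, 0L, n + 1L)
  parent[tr$root] <- n + 1L
  out <- rooted_tree(parent, c(tr$label, NA_character_, og),
                     node_id = c(tr$node_id, "new_root", og),
                     ingroup = tr$root)
  out
}
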