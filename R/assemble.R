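# -- grafting, unpruning, naming -----------------------------------------------

#' Graft subproblem solutions into one tree
#'
#' Each non-root slice-point taxon occurs as the root of exactly one solution
#' and as a leaf in exactly one other; grafting merges the nodes labelled
#' with the same taxon id. Internal labels are preserved. A single solution
#' grafts to itself.
#'
#' @param solutions list of solved subproblem trees ([solve_subproblem()])
#' @return a `rooted_tree` spanning all sampled terminal taxa
#' @export
graft_solutions <- function(solutions) {
  if (!length(solutions)) stop("no solutions to graft")
  roots <- vapply(solutions, function(s) s$label[s$root], character(1))
  if (anyDuplicated(roots))
    stop("taxon appears as the root of two solutions: ",
         paste(unique(roots[duplicated(roots)]), collapse = ", "))
  leaf_sets <- lapply(solutions, leaf_labels)
  as_leaf <- roots %in% unlist(leaf_sets, use.names = FALSE)
  top <- which(!as_leaf)
  if (length(top) != 1L)
    stop("expected exactly one top-level solution, found ", length(top))
  used <- logical(length(solutions))
  n <- 0L
  parent <- integer(256); label <- character(256); node_id <- character(256)
  add <- function(p, lab, id) {
    n <<- n + 1L
    if (n > length(parent)) {
      length(parent) <<- 2L * n; length(label) <<- 2L * n
      length(node_id) <<- 2L * n
    }
    parent[n] <<- p; label[n] <<- lab; node_id[n] <<- id
    n
  }
  emit <- function(si, p) {
    if (used[si]) stop("solution for ", roots[si], " grafted twice")
    used[si] <<- TRUE
    s <- solutions[[si]]
    new_idx <- integer(length(s$parent))
    for (v in preorder(s)) {
      pp <- if (v == s$root) p else new_idx[s$parent[v]]
      lab <- s$label[v]
      if (v != s$root && !length(s$children[[v]]) &&
          !is.na(lab) && lab %in% roots) {
        new_idx[v] <- emit(match(lab, roots), pp)
      } else {
        new_idx[v] <- add(pp, lab, s$node_id[v])
      }
    }
    new_idx[s$root]
  }
  emit(top, 0L)
  if (!all(used))
    stop("solution root(s) never grafted (no matching leaf): ",
         paste(roots[!used], collapse = ", "))
  rooted_tree(parent[seq_len(n)], label[seq_len(n)],
              node_id = node_id[seq_len(n)])
}

#' Reattach taxonomy-only taxa to the grafted solution
#'
#' Every taxon with no sampled descendant is grafted back so that the final
#' leaf set equals the terminal taxa of the flag-cleaned taxonomy:
#'
#' * a taxon whose sampled descendants form exactly the cluster of a node of
#'   the grafted tree is *represented*: its unsampled children attach there,
#'   and nested monotypic containers are reinstated as named degree-two
#'   nodes;
#' * a taxon whose sampled descendants do not form a cluster conflicts with
#'   the grafted tree and is *broken*: its unsampled children attach at the
#'   MRCA of its sampled children (default), not at the least inclusive
#'   unbroken ancestor -- `broken_attach = "ancestor"` selects that
#'   alternative, which can pile very large polytomies deep in the tree.
#'
#' When a broken taxon has a single sampled child, the MRCA degenerates to
#' that child's own node; the unsampled children then attach one level up,
#' as siblings of it. Newly attached siblings are added in uid order, so the
#' output is byte-stable.
#'
#' @param grafted the grafted solution tree
#' @param tax the flag-cleaned [taxonomy()]
#' @param broken_attach `"mrca"` (default) or `"ancestor"`
#' @return a `rooted_tree` over all terminal taxa, with represented taxa as
#'   labelled nodes; attribute `broken_taxa` is a data.frame (taxon,
#'   attachment node label/id) listing every broken taxon
#' @export
unprune_taxa <- function(grafted, tax, broken_attach = c("mrca", "ancestor")) {
  broken_attach <- match.arg(broken_attach)
  sampled <- leaf_labels(grafted)
  bad <- setdiff(sampled, terminal_taxa(tax))
  if (length(bad))
    stop("grafted leaves are not terminal taxa: ", paste(bad, collapse = ", "))

  tt <- tax$tree
  tax_cl <- node_clusters(tt)
  g_cl <- node_clusters(grafted)
  leaf_node <- match(sampled, grafted$label)  # label -> grafted leaf index
  names(leaf_node) <- sampled

  n_tax <- length(tt$parent)
  sdesc <- vector("list", n_tax); n_s <- integer(n_tax)
  for (v in seq_len(n_tax)) {
    sdesc[[v]] <- intersect(tax_cl[[v]], sampled)
    n_s[v] <- length(sdesc[[v]])
  }
  M0 <- rep(NA_integer_, n_tax); exact <- rep(NA, n_tax)
  for (v in seq_len(n_tax)) {
    if (n_s[v] == 0L) next
    M0[v] <- mrca_node(grafted, unname(leaf_node[sdesc[[v]]]))
    exact[v] <- length(g_cl[[M0[v]]]) == n_s[v]
  }

  # mutable copy of the grafted tree; original indices stay valid
  n <- length(grafted$parent)
  parent <- grafted$parent; label <- grafted$label
  node_id <- grafted$node_id; children <- grafted$children
  root <- grafted$root
  add <- function(p, lab, id) {
    n <<- n + 1L
    parent[n] <<- p; label[n] <<- lab; node_id[n] <<- id
    children[[n]] <<- integer(0)
    if (p != 0L) children[[p]] <<- c(children[[p]], n)
    n
  }
  insert_above <- function(v, lab) {
    p <- parent[v]
    nn <- add(0L, lab, lab)
    parent[nn] <<- p
    if (p == 0L) root <<- nn else
      children[[p]][children[[p]] == v] <<- nn
    parent[v] <<- nn
    children[[nn]] <<- v
    nn
  }
  insert_below <- function(v, lab) {  # new node inherits all of v's children
    nn <- add(0L, lab, lab)
    parent[nn] <<- v
    children[[nn]] <<- children[[v]]
    for (k in children[[nn]]) parent[k] <<- nn
    children[[v]] <<- nn
    nn
  }

  # follow a degree-two chain to its structural ends
  descend_chain <- function(v) {
    while (length(children[[v]]) == 1L) v <- children[[v]]
    v
  }
  ascend_chain <- function(v) {
    while (parent[v] != 0L && length(children[[parent[v]]]) == 1L)
      v <- parent[v]
    v
  }

  # Taxa whose sampled cluster matches the same grafted node form a
  # monotypic chain. The grafted tree may itself already hold part of that
  # chain as labelled degree-two nodes (degenerate subproblem roots), so the
  # taxonomy chain is merged into the existing one in taxonomy order,
  # inserting the missing containers below or above as needed.
  node_of <- rep(NA_integer_, n_tax)
  tlf <- is_leaf(tt)
  internal_tax <- which(!tlf)
  chain_of <- new.env(parent = emptyenv())   # base node -> taxa, deepest first
  for (t in postorder(tt)) {
    if (tlf[t] || n_s[t] == 0L || !exact[t]) next
    key <- as.character(M0[t])
    chain_of[[key]] <- c(get0(key, envir = chain_of, inherits = FALSE), t)
  }
  for (key in ls(chain_of)) {
    base <- as.integer(key)                      # MRCA: bottom of the chain
    taxa <- chain_of[[key]]                      # deepest first
    ex <- base                                   # existing chain, bottom-up
    v <- base
    while (v != ascend_chain(v)) { v <- parent[v]; ex <- c(ex, v) }
    pinned <- label[ex]
    k <- length(ex)
    j <- if (length(children[[ex[1]]]) == 0L) 2L else 1L  # leaf base: go above
    top <- ex[k]
    for (t in taxa) {
      placed <- FALSE
      while (!placed) {
        if (j > k) {
          top <- insert_above(top, tt$label[t])
          node_of[t] <- top
          placed <- TRUE
        } else if (!is.na(label[ex[j]]) && label[ex[j]] == tt$label[t]) {
          node_of[t] <- ex[j]; j <- j + 1L; placed <- TRUE
        } else if (is.na(label[ex[j]]) && !(tt$label[t] %in% pinned)) {
          label[ex[j]] <- tt$label[t]            # claim the unlabelled node
          node_of[t] <- ex[j]; j <- j + 1L; placed <- TRUE
        } else if (is.na(label[ex[j]])) {
          j <- j + 1L                            # skip; taxon is pinned higher
        } else {
          # a shallower container is already here: slot t in underneath it
          node_of[t] <- insert_below(ex[j], tt$label[t])
          placed <- TRUE
        }
      }
    }
  }

  # copy a whole taxonomy subtree below an anchor
  attach_subtree <- function(anchor, tax_node) {
    idx_map <- integer(length(tt$parent))
    for (v in preorder(tt, tax_node)) {
      p <- if (v == tax_node) anchor else idx_map[tt$parent[v]]
      idx_map[v] <- add(p, tt$label[v], tt$label[v])
    }
  }

  broken_log <- list()
  for (t in internal_tax) {
    if (n_s[t] == 0L) next
    kids <- tt$children[[t]]
    unsampled_kids <- kids[n_s[kids] == 0L]
    if (!length(unsampled_kids)) {
      if (!exact[t]) broken_log[[length(broken_log) + 1L]] <-
          c(tt$label[t], NA_character_)
      next
    }
    if (exact[t]) {
      anchor <- node_of[t]
    } else if (broken_attach == "ancestor") {
      a <- tt$parent[t]
      while (a != 0L && (n_s[a] == 0L || !isTRUE(exact[a]))) a <- tt$parent[a]
      if (a == 0L) stop("no unbroken ancestor found for ", tt$label[t])
      anchor <- node_of[a]
    } else {
      anchor <- descend_chain(M0[t])
      sampled_kids <- kids[n_s[kids] > 0L]
      if (length(sampled_kids) == 1L &&
          length(g_cl[[M0[t]]]) == n_s[sampled_kids]) {
        # the MRCA degenerates to the single sampled child's own node:
        # attach the unsampled children as its siblings, one level up
        at <- ascend_chain(M0[t])
        anchor <- if (parent[at] == 0L) at else parent[at]
      }
      broken_log[[length(broken_log) + 1L]] <-
        c(tt$label[t], node_id[anchor] %||% NA_character_)
    }
    for (c_ in unsampled_kids[order(ott_uid(tt$label[unsampled_kids]))]) {
      attach_subtree(anchor, c_)
    }
  }

  out <- rooted_tree(parent[seq_len(n)], label[seq_len(n)],
                     node_id = node_id[seq_len(n)])
  attr(out, "broken_taxa") <- if (length(broken_log)) {
    data.frame(taxon = vapply(broken_log, `[`, character(1), 1),
               attached_at = vapply(broken_log, `[`, character(1), 2))
  } else data.frame(taxon = character(0), attached_at = character(0))
  out
}

#' Assign stable names to every node
#'
#' A node whose include group equals the include group of a taxonomy node is
#' given that taxon's `ottX` identifier (the least inclusive taxon when a
#' monotypic chain shares the cluster). Every other node gets
#' `mrcaottX1ottX2`, where `X1` is the numerically smallest OTT id below the
#' node and `X2` the smallest id that designates the node as the MRCA of
#' `X1` and `X2` (i.e. the smallest id below a different child). The scheme
#' is insensitive to branch rotation, and low ids make labels likely to
#' survive into later taxonomy versions.
#'
#' @param tr the unpruned summary tree (leaf labels `ottX`)
#' @param tax the flag-cleaned [taxonomy()]
#' @return the tree with every node labelled
#' @export
name_nodes <- function(tr, tax) {
  tax_cl <- node_clusters(tax$tree)
  keymap <- new.env(parent = emptyenv())
  for (v in postorder(tax$tree)) {
    k <- cluster_key(tax_cl[[v]])
    keymap[[k]] <- c(get0(k, envir = keymap, inherits = FALSE),
                     tax$tree$label[v])  # least inclusive first
  }
  cl <- node_clusters(tr)
  used <- tr$label[!is.na(tr$label)]
  min_uid <- rep(NA_integer_, length(tr$parent))
  for (v in postorder(tr)) {
    kids <- tr$children[[v]]
    min_uid[v] <- if (!length(kids)) ott_uid(tr$label[v]) else
      min(min_uid[kids])
  }
  if (anyNA(min_uid[tree_leaves(tr)]))
    stop("mrca naming requires ott-style leaf labels")
  for (v in postorder(tr)) {
    if (!is.na(tr$label[v])) next
    cand <- setdiff(get0(cluster_key(cl[[v]]), envir = keymap,
                         inherits = FALSE), used)
    if (length(cand)) {
      tr$label[v] <- cand[1]
    } else {
      kids <- tr$children[[v]]
      if (length(kids) < 2L)
        stop("cannot mrca-name an out-degree-", length(kids), " node")
      x1 <- min(min_uid[kids])
      x2 <- min(min_uid[kids][-which.min(min_uid[kids])])
      tr$label[v] <- paste0("mrcaott", x1, "ott", x2)
    }
    if (tr$label[v] %in% used)
      stop("internal error: duplicate generated name ", tr$label[v])
    used <- c(used, tr$label[v])
  }
  tr$node_id <- ifelse(is.na(tr$label), tr$node_id, tr$label)
  tr
}

cluster_key <- function(labels) paste(sort(labels), collapse = "\r")
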