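#' @useDynLib synthtree, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# -- rooted_tree ---------------------------------------------------------------
#
# A rooted tree is stored as parallel node arrays:
#   parent   integer, 0 for the root
#   children list of integer vectors, in order
#   label    character, NA when the node is unlabelled
#   node_id  character, a stable identifier that survives pruning/exemplifying
#   root     integer index of the root
#   ingroup  integer index of the ingroup node, NA when not annotated
#
# Degree-two ("knuckle") nodes are first-class citizens: taxonomy trees use
# them for nested monotypic taxa, and induced trees use them for partial paths.

#' Construct a rooted tree from a parent vector
#'
#' @param parent integer vector; `parent[i]` is the index of node `i`'s parent,
#'   with `0` marking the root. Exactly one root is required.
#' @param label character vector of node labels (`NA` = unlabelled). Leaf
#'   labels are the taxon identifiers used by the whole pipeline.
#' @param node_id optional character vector of stable node identifiers; by
#'   default leaves take their label and internal nodes take `"nodeK"`.
#' @param ingroup optional index of the ingroup node.
#' @return an object of class `rooted_tree`.
#' @export
rooted_tree <- function(parent, label = rep(NA_character_, length(parent)),
                        node_id = NULL, ingroup = NA_integer_) {
  parent <- as.integer(parent)
  n <- length(parent)
  if (n == 0L) stop("a rooted tree needs at least one node")
  if (sum(parent == 0L) != 1L) stop("exactly one root (parent == 0) required")
  if (any(parent < 0L | parent > n)) stop("parent index out of range")
  children <- vector("list", n)
  for (i in seq_len(n)) children[[i]] <- integer(0)
  ord <- seq_len(n)[parent != 0L]
  for (i in ord) children[[parent[i]]] <- c(children[[parent[i]]], i)
  tr <- structure(
    list(parent = parent, children = children,
         label = as.character(label),
         node_id = node_id %||% default_node_ids(parent, label, children),
         root = which(parent == 0L), ingroup = as.integer(ingroup)),
    class = "rooted_tree")
  validate_tree(tr)
  tr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

default_node_ids <- function(parent, label, children) {
  ids <- paste0("node", seq_along(parent))
  leaf <- lengths(children) == 0L
  ids[leaf & !is.na(label)] <- label[leaf & !is.na(label)]
  ids
}

validate_tree <- function(tr) {
  # reject cycles / disconnected parts: every node must reach the root
  n <- length(tr$parent)
  depth <- rep(NA_integer_, n)
  depth[tr$root] <- 0L
  for (v in preorder(tr)) if (v != tr$root) depth[v] <- depth[tr$parent[v]] + 1L
  if (anyNA(depth)) stop("tree is not connected (cyclic parent links?)")
  invisible(tr)
}

#' @export
print.rooted_tree <- function(x, ...) {
  cat("rooted_tree:", n_leaves(x), "leaves,", length(x$parent), "nodes\n")
  nw <- write_newick(x)
  if (nchar(nw) > 200) nw <- paste0(substr(nw, 1, 197), "...")
  cat(nw, "\n")
  invisible(x)
}

is_leaf <- function(tr) lengths(tr$children) == 0L

#' Leaf node indices of a tree
#' @param tr a `rooted_tree`
#' @export
tree_leaves <- function(tr) which(is_leaf(tr))

#' Leaf labels of a tree
#' @param tr a `rooted_tree`
#' @export
leaf_labels <- function(tr) tr$label[is_leaf(tr)]

n_leaves <- function(tr) sum(is_leaf(tr))

#' Preorder / postorder node traversals
#'
#' `preorder()` visits parents before children; `postorder()` visits children
#' (left to right, in parsed order) before their parent. The traversal order
#' is the one fixed for split incorporation in [solve_subproblem()].
#' @param tr a `rooted_tree`
#' @param from node to start from (default: the root)
#' @return integer vector of node indices
#' @export
preorder <- function(tr, from = tr$root) {
  out <- integer(length(tr$parent)); k <- 0L
  stack <- from
  while (length(stack)) {
    v <- stack[[length(stack)]]; stack <- stack[-length(stack)]
    k <- k + 1L; out[k] <- v
    kids <- tr$children[[v]]
    if (length(kids)) stack <- c(stack, rev(kids))
  }
  out[seq_len(k)]
}

#' @rdname preorder
#' @export
postorder <- function(tr, from = tr$root) rev(postorder_rev(tr, from))

# reverse postorder = preorder with children pushed in order
postorder_rev <- function(tr, from) {
  out <- integer(length(tr$parent)); k <- 0L
  stack <- from
  while (length(stack)) {
    v <- stack[[length(stack)]]; stack <- stack[-length(stack)]
    k <- k + 1L; out[k] <- v
    kids <- tr$children[[v]]
    if (length(kids)) stack <- c(stack, kids)
  }
  out[seq_len(k)]
}

#' Leaf-label clusters for every node
#'
#' The cluster of a node is the set of leaf labels at or below it -- the
#' include side of the rooted split obtained by cutting the edge above the
#' node.
#' @param tr a `rooted_tree`
#' @return list of character vectors, indexed by node
#' @export
node_clusters <- function(tr) {
  cl <- vector("list", length(tr$parent))
  for (v in postorder(tr)) {
    kids <- tr$children[[v]]
    cl[[v]] <- if (!length(kids)) tr$label[v] else
      unlist(cl[kids], use.names = FALSE)
  }
  cl
}

#' Most recent common ancestor of a set of nodes
#' @param tr a `rooted_tree`
#' @param nodes integer node indices (at least one)
#' @export
mrca_node <- function(tr, nodes) {
  stopifnot(length(nodes) >= 1L)
  if (length(nodes) == 1L) return(nodes)
  anc <- function(v) {
    path <- v
    while (tr$parent[v] != 0L) { v <- tr$parent[v]; path <- c(path, v) }
    path
  }
  common <- anc(nodes[1])
  for (v in nodes[-1]) common <- intersect(common, anc(v))
  common[1]  # deepest shared ancestor comes first
}

node_by_label <- function(tr, lab) {
  hit <- which(!is.na(tr$label) & tr$label == lab)
  if (!length(hit)) stop("no node labelled '", lab, "'")
  hit[1]
}

# -- Newick I/O ----------------------------------------------------------------

#' Parse a Newick string into a rooted tree
#'
#' Dialect: unquoted labels, underscores literal (labels in this pipeline are
#' `ottX` identifiers, so the classic Newick space/underscore ambiguity never
#' arises), branch lengths parsed and discarded, square-bracket comments
#' stripped. Degree-two chains such as `"(a);"` are preserved.
#'
#' @param text a single Newick string (terminating `;` optional)
#' @param allow_duplicates keep duplicate leaf labels instead of erroring.
#'   Raw curated trees can legitimately carry duplicate tips; they are removed
#'   by [resolve_duplicate_and_nested_tips()]. Everywhere else a duplicate is
#'   an input error and is reported with the offending label.
#' @return a `rooted_tree`
#' @export
parse_newick <- function(text, allow_duplicates = FALSE) {
  stopifnot(is.character(text), length(text) == 1L)
  text <- gsub("\\[[^]]*\\]", "", text)
  text <- gsub("[[:space:]]", "", text)
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  np <- length(chars)
  i <- 1L
  n <- 0L
  parent <- integer(64); label <- character(64)
  grow <- function() {
    if (n > length(parent)) {
      length(parent) <<- 2L * n; length(label) <<- 2L * n
    }
  }
  add_node <- function(p) {
    n <<- n + 1L; grow(); parent[n] <<- p; label[n] <<- NA_character_; n
  }
  is_label_char <- function(ch) !(ch %in% c("(", ")", ",", ";", ":"))
  read_label <- function() {
    j <- i
    while (j <= np && is_label_char(chars[j])) j <- j + 1L
    lab <- if (j > i) paste(chars[i:(j - 1L)], collapse = "") else ""
    i <<- j
    lab
  }
  skip_blen <- function() {
    if (i <= np && chars[i] == ":") {
      i <<- i + 1L
      while (i <= np && is_label_char(chars[i])) i <<- i + 1L
    }
  }
  parse_clade <- function(p) {
    id <- add_node(p)
    if (i <= np && chars[i] == "(") {
      i <<- i + 1L
      repeat {
        parse_clade(id)
        if (i <= np && chars[i] == ",") { i <<- i + 1L } else break
      }
      if (i > np || chars[i] != ")") stop("malformed Newick: unbalanced '('")
      i <<- i + 1L
      lab <- read_label()
      if (nzchar(lab)) label[id] <<- lab
    } else {
      lab <- read_label()
      if (!nzchar(lab)) stop("malformed Newick: empty leaf label")
      label[id] <<- lab
    }
    skip_blen()
    id
  }
  parse_clade(0L)
  if (i <= np && chars[i] == ";") i <- i + 1L
  if (i <= np) stop("malformed Newick: trailing characters '",
                    paste(chars[i:np], collapse = ""), "'")
  tr <- rooted_tree(parent[seq_len(n)], label[seq_len(n)])
  ll <- leaf_labels(tr)
  if (!allow_duplicates && anyDuplicated(ll)) {
    stop("duplicate leaf label(s): ",
         paste(unique(ll[duplicated(ll)]), collapse = ", "))
  }
  tr
}

#' Serialize a rooted tree to Newick
#'
#' Internal labels are written after the closing parenthesis; no branch
#' lengths are emitted (they play no role in this method).
#' @param tr a `rooted_tree`
#' @return a Newick string ending in `;`
#' @export
write_newick <- function(tr) {
  fmt <- function(v) {
    lab <- tr$label[v]
    lab <- if (is.na(lab)) "" else lab
    kids <- tr$children[[v]]
    if (!length(kids)) return(lab)
    paste0("(", paste(vapply(kids, fmt, character(1)), collapse = ","), ")", lab)
  }
  paste0(fmt(tr$root), ";")
}

#' Read Newick trees from a file, one per line
#' @param path file with one Newick string per non-empty line
#' @param allow_duplicates passed to [parse_newick()]
#' @return list of `rooted_tree`
#' @export
read_newick <- function(path, allow_duplicates = FALSE) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lapply(lines[nzchar(lines)], parse_newick, allow_duplicates = allow_duplicates)
}

# -- structural surgery --------------------------------------------------------

# Rebuild a compacted rooted_tree keeping exactly the nodes in `keep`
# (logical), re-rooting at `new_root`. Each kept node is attached to its
# nearest kept proper ancestor; kept nodes above new_root are dropped.
compact_tree <- function(tr, keep, new_root = tr$root) {
  stopifnot(keep[new_root])
  ord <- preorder(tr, new_root)
  ord <- ord[keep[ord]]
  new_idx <- integer(length(tr$parent))
  new_idx[ord] <- seq_along(ord)
  np <- integer(length(ord)); lab <- character(length(ord))
  ids <- character(length(ord))
  for (k in seq_along(ord)) {
    v <- ord[k]
    p <- if (v == new_root) 0L else {
      a <- tr$parent[v]
      while (a != new_root && !keep[a]) a <- tr$parent[a]
      new_idx[a]
    }
    np[k] <- p; lab[k] <- tr$label[v]; ids[k] <- tr$node_id[v]
  }
  out <- rooted_tree(np, lab, node_id = ids)
  attr(out, "node_map") <- ord   # new index -> old index
  out
}

#' Extract the subtree rooted at a node
#' @param tr a `rooted_tree`
#' @param node node index
#' @export
subtree_at <- function(tr, node) {
  keep <- rep(FALSE, length(tr$parent))
  keep[preorder(tr, node)] <- TRUE
  compact_tree(tr, keep, new_root = node)
}

#' Restrict a tree to a set of leaf labels
#'
#' Keeps the named leaves and every node with at least one kept descendant;
#' the root is retained. Degree-one chains created by the restriction are kept
#' (use [suppress_knuckles()] to remove them); this is the taxonomy-pruning
#' semantics in which monotypic containers survive.
#' @param tr a `rooted_tree`
#' @param labels leaf labels to keep
#' @export
keep_leaf_set <- function(tr, labels) {
  lf <- is_leaf(tr)
  keep_leaf <- lf & !is.na(tr$label) & tr$label %in% labels
  if (!any(keep_leaf)) stop("none of the requested leaves are in the tree")
  keep <- keep_leaf
  for (v in postorder(tr)) {
    if (!lf[v]) keep[v] <- any(keep[tr$children[[v]]])
  }
  keep[tr$root] <- TRUE
  compact_tree(tr, keep)
}

#' Remove degree-one internal nodes
#'
#' Collapses out-degree-1 internal nodes; with `collapse_root = TRUE` a root
#' chain is collapsed too, the new root being the first node with out-degree
#' other than one. The surviving child keeps its own label.
#' @param tr a `rooted_tree`
#' @param collapse_root also collapse a single-child root chain
#' @export
suppress_knuckles <- function(tr, collapse_root = TRUE) {
  root <- tr$root
  if (collapse_root) {
    while (length(tr$children[[root]]) == 1L) root <- tr$children[[root]]
  }
  deg1 <- lengths(tr$children) == 1L
  keep <- !deg1
  keep[root] <- TRUE
  keep[is_leaf(tr)] <- TRUE
  compact_tree(tr, keep, new_root = root)
}

#' Contract an internal edge
#'
#' Removes the edge above `node`, reattaching its children to its parent.
#' Used by the support criterion: an edge is supported when contracting it
#' loses a displayed input split.
#' @param tr a `rooted_tree`
#' @param node a non-root internal node
#' @export
contract_edge <- function(tr, node) {
  if (node == tr$root) stop("cannot contract the root edge")
  if (!length(tr$children[[node]])) stop("cannot contract a terminal edge")
  keep <- rep(TRUE, length(tr$parent))
  keep[node] <- FALSE
  compact_tree(tr, keep)
}

# -- comparison ----------------------------------------------------------------

#' Canonical Newick form
#'
#' Children are ordered by their canonical subtree strings, making the output
#' invariant under branch rotation; two trees are isomorphic (as
#' leaf-labelled rooted trees) iff their canonical forms are equal.
#' @param tr a `rooted_tree`
#' @param use_internal_labels include internal labels in the canonical form
#' @export
canonical_newick <- function(tr, use_internal_labels = TRUE) {
  fmt <- function(v) {
    kids <- tr$children[[v]]
    lab <- tr$label[v]
    lab <- if (is.na(lab)) "" else lab
    if (!length(kids)) return(lab)
    if (!use_internal_labels) lab <- ""
    sub <- sort(vapply(kids, fmt, character(1)))
    paste0("(", paste(sub, collapse = ","), ")", lab)
  }
  paste0(fmt(tr$root), ";")
}

#' Test whether two rooted trees are isomorphic
#' @param a,b `rooted_tree` objects
#' @param use_internal_labels compare internal labels as well
#' @export
trees_isomorphic <- function(a, b, use_internal_labels = FALSE) {
  canonical_newick(a, use_internal_labels) ==
    canonical_newick(b, use_internal_labels)
}
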