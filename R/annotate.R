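# -- node provenance annotation ------------------------------------------------
#
# Relates every named summary node x to the nodes of each input tree i via
# the induced tree S(i) (the summary restricted to the input's leaves, with
# degree-one chains kept). Only input nodes whose bipartition conflicts
# with, is displayed by, or is resolved by x's bipartition are listed;
# compatible-but-irrelevant nodes are omitted, and trees whose induced tree
# does not contain x contribute nothing to x.

# per-tree classification; returns list: x summary-node index ->
# list(category -> character vector of input node ids)
annotate_one_tree <- function(summary, input) {
  L <- leaf_labels(input)
  missing <- setdiff(L, leaf_labels(summary))
  if (length(missing))
    stop("input leaves not in summary: ", paste(missing, collapse = ", "))
  si <- induce_tree(summary, L)
  node_map <- attr(si, "node_map")          # induced idx -> summary idx
  si_cl <- node_clusters(si)
  si_lf <- is_leaf(si)
  # group induced nodes by restricted cluster: multi-node groups are the
  # degree-one paths
  paths <- new.env(parent = emptyenv())
  for (v in seq_along(si$parent)) {
    k <- cluster_key(si_cl[[v]])
    paths[[k]] <- c(get0(k, envir = paths, inherits = FALSE), v)
  }
  in_cl <- node_clusters(input)
  in_lf <- is_leaf(input)
  out <- new.env(parent = emptyenv())
  note <- function(x_summary_idx, category, j_id) {
    key <- as.character(x_summary_idx)
    rec <- get0(key, envir = out, inherits = FALSE) %||% list()
    rec[[category]] <- c(rec[[category]], j_id)
    out[[key]] <- rec
  }
  conflicted_x <- logical(length(si$parent))
  displayed_keys <- character(0)
  for (j in seq_along(input$parent)) {
    if (j == input$root) next
    C_j <- in_cl[[j]]
    path <- get0(cluster_key(C_j), envir = paths, inherits = FALSE)
    if (!is.null(path)) {
      displayed_keys <- c(displayed_keys, cluster_key(C_j))
      category <- if (in_lf[j]) "terminal"
        else if (length(path) > 1L) "partial_path_of" else "supported_by"
      for (x in path) note(node_map[x], category, input$node_id[j])
      next
    }
    if (length(C_j) < 2L || length(C_j) == length(L)) next  # trivial
    # not displayed: list every conflicting summary node, else resolved_by
    any_conflict <- FALSE
    for (x in seq_along(si$parent)) {
      I_x <- si_cl[[x]]
      if (length(I_x) < 2L || length(I_x) == length(L)) next
      if (any(I_x %in% C_j) && !all(I_x %in% C_j) && !all(C_j %in% I_x)) {
        note(node_map[x], "conflicts_with", input$node_id[j])
        conflicted_x[x] <- TRUE
        any_conflict <- TRUE
      }
    }
    if (!any_conflict) {
      # compatible but absent: could resolve a summary polytomy
      tips <- which(si_lf & si$label %in% C_j)
      x <- mrca_node(si, tips)
      kids <- si$children[[x]]
      inter <- vapply(kids, function(k2) {
        n_in <- sum(si_cl[[k2]] %in% C_j)
        if (n_in > 0L && n_in < length(si_cl[[k2]])) NA else n_in > 0L
      }, logical(1))
      if (!anyNA(inter) && sum(inter) >= 2L && sum(inter) < length(kids))
        note(node_map[x], "resolved_by", input$node_id[j])
    }
  }
  # resolves: x's grouping would refine a soft polytomy of the input
  in_paths <- new.env(parent = emptyenv())
  for (j in seq_along(input$parent)) {
    k <- cluster_key(in_cl[[j]])
    if (is.null(get0(k, envir = in_paths, inherits = FALSE)))
      in_paths[[k]] <- j
  }
  for (x in seq_along(si$parent)) {
    I_x <- si_cl[[x]]
    if (length(I_x) < 2L || length(I_x) == length(L)) next
    if (conflicted_x[x]) next
    if (!is.null(get0(cluster_key(I_x), envir = in_paths, inherits = FALSE)))
      next  # displayed by the input
    tips <- which(in_lf & input$label %in% I_x)
    j <- mrca_node(input, tips)
    kids <- input$children[[j]]
    inter <- vapply(kids, function(k2) {
      n_in <- sum(in_cl[[k2]] %in% I_x)
      if (n_in > 0L && n_in < length(in_cl[[k2]])) NA else n_in > 0L
    }, logical(1))
    if (!anyNA(inter) && sum(inter) >= 2L && sum(inter) < length(kids))
      note(node_map[x], "resolves", input$node_id[j])
  }
  out
}

annotation_categories <- c("supported_by", "partial_path_of", "terminal",
                           "conflicts_with", "resolves", "resolved_by")

#' Annotate a summary tree against its ranked inputs
#'
#' Produces the node-provenance document: for every named summary node, the
#' input tree nodes that support it, lie on its displayed path, conflict
#' with it, are resolved by it, or could resolve it. The taxonomy
#' participates as an ordinary (lowest-ranked) input tree. For a summary
#' produced by this pipeline from the same inputs, every `resolved_by` list
#' is empty -- the tree contains no unnecessary polytomies.
#'
#' @param summary a fully named summary tree ([name_nodes()])
#' @param inputs named list of input `rooted_tree`s in rank order, taxonomy
#'   last; every input leaf must occur in the summary
#' @param run_id optional identifier recorded in the metadata
#' @return an `annotation_doc`: `metadata` (run id, tree ids, ranks) and
#'   `nodes` (summary-node name -> category -> tree id -> sorted input node
#'   ids); serialization is deterministic.
#' @export
annotate_summary <- function(summary, inputs, run_id = "synthesis") {
  if (anyNA(summary$label))
    stop("summary has unnamed nodes; run name_nodes() first")
  if (is.null(names(inputs)) || !all(nzchar(names(inputs))))
    stop("inputs must be a named list (tree ids)")
  nodes <- list()
  for (tid in names(inputs)) {
    ann <- annotate_one_tree(summary, inputs[[tid]])
    for (key in ls(ann)) {
      x_name <- summary$label[as.integer(key)]
      rec <- ann[[key]]
      for (category in names(rec)) {
        nodes[[x_name]][[category]][[tid]] <-
          sort(unique(rec[[category]]))
      }
    }
  }
  # deterministic ordering: node names, categories, tree ids
  nodes <- nodes[order(names(nodes))]
  nodes <- lapply(nodes, function(rec) {
    rec <- rec[intersect(annotation_categories, names(rec))]
    lapply(rec, function(bytree) bytree[order(names(bytree))])
  })
  structure(list(metadata = list(run_id = run_id,
                                 trees = names(inputs),
                                 ranks = seq_along(inputs)),
                 nodes = nodes),
            class = "annotation_doc")
}

#' @export
print.annotation_doc <- function(x, ...) {
  counts <- annotation_counts(x)
  cat("annotation_doc:", length(x$nodes), "summary nodes;",
      paste(names(counts), unlist(counts), sep = "=", collapse = " "), "\n")
  invisible(x)
}

#' Classify one summary node against one input tree
#'
#' @param summary a named summary tree
#' @param x a summary node name
#' @param input an input `rooted_tree`
#' @return named list (category -> input node ids); empty when the node is
#'   absent from the induced tree
#' @export
classify_node <- function(summary, x, input) {
  idx <- node_by_label(summary, x)
  ann <- annotate_one_tree(summary, input)
  get0(as.character(idx), envir = ann, inherits = FALSE) %||% list()
}

#' Per-category totals of an annotation document
#'
#' Counts, for each category, the number of (tree, input node) pairs listed
#' under it anywhere in the summary -- each input split lands in one
#' displayed category, or in conflicts_with / resolved_by.
#' @param doc an `annotation_doc`
#' @export
annotation_counts <- function(doc) {
  seen <- stats::setNames(vector("list", length(annotation_categories)),
                          annotation_categories)
  for (category in annotation_categories) seen[[category]] <- character(0)
  for (rec in doc$nodes) {
    for (category in names(rec)) {
      for (tid in names(rec[[category]])) {
        key <- paste(tid, rec[[category]][[tid]])
        seen[[category]] <- union(seen[[category]], key)
      }
    }
  }
  lapply(seen, length)
}
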