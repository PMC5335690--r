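# -- end-to-end synthesis pipeline ---------------------------------------------

#' Run the full ranked supertree synthesis
#'
#' Orchestrates every stage: taxonomy flag-cleaning, input cleaning,
#' exemplification, uncontested-taxon decomposition, greedy ranked solving,
#' grafting, unpruning, naming, and annotation. With an empty tree list the
#' output is the flag-cleaned taxonomy itself.
#'
#' @param config a list (or path to a YAML file) with elements:
#'   \describe{
#'     \item{taxonomy}{a [taxonomy()] object or path to `taxonomy.tsv`}
#'     \item{forwards}{optional path to `forwards.tsv` (when `taxonomy` is a
#'       path)}
#'     \item{trees}{named list of `rooted_tree`s, or character vector of
#'       Newick file paths (one tree per file), in rank order (highest
#'       first)}
#'     \item{prune_flags}{character vector of taxonomy flags to prune
#'       (required; may be empty)}
#'     \item{root}{optional uid: restrict the synthesis to this taxon}
#'     \item{broken_attach}{`"mrca"` (default) or `"ancestor"`, see
#'       [unprune_taxa()]}
#'     \item{out_dir}{optional directory; when given, every stage writes its
#'       artifacts there}
#'     \item{run_id}{optional identifier for the annotation metadata}
#'   }
#' @return a `synthesis` object: the flag-cleaned taxonomy, cleaned /
#'   exemplified trees, subproblems and solutions, the grafted tree, the
#'   labelled supertree, the annotation document, and a `report` of summary
#'   statistics (subproblem census, split-category totals).
#' @export
run_synthesis <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config$prune_flags))
    stop("config$prune_flags is required (may be an empty vector)")
  tax <- config$taxonomy
  if (is.character(tax)) tax <- load_taxonomy(tax, config$forwards)
  if (!inherits(tax, "taxonomy")) stop("config$taxonomy must be a taxonomy")
  trees <- config$trees %||% list()
  if (is.character(trees)) {
    paths <- trees
    trees <- lapply(paths, function(p) read_newick(p, allow_duplicates = TRUE)[[1]])
    names(trees) <- sub("\\.[^.]*$", "", basename(paths))
  }
  run_id <- config$run_id %||% "synthesis"

  tax_clean <- prune_flagged(tax, config$prune_flags)
  if (!is.null(config$root)) {
    rl <- if (is.numeric(config$root)) ott_label(config$root) else config$root
    node <- node_by_label(tax_clean$tree, rl)
    tax_clean$tree <- subtree_at(tax_clean$tree, node)
    keep <- ott_uid(tax_clean$tree$label)
    tax_clean$records <- tax_clean$records[tax_clean$records$uid %in% keep, ]
    tax_clean$records$parent_uid[tax_clean$records$uid == ott_uid(rl)] <-
      NA_integer_
  }

  cleaned <- clean_input_trees(trees, tax_clean)

  if (!length(cleaned$trees)) {
    labelled <- tax_clean$tree
    annotation <- annotate_summary(labelled,
                                   list(taxonomy = tax_clean$tree), run_id)
    res <- structure(
      list(taxonomy = tax_clean, cleaned = cleaned,
           exemplar_map = list(), exemplified = list(),
           pruned_taxonomy = tax_clean$tree, subproblems = list(),
           solutions = list(), rejections = empty_rejections(),
           grafted = tax_clean$tree, labelled = labelled,
           annotation = annotation,
           report = synthesis_report(list(), list(), empty_rejections(),
                                     annotation, trees)),
      class = "synthesis")
    if (!is.null(config$out_dir)) write_stage_dirs(res, config$out_dir)
    return(res)
  }

  exmap <- compute_exemplars(cleaned$trees, tax_clean)
  exemplified <- lapply(cleaned$trees, exemplify_tree, map = exmap)
  sampled <- unique(unlist(lapply(exemplified, leaf_labels)))
  taxp <- prune_taxonomy_to_sampled(tax_clean, sampled)

  subproblems <- build_subproblems(exemplified, taxp)
  solutions <- lapply(subproblems, solve_subproblem)
  rejections <- do.call(rbind, c(list(empty_rejections()), lapply(
    names(solutions), function(nm) {
      rj <- attr(solutions[[nm]], "rejections")
      if (nrow(rj)) cbind(subproblem = nm, rj) else NULL
    })))

  grafted <- graft_solutions(solutions)
  labelled <- name_nodes(
    unprune_taxa(grafted, tax_clean,
                 broken_attach = config$broken_attach %||% "mrca"),
    tax_clean)
  annotation <- annotate_summary(
    labelled, c(exemplified, list(taxonomy = tax_clean$tree)), run_id)

  res <- structure(
    list(taxonomy = tax_clean, cleaned = cleaned, exemplar_map = exmap,
         exemplified = exemplified, pruned_taxonomy = taxp,
         subproblems = subproblems, solutions = solutions,
         rejections = rejections, grafted = grafted, labelled = labelled,
         annotation = annotation,
         report = synthesis_report(subproblems, solutions, rejections,
                                   annotation, trees)),
    class = "synthesis")
  if (!is.null(config$out_dir)) write_stage_dirs(res, config$out_dir)
  res
}

empty_rejections <- function() {
  data.frame(subproblem = character(0), rank = integer(0),
             tree_id = character(0), node_id = character(0),
             reason = character(0))
}

synthesis_report <- function(subproblems, solutions, rejections, annotation,
                             raw_trees) {
  tips <- vapply(subproblems, function(sp) length(sp$universe), integer(1))
  ntrees <- vapply(subproblems, function(sp) length(sp$trees) + 1L, integer(1))
  phylo_ids <- setdiff(annotation$metadata$trees, "taxonomy")
  list(
    n_input_trees = length(raw_trees),
    n_subproblems = length(subproblems),
    n_trivial_by_tips = sum(tips <= 2L),
    n_trivial_by_trees = sum(ntrees <= 2L),
    n_nontrivial = sum(tips > 2L & ntrees > 2L),
    largest_subproblem_tips = if (length(tips)) max(tips) else 0L,
    largest_subproblem_trees = if (length(ntrees)) max(ntrees) else 0L,
    n_rejected_splits = nrow(rejections),
    input_split_categories = annotation_counts_for(annotation, phylo_ids),
    taxonomy_split_categories = annotation_counts_for(annotation, "taxonomy"))
}

# category totals restricted to a subset of input trees
annotation_counts_for <- function(doc, tree_ids) {
  doc$nodes <- lapply(doc$nodes, function(rec) {
    lapply(rec, function(bytree) bytree[names(bytree) %in% tree_ids])
  })
  annotation_counts(doc)
}

#' @export
print.synthesis <- function(x, ...) {
  r <- x$report
  cat("supertree synthesis:", n_leaves(x$labelled), "leaves\n")
  cat("  subproblems:", r$n_subproblems,
      "(trivial by tips:", r$n_trivial_by_tips,
      ", by trees:", r$n_trivial_by_trees,
      "); largest:", r$largest_subproblem_tips, "tips\n")
  ic <- r$input_split_categories
  cat("  input splits: supported_by", ic$supported_by,
      "partial_path_of", ic$partial_path_of,
      "conflicts_with", ic$conflicts_with,
      "resolved_by", ic$resolved_by, "\n")
  invisible(x)
}

#' Slice a summary tree back into input trees at taxonomy nodes
#'
#' The reliability round-trip: the named summary is split at every node
#' carrying a taxonomy (`ottX`) label, so that each slice has a taxonomy
#' node at its root and taxonomy nodes (or terminal tips) at its tips but no
#' taxonomy nodes internally. Tips that are internal taxa are then replaced
#' with a leaf taxon (the smallest-uid terminal descendant), so the slices
#' are valid phylogenetic inputs. Contested taxa in the original run remain
#' contested: their structure sits strictly inside one slice. Re-running the
#' synthesis on these slices plus the same taxonomy reproduces the summary.
#'
#' @param summary the labelled supertree
#' @param tax the flag-cleaned [taxonomy()]
#' @return named list of `rooted_tree` slices (slices with fewer than 3 tips
#'   carry no grouping information and are omitted)
#' @export
slice_for_roundtrip <- function(summary, tax) {
  is_tax_label <- !is.na(summary$label) &
    summary$label %in% tax$tree$label
  lf <- is_leaf(summary)
  term <- terminal_taxa(tax)
  cl <- node_clusters(tax$tree)
  rep_tip <- function(lab) {   # internal taxon -> smallest-uid terminal
    if (lab %in% term) return(lab)
    below <- cl[[node_by_label(tax$tree, lab)]]
    below[which.min(ott_uid(below))]
  }
  out <- list()
  for (t in which(is_tax_label & !lf)) {
    # walk down, stopping at taxonomy-labelled nodes
    keep <- rep(FALSE, length(summary$parent))
    stack <- t
    while (length(stack)) {
      v <- stack[[length(stack)]]; stack <- stack[-length(stack)]
      keep[v] <- TRUE
      if (v != t && (lf[v] || is_tax_label[v])) next
      stack <- c(stack, summary$children[[v]])
    }
    sl <- compact_tree(summary, keep, new_root = t)
    if (n_leaves(sl) < 3L) next
    # tips that are internal taxa become representative terminal leaves;
    # non-taxonomy internal labels are stripped
    slf <- is_leaf(sl)
    for (v in which(slf)) sl$label[v] <- rep_tip(sl$label[v])
    sl$label[!slf & !sl$label %in% tax$tree$label] <- NA_character_
    out[[paste0("slice_", summary$label[t])]] <- sl
  }
  out
}

#' Check the reliability round-trip on a finished synthesis
#'
#' @param result a `synthesis` object
#' @return list with `slices`, the re-synthesis `result`, and `identical`
#'   (exact equality of the two labelled supertrees)
#' @export
roundtrip_check <- function(result) {
  slices <- slice_for_roundtrip(result$labelled, result$taxonomy)
  res2 <- run_synthesis(list(taxonomy = result$taxonomy, trees = slices,
                             prune_flags = character(0)))
  list(slices = slices, result = res2,
       identical = canonical_newick(res2$labelled) ==
         canonical_newick(result$labelled))
}

# -- staged artifact output ----------------------------------------------------

write_stage_dirs <- function(res, out_dir) {
  mk <- function(...) {
    d <- file.path(out_dir, ...)
    dir.create(d, recursive = TRUE, showWarnings = FALSE)
    d
  }
  d <- mk("cleaned_ott")
  write_taxonomy(res$taxonomy, file.path(d, "taxonomy.tsv"),
                 file.path(d, "forwards.tsv"))
  d <- mk("cleaned_phylo")
  for (id in names(res$cleaned$trees))
    writeLines(write_newick(res$cleaned$trees[[id]]),
               file.path(d, paste0(id, ".tre")))
  utils::write.table(res$cleaned$log, file.path(d, "pruned_tips.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  d <- mk("exemplified_phylo")
  for (id in names(res$exemplified))
    writeLines(write_newick(res$exemplified[[id]]),
               file.path(d, paste0(id, ".tre")))
  jsonlite::write_json(res$exemplar_map, file.path(d, "exemplar_map.json"))
  writeLines(write_newick(res$pruned_taxonomy),
             file.path(d, "pruned_taxonomy.tre"))
  writeLines(attr(res$pruned_taxonomy, "pruned_tips") %||% character(0),
             file.path(d, "pruned_tips.txt"))
  d <- mk("subproblems")
  for (nm in names(res$subproblems)) {
    sp <- res$subproblems[[nm]]
    writeLines(c(vapply(sp$trees, write_newick, character(1)),
                 write_newick(sp$taxonomy)),
               file.path(d, paste0(nm, ".tre")))
    writeLines(c(names(sp$trees), "taxonomy"),
               file.path(d, paste0(nm, "-tree-names.txt")))
  }
  d <- mk("subproblem_solutions")
  for (nm in names(res$solutions))
    writeLines(write_newick(res$solutions[[nm]]),
               file.path(d, paste0(nm, ".tre")))
  utils::write.table(res$rejections, file.path(d, "rejections.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  writeLines(write_newick(res$grafted),
             file.path(mk("grafted_solution"), "grafted_solution.tre"))
  writeLines(write_newick(res$labelled),
             file.path(mk("labelled_supertree"), "labelled_supertree.tre"))
  d <- mk("annotated_supertree")
  jsonlite::write_json(unclass(res$annotation),
                       file.path(d, "annotations.json"), auto_unbox = TRUE)
  yaml::write_yaml(res$report, file.path(out_dir, "report.yaml"))
  invisible(out_dir)
}
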