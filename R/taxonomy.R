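# -- taxonomy ------------------------------------------------------------------
#
# The reference taxonomy is a rooted tree over taxa identified by integer
# uids. Node labels are "ott<uid>" so that taxonomy nodes and tree tips share
# one label space. Flag-based pruning and id forwarding happen here; a uid
# pruned by flags is afterwards indistinguishable from an invalid uid.

ott_label <- function(uid) paste0("ott", uid)

ott_uid <- function(label) {
  uid <- suppressWarnings(as.integer(sub("^ott", "", label)))
  uid[!grepl("^ott[0-9]+$", label)] <- NA_integer_
  uid
}

#' Construct a taxonomy object
#'
#' @param records data.frame with columns `uid` (integer, unique),
#'   `parent_uid` (integer, `NA` for the root), `name`, `rank`, and `flags`
#'   (comma-separated string, possibly empty).
#' @param forwards data.frame with columns `old_uid`, `new_uid`, or `NULL`.
#' @return an object of class `taxonomy`: the taxonomy tree (labels
#'   `ott<uid>`), the per-taxon records, the forwarding map, and the set of
#'   uids removed by flag pruning (initially empty).
#' @export
taxonomy <- function(records, forwards = NULL) {
  req <- c("uid", "parent_uid", "name", "rank", "flags")
  if (!all(req %in% names(records)))
    stop("taxonomy records need columns: ", paste(req, collapse = ", "))
  records$uid <- as.integer(records$uid)
  records$parent_uid <- suppressWarnings(as.integer(records$parent_uid))
  records$flags <- as.character(records$flags)
  records$flags[is.na(records$flags)] <- ""
  if (anyDuplicated(records$uid))
    stop("duplicate uid: ",
         paste(unique(records$uid[duplicated(records$uid)]), collapse = ", "))
  root_rows <- which(is.na(records$parent_uid))
  if (length(root_rows) != 1L) stop("taxonomy must have exactly one root")
  idx <- match(records$parent_uid, records$uid)
  orphan <- which(!is.na(records$parent_uid) & is.na(idx))
  if (length(orphan))
    stop("parent uid missing for taxa: ",
         paste(records$uid[orphan], collapse = ", "))
  parent <- ifelse(is.na(idx), 0L, idx)
  # node ids are the taxon labels, so reports cite taxa directly
  tr <- rooted_tree(parent, ott_label(records$uid),
                    node_id = ott_label(records$uid))  # also detects cycles
  fw <- integer(0)
  if (!is.null(forwards) && nrow(forwards)) {
    fw <- as.integer(forwards$new_uid)
    names(fw) <- as.character(as.integer(forwards$old_uid))
  }
  structure(list(tree = tr, records = records, forwards = fw,
                 pruned = integer(0)),
            class = "taxonomy")
}

#' @export
print.taxonomy <- function(x, ...) {
  cat("taxonomy:", nrow(x$records), "taxa,",
      length(terminal_taxa(x)), "terminal;",
      length(x$forwards), "forwards,",
      length(x$pruned), "flag-pruned uids\n")
  invisible(x)
}

#' Load a taxonomy from OTT-style distribution files
#'
#' `taxonomy.tsv` has a header line and one row per taxon, fields separated
#' by the literal five-byte sequence tab-pipe-tab (`"\t|\t"`): uid,
#' parent_uid, name, rank, flags (flags comma-separated). `forwards.tsv` has
#' two tab-separated columns: old id, new id.
#'
#' @param path path to `taxonomy.tsv`
#' @param forwards_path optional path to `forwards.tsv`
#' @return a [taxonomy()] object
#' @export
load_taxonomy <- function(path, forwards_path = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty taxonomy file: ", path)
  fields <- strsplit(lines, "\t|\t", fixed = TRUE)
  if (tolower(fields[[1]][1]) == "uid") fields <- fields[-1]
  get <- function(k) vapply(fields, function(f) {
    if (length(f) >= k) f[k] else ""
  }, character(1))
  records <- data.frame(
    uid = as.integer(get(1)),
    parent_uid = suppressWarnings(as.integer(get(2))),
    name = get(3), rank = get(4), flags = get(5),
    stringsAsFactors = FALSE)
  forwards <- NULL
  if (!is.null(forwards_path)) {
    fl <- readLines(forwards_path, warn = FALSE)
    fl <- fl[nzchar(trimws(fl))]
    if (length(fl) && grepl("^id|^old", tolower(fl[1]))) fl <- fl[-1]
    if (length(fl)) {
      parts <- strsplit(fl, "\t", fixed = TRUE)
      forwards <- data.frame(
        old_uid = as.integer(vapply(parts, `[`, character(1), 1)),
        new_uid = as.integer(vapply(parts, `[`, character(1), 2)))
    }
  }
  taxonomy(records, forwards)
}

#' Write a taxonomy back to the OTT distribution dialect
#' @param tax a [taxonomy()] object
#' @param path output path for `taxonomy.tsv`
#' @param forwards_path optional output path for `forwards.tsv`
#' @export
write_taxonomy <- function(tax, path, forwards_path = NULL) {
  r <- tax$records
  hdr <- paste(c("uid", "parent_uid", "name", "rank", "flags"),
               collapse = "\t|\t")
  rows <- paste(r$uid,
                ifelse(is.na(r$parent_uid), "", r$parent_uid),
                r$name, r$rank, r$flags, sep = "\t|\t")
  writeLines(c(hdr, rows), path)
  if (!is.null(forwards_path)) {
    writeLines(c("id\treplacement",
                 paste(names(tax$forwards), tax$forwards, sep = "\t")),
               forwards_path)
  }
  invisible(tax)
}

taxon_flags <- function(tax, uid) {
  f <- tax$records$flags[match(uid, tax$records$uid)]
  if (is.na(f) || !nzchar(f)) character(0) else
    trimws(strsplit(f, ",", fixed = TRUE)[[1]])
}

#' Terminal taxa of a taxonomy
#'
#' A terminal taxon is a leaf of the (flag-cleaned) taxonomy; every tip of a
#' cleaned input tree must map to one.
#' @param tax a [taxonomy()] object
#' @return character vector of `ott<uid>` labels
#' @export
terminal_taxa <- function(tax) leaf_labels(tax$tree)

#' Prune flagged subtrees from a taxonomy
#'
#' Every taxon whose flag set intersects `prune_flags` is removed together
#' with its whole subtree. Pruned uids are recorded in `$pruned` and are from
#' then on treated in the same way as invalid ids by [forward_id()]. Flag
#' matching is exact string membership; the flag vocabulary is supplied by
#' the run configuration, not hard-coded.
#'
#' @param tax a [taxonomy()] object
#' @param prune_flags character vector of flags (e.g. `"unplaced"`,
#'   `"barren"`)
#' @return the pruned [taxonomy()] (idempotent; identity when
#'   `prune_flags` is empty)
#' @export
prune_flagged <- function(tax, prune_flags) {
  prune_flags <- as.character(prune_flags)
  if (!length(prune_flags)) return(tax)
  r <- tax$records
  flagged <- vapply(seq_len(nrow(r)), function(i) {
    any(taxon_flags(tax, r$uid[i]) %in% prune_flags)
  }, logical(1))
  if (!any(flagged)) return(tax)
  tr <- tax$tree
  hit_nodes <- match(ott_label(r$uid[flagged]), tr$label)
  if (tr$root %in% hit_nodes) stop("refusing to prune the taxonomy root")
  drop <- rep(FALSE, length(tr$parent))
  for (v in hit_nodes) drop[preorder(tr, v)] <- TRUE
  dropped_uids <- ott_uid(tr$label[drop])
  keep_uid <- setdiff(r$uid, dropped_uids)
  out <- tax
  out$records <- r[r$uid %in% keep_uid, , drop = FALSE]
  out$tree <- compact_tree(tr, !drop)
  out$pruned <- sort(unique(c(tax$pruned, dropped_uids)))
  out
}

#' Resolve a (possibly forwarded) OTT id to a live taxon
#'
#' Chases the forwarding map until a live taxon is reached. Unknown ids and
#' ids pruned by flags resolve to `NA` (invalid); a forwarding cycle is an
#' error.
#' @param tax a [taxonomy()] object
#' @param id integer uid
#' @return the live uid, or `NA_integer_` when invalid
#' @export
forward_id <- function(tax, id) {
  id <- as.integer(id)
  seen <- integer(0)
  while (as.character(id) %in% names(tax$forwards)) {
    if (id %in% seen) stop("forwarding cycle at uid ", id)
    seen <- c(seen, id)
    id <- tax$forwards[[as.character(id)]]
  }
  if (id %in% tax$records$uid) id else NA_integer_
}

#' The rooted split of a taxon over a leaf universe
#'
#' @param tax a [taxonomy()] object
#' @param t a taxon (integer uid or `ott<uid>` label)
#' @param universe character vector of taxon labels (typically the leaf set
#'   of an input tree)
#' @return a `rooted_split` with include = terminal descendants of `t`
#'   intersected with the universe, or `NULL` when that intersection is empty
#'   (degenerate marker). A monotypic parent and its child yield identical
#'   splits.
#' @export
taxon_split <- function(tax, t, universe) {
  lab <- if (is.numeric(t)) ott_label(t) else as.character(t)
  node <- node_by_label(tax$tree, lab)
  below <- node_clusters(tax$tree)[[node]]
  inc <- intersect(universe, below)
  if (!length(inc)) return(NULL)
  rooted_split(inc, setdiff(universe, inc))
}
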