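#' Build a taxonomy from a data frame
#'
#' The tree is stored as parent / rank / name lookup tables keyed by taxid.
#' Exactly one node must be its own parent (the root); every other node's
#' parent chain must reach the root without cycles.
#'
#' @param df data frame with columns `taxid`, `parent`, `rank`, `name`
#'   (`name` optional).
#' @return An object of class `skim_taxonomy`.
#' @examples
#' tree <- as_taxonomy(data.frame(
#'   taxid = c(1, 10, 11), parent = c(1, 1, 10),
#'   rank = c("no rank", "genus", "species"),
#'   name = c("root", "GenusA", "SpeciesA1")))
#' lca(tree, c(11, 10))  # 10
#' @export
as_taxonomy <- function(df) {
  need <- c("taxid", "parent", "rank")
  if (!all(need %in% names(df)))
    stop("taxonomy needs columns: ", paste(need, collapse = ", "))
  taxid <- as.character(as.integer(df$taxid))
  if (anyDuplicated(taxid)) stop("duplicated taxids in taxonomy")
  parent <- setNames(as.character(as.integer(df$parent)), taxid)
  rank <- setNames(as.character(df$rank), taxid)
  name <- if ("name" %in% names(df)) setNames(as.character(df$name), taxid)
          else setNames(taxid, taxid)
  missing <- setdiff(unique(parent), taxid)
  if (length(missing))
    stop("parent taxid(s) absent from taxonomy: ",
         paste(head(missing, 5L), collapse = ", "))
  roots <- taxid[parent[taxid] == taxid]
  if (length(roots) != 1L)
    stop("taxonomy must have exactly one root (node with parent == itself); found ",
         length(roots))
  tree <- structure(
    list(parent = parent, rank = rank, name = name, root = roots),
    class = "skim_taxonomy")
  # cycle check: every chain must reach the root within n steps
  n <- length(taxid)
  for (id in taxid) {
    cur <- id; steps <- 0L
    while (cur != tree$root) {
      cur <- parent[[cur]]
      steps <- steps + 1L
      if (steps > n) stop("cycle detected in taxonomy at taxid ", id)
    }
  }
  tree
}

#' Load a taxonomy from disk
#'
#' Two dialects are accepted: the NCBI taxdump convention (`nodes.dmp` with
#' `"\t|\t"`-separated fields `taxid | parent | rank | ...`, plus an optional
#' `names.dmp` from which scientific names are taken), and a simple
#' tab-separated table with a header line `taxid  parent  rank  name` for
#' synthetic fixtures.  The dialect is sniffed from the first line.
#'
#' @param nodes path to `nodes.dmp` or to the TSV table.
#' @param names optional path to `names.dmp` (NCBI dialect only).
#' @return A `skim_taxonomy` (see [as_taxonomy()]).
#' @export
load_taxonomy <- function(nodes, names = NULL) {
  if (!file.exists(nodes)) stop("cannot read taxonomy file: ", nodes)
  first <- readLines(nodes, n = 1L)
  if (grepl("\t|\t", first, fixed = TRUE)) {
    fields <- strsplit(readLines(nodes), "\t\\|\t?")
    df <- data.frame(
      taxid = vapply(fields, `[`, "", 1L),
      parent = vapply(fields, `[`, "", 2L),
      rank = vapply(fields, `[`, "", 3L),
      stringsAsFactors = FALSE)
    if (!is.null(names) && file.exists(names)) {
      nf <- strsplit(readLines(names), "\t\\|\t?")
      cls <- vapply(nf, `[`, "", 4L)
      cls <- sub("\t\\|$", "", cls)
      sci <- vapply(nf, `[`, "", 1L)[cls == "scientific name"]
      nm <- vapply(nf, `[`, "", 2L)[cls == "scientific name"]
      df$name <- nm[match(df$taxid, sci)]
      df$name[is.na(df$name)] <- df$taxid[is.na(df$name)]
    }
  } else {
    df <- read.delim(nodes, stringsAsFactors = FALSE)
  }
  as_taxonomy(df)
}

#' @export
print.skim_taxonomy <- function(x, ...) {
  cat(sprintf("skim_taxonomy: %d nodes, root %s, ranks: %s\n",
              length(x$parent), x$root,
              paste(head(sort(unique(x$rank)), 8L), collapse = ", ")))
  invisible(x)
}

check_taxids <- function(tree, taxids) {
  ids <- as.character(as.integer(taxids))
  bad <- setdiff(ids, names(tree$parent))
  if (length(bad))
    stop("taxid(s) not in taxonomy: ", paste(head(bad, 5L), collapse = ", "))
  ids
}

#' Root-to-node lineage
#'
#' @param tree a `skim_taxonomy`.
#' @param taxid a single taxid present in the tree.
#' @return Integer vector of taxids starting at the root and ending at
#'   `taxid`.
#' @export
lineage_of <- function(tree, taxid) {
  id <- check_taxids(tree, taxid)
  if (length(id) != 1L) stop("taxid must be a single id")
  path <- id
  while (id != tree$root) {
    id <- tree$parent[[id]]
    path <- c(id, path)
  }
  as.integer(path)
}

#' Rank and name lookups
#'
#' @param tree a `skim_taxonomy`.
#' @param taxid taxid(s) present in the tree.
#' @return Character vector of rank labels (or names).
#' @export
rank_of <- function(tree, taxid) {
  unname(tree$rank[check_taxids(tree, taxid)])
}

#' @rdname rank_of
#' @export
name_of <- function(tree, taxid) {
  unname(tree$name[check_taxids(tree, taxid)])
}

#' Lowest common ancestor
#'
#' The deepest node ancestral to (or equal to) every input taxid.  `lca` of a
#' single taxon is that taxon; `lca` of a node and one of its ancestors is
#' the ancestor.
#'
#' @param tree a `skim_taxonomy`.
#' @param taxids non-empty vector of taxids present in the tree.
#' @return A single taxid (integer).
#' @export
lca <- function(tree, taxids) {
  ids <- unique(check_taxids(tree, taxids))
  if (length(ids) == 0L) stop("taxids must be non-empty")
  lin <- lineage_of(tree, ids[1L])
  for (id in ids[-1L]) {
    other <- lineage_of(tree, id)
    d <- min(length(lin), length(other))
    eq <- lin[seq_len(d)] == other[seq_len(d)]
    lin <- lin[seq_len(if (all(eq)) d else which(!eq)[1L] - 1L)]
  }
  lin[length(lin)]
}

#' Ancestor of a taxon at a given rank
#'
#' Walks the lineage of `taxid` from the root and returns the node whose rank
#' label equals `rank`, or `NA` when the lineage has no such rank.
#'
#' @param tree a `skim_taxonomy`.
#' @param taxid a single taxid.
#' @param rank rank label, e.g. `"genus"`.
#' @return A taxid or `NA_integer_`.
#' @export
ancestor_at_rank <- function(tree, taxid, rank) {
  lin <- lineage_of(tree, taxid)
  hit <- lin[tree$rank[as.character(lin)] == rank]
  if (length(hit)) hit[length(hit)] else NA_integer_
}
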