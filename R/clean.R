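# Contaminant screening of genome skims prior to indexing.
#
# Each screening group (bacteria, fungi, algae, human, plus the target
# clade) is one ordinary index entry; reads are pushed through the same
# shared-k-mer / LCA assignment used for metagenome queries, with the group
# taxids sitting as leaves under a common root.

#' Conventional taxids for the screening groups
#'
#' Named after the NCBI clades customarily screened from plant tissue
#' extracts: Bacteria (2), fungi (4751), algae (2763), human (9606), and the
#' target clade Viridiplantae (33090).  Unknown group names are given
#' sequential ids above 10^6.
#' @keywords internal
#' @noRd
cleaning_taxid <- function(groups) {
  known <- c(bacteria = 2L, fungi = 4751L, algae = 2763L, human = 9606L,
             target = 33090L, viridiplantae = 33090L)
  ids <- known[tolower(groups)]
  ids[is.na(ids)] <- 1000000L + seq_len(sum(is.na(ids)))
  setNames(as.integer(ids), groups)
}

#' Build a cleaning index from contaminant and target references
#'
#' @param contaminants named list of sequence sets (character vectors or file
#'   paths), one per contaminant group, e.g.
#'   `list(bacteria = ..., fungi = ...)`.
#' @param target sequence set representing the target clade.
#' @param params a [skim_params()].
#' @return A `kmer_index` over the groups, with the flat group taxonomy
#'   attached as attribute `"taxonomy"` and the target taxid as
#'   `"target_taxid"`.
#' @export
build_cleaning_index <- function(contaminants, target,
                                 params = skim_params()) {
  if (is.null(names(contaminants)) || any(names(contaminants) == ""))
    stop("contaminants must be a named list of sequence sets")
  groups <- c(contaminants, list(target = target))
  ids <- cleaning_taxid(names(groups))
  seqs <- setNames(lapply(groups, gather_seqs), as.character(ids))
  idx <- build_index(seqs, params = params,
                     labels = setNames(names(groups), as.character(ids)))
  tree <- as_taxonomy(data.frame(
    taxid = c(1L, unname(ids)), parent = c(1L, rep(1L, length(ids))),
    rank = c("no rank", rep("clade", length(ids))),
    name = c("root", names(ids))))
  attr(idx, "taxonomy") <- tree
  attr(idx, "target_taxid") <- unname(ids["target"])
  idx
}

#' Remove contaminant reads from a genome skim
#'
#' Every read is assigned among the screening groups with the standard
#' algorithm ([assign_batch()]).  Reads are retained when they are
#' unidentified (best match below `t_c`), assigned to the target group, or
#' ambiguous between the target and a contaminant (their near-best matches
#' span both, so the LCA lands on the root) -- erring toward keeping reads
#' that may belong to the yet-unsequenced part of the target genome.  Reads
#' assigned to a contaminant group are discarded.
#'
#' @param reads character vector of skim reads (or a data frame with a `seq`
#'   column).
#' @param cleaning_index index from [build_cleaning_index()].
#' @param params optional [skim_params()] override (separately configurable
#'   `t_c` / `delta` for cleaning).
#' @return List with `reads` (the retained reads) and `report`, a
#'   `cleaning_report`: per-group discarded proportions, the proportion
#'   retained as target, and the unidentified proportion, all relative to
#'   the input read count.
#' @export
clean_skim <- function(reads, cleaning_index, params = NULL) {
  tree <- attr(cleaning_index, "taxonomy")
  target <- attr(cleaning_index, "target_taxid")
  if (is.null(tree) || is.null(target))
    stop("cleaning_index must come from build_cleaning_index()")
  if (is.data.frame(reads)) reads <- setNames(reads$seq, reads$id)
  reads <- as.character(reads)
  asg <- assign_batch(reads, cleaning_index, tree, params)
  root <- as.integer(tree$root)
  keep <- asg$taxid == 0L | asg$taxid == target | asg$taxid == root
  n <- max(length(reads), 1L)
  ids <- index_taxids(cleaning_index)
  labels <- vapply(cleaning_index$entries, `[[`, "", "label")
  contam <- ids[labels != "target"]
  discarded <- vapply(contam, function(id) sum(asg$taxid == id) / n,
                      numeric(1))
  names(discarded) <- labels[labels != "target"]
  report <- structure(list(
    n_input = length(reads), n_retained = sum(keep),
    discarded = discarded,
    retained_target = sum(asg$taxid == target) / n,
    ambiguous_root = sum(asg$taxid == root) / n,
    unidentified = sum(asg$taxid == 0L) / n), class = "cleaning_report")
  list(reads = reads[keep], report = report)
}

#' @export
print.cleaning_report <- function(x, ...) {
  cat(sprintf("cleaning_report: %d reads in, %d retained (%.3f%%)\n",
              x$n_input, x$n_retained,
              100 * x$n_retained / max(x$n_input, 1L)))
  for (g in names(x$discarded))
    cat(sprintf("  discarded as %-10s %8.4f%%\n", g, 100 * x$discarded[[g]]))
  cat(sprintf("  retained as target   %8.4f%%\n", 100 * x$retained_target))
  cat(sprintf("  ambiguous (kept)     %8.4f%%\n", 100 * x$ambiguous_root))
  cat(sprintf("  unidentified (kept)  %8.4f%%\n", 100 * x$unidentified))
  invisible(x)
}
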