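# Scoring assignments against known read origins: the eight-way category
# scheme, parameter sweeps, and the genomic-completeness titration.

#' The eight assignment categories
#' @export
assignment_categories <- function() {
  c("target_species", "target_genus", "target_family", "higher_target",
    "incorrect_species", "incorrect_genus", "incorrect_family",
    "unidentified")
}

#' Categorize assignments against the true source species
#'
#' Each read falls in exactly one of eight categories.  Correct assignments,
#' by decreasing precision: `target_species` (assigned the true species),
#' `target_genus` (a correct ancestor at or below the genus),
#' `target_family` (a correct ancestor at or below the family),
#' `higher_target` (a correct ancestor above family).  Misassignments, by
#' locality: `incorrect_species` (a different taxon inside the target
#' genus), `incorrect_genus` (outside the genus but inside the target
#' family), `incorrect_family` (outside the target family).  Unassigned
#' reads (taxid 0) are `unidentified`.  Assignments at uncommon ranks (for
#' example subgenus or subspecies) are resolved by lineage containment:
#' whichever of the true species / genus / family contains them decides the
#' category, so a node below the correct species still counts as
#' `target_species`.
#'
#' @param assigned integer vector of assigned taxids (0 = unidentified).
#' @param true_taxid the true source species (single taxid, or one per
#'   read).
#' @param tree a `skim_taxonomy`.
#' @return Factor with the eight levels of [assignment_categories()].
#' @export
categorize_assignments <- function(assigned, true_taxid, tree) {
  assigned <- as.integer(assigned)
  true_taxid <- rep_len(as.integer(true_taxid), length(assigned))
  levs <- assignment_categories()
  one_true <- function(tt) {
    list(genus = ancestor_at_rank(tree, tt, "genus"),
         family = ancestor_at_rank(tree, tt, "family"),
         lineage = lineage_of(tree, tt))
  }
  truths <- lapply(setNames(nm = unique(true_taxid)), one_true)
  lin_cache <- new.env(parent = emptyenv())
  lin_of <- function(a) {
    key <- as.character(a)
    if (is.null(lin_cache[[key]]))
      lin_cache[[key]] <- lineage_of(tree, a)
    lin_cache[[key]]
  }
  out <- character(length(assigned))
  for (i in seq_along(assigned)) {
    a <- assigned[i]
    tt <- true_taxid[i]
    tr <- truths[[as.character(tt)]]
    out[i] <- if (a == 0L) "unidentified"
    else if (a == tt) "target_species"
    else {
      alin <- lin_of(a)
      if (tt %in% alin) "target_species"  # below the true species
      else if (a %in% tr$lineage) {   # correct, at reduced precision
        if (!is.na(tr$genus) && tr$genus %in% alin) "target_genus"
        else if (!is.na(tr$family) && tr$family %in% alin) "target_family"
        else "higher_target"
      } else {                        # misassigned; how local?
        if (!is.na(tr$genus) && tr$genus %in% alin) "incorrect_species"
        else if (!is.na(tr$family) && tr$family %in% alin) "incorrect_genus"
        else "incorrect_family"
      }
    }
  }
  factor(out, levels = levs)
}

#' Category counts for a batch of assignments
#'
#' @param assignments data frame from [assign_batch()].
#' @inheritParams categorize_assignments
#' @return Named integer vector over the eight categories (sums to the read
#'   count).
#' @export
category_counts <- function(assignments, true_taxid, tree) {
  cat <- categorize_assignments(assignments$taxid, true_taxid, tree)
  table(cat)
}

#' Confusion matrix of true species against assigned taxa
#'
#' @param true_taxid per-read true source species.
#' @param assigned per-read assigned taxid (0 = unidentified).
#' @return A contingency table (rows = true species, columns = assigned
#'   taxid).
#' @export
confusion_matrix <- function(true_taxid, assigned) {
  table(true = as.integer(true_taxid), assigned = as.integer(assigned))
}

#' Sweep the acceptance cutoff and the near-best window
#'
#' Re-applies the candidate-selection rule over a grid of `t_c` and `delta`
#' values from one precomputed shared-k-mer matrix, so the index is queried
#' once.  For each grid point the eight category counts are tabulated along
#' with the off-target total (the three incorrect categories) and the
#' objective `ratio = target_species / off_target` (infinite when nothing is
#' off target); the row maximizing the ratio (ties broken toward more
#' correct species calls, then the stricter cutoff) is returned as `best`.
#'
#' @param reads character vector of truth-labelled reads.
#' @param index a `kmer_index`.
#' @param tree a `skim_taxonomy`.
#' @param true_taxid true source species of the reads (single or per-read).
#' @param t_c_grid,delta_grid numeric grids to sweep.
#' @param params base [skim_params()] (all non-swept fields).
#' @return List with `table` (one row per grid point) and `best`.
#' @export
sweep_parameters <- function(reads, index, tree, true_taxid,
                             t_c_grid = seq(0.3, 1, by = 0.1),
                             delta_grid = c(0.05, 0.1, 0.2),
                             params = NULL) {
  if (is.null(params)) params <- index$params
  reads <- as.character(reads)
  counts <- shared_kmer_matrix(reads, index)
  nk <- n_kmer_windows(reads, params$k)
  taxids <- index_taxids(index)
  grid <- expand.grid(t_c = t_c_grid, delta = delta_grid,
                      KEEP.OUT.ATTRS = FALSE)
  grid <- grid[grid$delta < grid$t_c, , drop = FALSE]
  if (nrow(grid) == 0L) stop("empty parameter grid")
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    p <- params
    p$t_c <- grid$t_c[i]
    p$delta <- grid$delta[i]
    asg <- assign_from_counts(counts, nk, taxids, tree, p)
    cc <- category_counts(asg, true_taxid, tree)
    off <- sum(cc[c("incorrect_species", "incorrect_genus",
                    "incorrect_family")])
    cbind(data.frame(t_c = p$t_c, delta = p$delta),
          as.data.frame.matrix(t(as.matrix(cc))),
          data.frame(off_target = off,
                     ratio = cc[["target_species"]] / off))
  })
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  o <- order(-tab$ratio, -tab$target_species, -tab$t_c)
  list(table = tab, best = tab[o[1L], , drop = FALSE])
}

#' Genomic-completeness titration
#'
#' Measures how assignment accuracy for a target species grows with the
#' sequencing effort behind its reference entry.  For each fraction of the
#' read pool, an index is rebuilt with that many target reads (other entries
#' unchanged), the query reads are re-assigned, and the eight categories are
#' tabulated.  At fraction 0 the target entry is empty, so no species-level
#' call on the target is possible.
#'
#' @param target_pool character vector of target skim reads; fraction `f`
#'   uses the first `round(f * length(target_pool))` of them.
#' @param background named list (taxid -> sequences) of the other index
#'   entries.
#' @param fractions ascending fractions of the pool in `[0, 1]`.
#' @param query_reads reads drawn from the target species to annotate.
#' @param true_taxid the target species taxid.
#' @param tree a `skim_taxonomy`.
#' @param params a [skim_params()].
#' @param target_taxid taxid of the rebuilt entry (defaults to
#'   `true_taxid`).
#' @return Data frame, one row per fraction: `fraction`, `n_reads_used`,
#'   `n_distinct` (distinct s-mers of the target entry) and the eight
#'   category counts.
#' @export
coverage_titration <- function(target_pool, background, fractions,
                               query_reads, true_taxid, tree,
                               params = skim_params(),
                               target_taxid = true_taxid) {
  if (is.unsorted(fractions)) stop("fractions must be sorted ascending")
  target_pool <- as.character(target_pool)
  query_reads <- as.character(query_reads)
  rows <- lapply(fractions, function(f) {
    n_use <- round(f * length(target_pool))
    seqs <- c(setNames(list(if (n_use > 0) target_pool[seq_len(n_use)]
                            else ""),
                       as.character(target_taxid)),
              background)
    idx <- build_index(seqs, params = params)
    asg <- assign_batch(query_reads, idx, tree, params)
    cc <- category_counts(asg, true_taxid, tree)
    nd <- idx$entries[[as.character(target_taxid)]]$n_distinct
    cbind(data.frame(fraction = f, n_reads_used = n_use, n_distinct = nd),
          as.data.frame.matrix(t(as.matrix(cc))))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
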