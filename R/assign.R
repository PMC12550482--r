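#' Shared k-mer counts of reads against every index entry
#'
#' @param reads character vector of read sequences.
#' @param index a `kmer_index`.
#' @return Integer matrix, one row per read and one column per entry
#'   (columns named by taxid).
#' @export
shared_kmer_matrix <- function(reads, index) {
  stopifnot(inherits(index, "kmer_index"))
  counts <- vapply(index$entries,
                   function(e) count_shared_kmers(reads, e$filter),
                   integer(length(reads)))
  if (length(reads) == 1L) counts <- matrix(counts, nrow = 1L,
                                            dimnames = list(NULL, names(index$entries)))
  colnames(counts) <- names(index$entries)
  counts
}

#' Assign taxa from a precomputed shared-k-mer matrix
#'
#' The per-read decision, given the shared-k-mer count `S_G` against every
#' database entry `G`:
#' \enumerate{
#'   \item `N_Q = L_Q - k + 1` k-mer windows for a read of length `L_Q`;
#'   \item `S_max = max(S_G)` and `t_max = S_max / N_Q`;
#'   \item if `t_max < t_c` the read is unidentified (taxid 0);
#'   \item otherwise `t_min = t_max - delta`, `S_min = t_min * N_Q`
#'     (real-valued, no rounding), and all entries with
#'     `S_G` in the closed interval `[S_min, S_max]` are candidates;
#'   \item the read is assigned the lowest common ancestor of the candidate
#'     taxids.
#' }
#' Boundary ties (`S_G` exactly at `S_min`) count as candidates; a small
#' numeric tolerance protects the comparison from floating-point noise in
#' `delta * N_Q`.  Reads shorter than `k` (`N_Q = 0`) are unidentified, not
#' an error.
#'
#' @param counts integer matrix from [shared_kmer_matrix()] (columns =
#'   entries).
#' @param n_kmers integer vector of per-read window counts `N_Q`.
#' @param taxids entry taxids, one per column of `counts`.
#' @param tree a `skim_taxonomy` covering all entry taxids.
#' @param params a [skim_params()] (uses `t_c` and `delta`).
#' @param ids optional read identifiers.
#' @return Data frame with one row per read: `read_id`, `n_kmers`, `s_max`,
#'   `t_max`, `n_candidates`, `taxid` (0 = unidentified).
#' @export
assign_from_counts <- function(counts, n_kmers, taxids, tree,
                               params = skim_params(), ids = NULL) {
  stopifnot(is.matrix(counts), ncol(counts) == length(taxids))
  n <- nrow(counts)
  if (is.null(ids)) ids <- paste0("read_", seq_len(n))
  n_kmers <- as.integer(n_kmers)
  s_max <- if (ncol(counts) == 1L) as.integer(counts[, 1L])
           else do.call(pmax, as.data.frame(counts))
  t_max <- ifelse(n_kmers > 0L, s_max / n_kmers, NA_real_)
  identified <- !is.na(t_max) & t_max >= params$t_c
  taxid <- integer(n)
  n_cand <- integer(n)
  if (any(identified)) {
    s_min <- (t_max[identified] - params$delta) * n_kmers[identified]
    sub <- counts[identified, , drop = FALSE]
    memb <- sub >= (s_min - 1e-9)  # inclusive lower bound, FP-safe
    n_cand[identified] <- as.integer(rowSums(memb))
    keys <- apply(memb, 1L, function(r) paste(which(r), collapse = ","))
    uk <- unique(keys)
    lcas <- vapply(uk, function(key) {
      cols <- as.integer(strsplit(key, ",", fixed = TRUE)[[1L]])
      lca(tree, taxids[cols])
    }, integer(1))
    taxid[identified] <- lcas[keys]
  }
  data.frame(read_id = ids, n_kmers = n_kmers, s_max = as.integer(s_max),
             t_max = as.numeric(t_max), n_candidates = n_cand,
             taxid = taxid, row.names = NULL, stringsAsFactors = FALSE)
}

#' Assign a taxon to each read of a metagenome
#'
#' Scores every read against every entry of the index
#' ([shared_kmer_matrix()]) and applies the candidate-selection / LCA rule of
#' [assign_from_counts()].  Output rows preserve input order, and every read
#' yields a row -- reads failing the cutoff appear with taxid 0 rather than
#' being dropped.
#'
#' @param reads character vector of read sequences.
#' @param index a `kmer_index`.
#' @param tree a `skim_taxonomy`.
#' @param params a [skim_params()]; defaults to the index's parameters (with
#'   their `t_c`, `delta`).
#' @param ids optional read identifiers (defaults to `names(reads)` when
#'   present).
#' @return Data frame as in [assign_from_counts()].
#' @export
assign_batch <- function(reads, index, tree, params = NULL, ids = NULL) {
  stopifnot(inherits(index, "kmer_index"))
  if (is.null(params)) params <- index$params
  if (params$k != index$params$k || params$z != index$params$z)
    stop(sprintf("parameter mismatch: query k=%d z=%d but index k=%d z=%d",
                 params$k, params$z, index$params$k, index$params$z))
  if (is.null(ids)) ids <- names(reads)
  reads <- as.character(reads)
  if (length(reads) == 0L)
    return(assign_from_counts(
      matrix(integer(0), 0L, length(index$entries)), integer(0),
      index_taxids(index), tree, params, character(0)))
  counts <- shared_kmer_matrix(reads, index)
  assign_from_counts(counts, n_kmer_windows(reads, params$k),
                     index_taxids(index), tree, params, ids)
}

#' @rdname assign_batch
#' @param read a single read sequence.
#' @return `assign_read()` returns a one-row data frame.
#' @export
assign_read <- function(read, index, tree, params = NULL, ids = NULL) {
  assign_batch(read, index, tree, params, ids)
}

#' Reset rare taxa to unidentified
#'
#' Dataset-level noise filter: a taxon is retained only when it received
#' strictly more than a proportion `r` of the total queried reads; reads
#' assigned to dropped taxa are reset to taxid 0.  The denominator is the
#' total number of queried reads (not just the assigned ones), so with the
#' default of `r` at 1e-5 a taxon needs more than one read per hundred thousand
#' queried to survive -- chosen to absorb the Bloom-filter false-positive
#' assignments expected at about `fp^z = 1.25e-4` per k-mer.
#'
#' @param assignments data frame from [assign_batch()].
#' @param r retention proportion in `[0, 1)`.
#' @param total_reads total queried reads (defaults to `nrow(assignments)`).
#' @return The assignments with rare taxa reset to 0; other rows unchanged.
#' @export
filter_low_abundance <- function(assignments, r = 1e-5,
                                 total_reads = nrow(assignments)) {
  if (total_reads < nrow(assignments))
    stop("total_reads is smaller than the number of assignment records")
  tab <- table(assignments$taxid[assignments$taxid != 0L])
  drop <- as.integer(names(tab)[as.numeric(tab) / total_reads <= r])
  assignments$taxid[assignments$taxid %in% drop] <- 0L
  assignments
}

#' Per-taxon read counts after the abundance cutoff
#'
#' @param assignments data frame from [assign_batch()].
#' @param tree optional `skim_taxonomy` used to attach names and ranks.
#' @return Data frame `taxid`, `n_reads` (and `rank`, `name` when a tree is
#'   given), sorted by decreasing count; unidentified reads are excluded.
#' @export
summarize_taxa <- function(assignments, tree = NULL) {
  tab <- table(assignments$taxid[assignments$taxid != 0L])
  out <- data.frame(taxid = as.integer(names(tab)),
                    n_reads = as.integer(tab), row.names = NULL)
  out <- out[order(-out$n_reads, out$taxid), , drop = FALSE]
  if (!is.null(tree)) {
    out$rank <- rank_of(tree, out$taxid)
    out$name <- name_of(tree, out$taxid)
  }
  rownames(out) <- NULL
  out
}

#' Write per-read assignments as TSV
#'
#' One row per read: `read_id`, `t_max` (4 decimals; `NA` for reads shorter
#' than k), `n_candidates`, `taxid` (0 = unidentified).
#'
#' @param assignments data frame from [assign_batch()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_assignments <- function(assignments, path) {
  out <- data.frame(
    read_id = assignments$read_id,
    t_max = ifelse(is.na(assignments$t_max), "NA",
                   sprintf("%.4f", assignments$t_max)),
    n_candidates = assignments$n_candidates,
    taxid = assignments$taxid)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
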