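#' Read a skim-to-taxid manifest
#'
#' Tab-separated table with columns `taxid`, `label`, `path`, one row per
#' sequence file.  Several rows may share a taxid: their files are
#' concatenated into a single index entry, so multiple skims of one species
#' form one entry.
#'
#' @param path manifest TSV.
#' @return Data frame with columns `taxid`, `label`, `path`.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("cannot read manifest: ", path)
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("taxid", "label", "path")
  if (!all(need %in% names(df)))
    stop("manifest needs columns: ", paste(need, collapse = ", "))
  df$taxid <- as.integer(df$taxid)
  df
}

#' Count distinct canonical s-mers
#'
#' `method = "exact"` builds the full hash set and returns its size.
#' `method = "sample"` keeps only s-mers whose hash falls in a fixed
#' `1 / 2^sample_bits` slice and scales the sampled distinct count back up --
#' a cheap cardinality estimate whose relative error is about
#' `1 / sqrt(distinct / 2^sample_bits)`.
#'
#' @param x character vector of sequences, or paths to FASTA/FASTQ files.
#' @param s s-mer length.
#' @param method `"exact"` or `"sample"`.
#' @param sample_bits sampling depth `b` for `method = "sample"`.
#' @return Estimated (or exact) number of distinct canonical s-mers.
#' @export
estimate_distinct_smers <- function(x, s, method = c("exact", "sample"),
                                    sample_bits = 6L) {
  method <- match.arg(method)
  seqs <- gather_seqs(x)
  if (method == "exact") {
    st <- cpp_smer_set(seqs, as.integer(s))
    cpp_smer_set_size(st)
  } else {
    cpp_distinct_estimate(seqs, as.integer(s), as.integer(sample_bits))
  }
}

gather_seqs <- function(x) {
  if (is.character(x) && length(x) > 0 && all(file.exists(x))) {
    seqs <- unlist(lapply(x, read_sequences), use.names = FALSE)
  } else {
    seqs <- as.character(x)
  }
  if (length(seqs) == 0L) stop("no sequences to process")
  seqs
}

#' Group index entries by k-mer diversity
#'
#' Entries are sorted by their distinct-s-mer counts and cut into geometric
#' bins: entry `i` joins the bin `floor(log(n_i / n_min) / log(ratio))`.
#' Every entry in a bin receives the bin's common bit-field size, computed
#' from the bin's largest count via [required_bits()], so the realized
#' false-positive rate of every member is at or below `fp` (smaller members
#' are over-sized and land below the target).  Groups are contiguous ranges
#' of the sorted counts.
#'
#' @param counts named numeric vector, taxid -> distinct s-mer count.
#' @param fp false-positive target used to size each group.
#' @param ratio geometric bin ratio (> 1).
#' @return Data frame with columns `taxid`, `n_distinct`, `group`, `m`,
#'   sorted by `n_distinct`.
#' @export
group_entries <- function(counts, fp = 0.05, ratio = 2) {
  if (length(counts) == 0L) stop("counts must be non-empty")
  if (ratio <= 1) stop("ratio must be > 1")
  taxid <- names(counts)
  if (is.null(taxid)) stop("counts must be named by taxid")
  o <- order(counts)
  n <- as.numeric(counts[o])
  base <- min(n[n > 0], 1)
  bin <- ifelse(n <= 0, 0L,
                pmax(0L, floor(log(n / base) / log(ratio) + 1e-9)))
  group <- match(bin, sort(unique(bin)))
  m <- vapply(split(n, group), function(v) required_bits(max(v), fp),
              numeric(1))[as.character(group)]
  data.frame(taxid = as.integer(taxid[o]), n_distinct = n,
             group = as.integer(group), m = as.numeric(m),
             row.names = NULL)
}

#' Build the k-mer reference database
#'
#' One entry is built per taxid: all sequences mapped to that taxid are
#' pooled, their distinct canonical s-mers are collected, entries are grouped
#' by diversity ([group_entries()]) so that entries in a group share one
#' bit-field size, and every distinct s-mer is inserted into the entry's
#' filter.
#'
#' @param x either a manifest data frame (`taxid`, `label`, `path`; see
#'   [read_manifest()]) or a named list of character vectors of sequences,
#'   names being taxids.
#' @param params a [skim_params()]; `params$backend` selects the Bloom or the
#'   exact backend for every entry.
#' @param labels optional named character vector, taxid -> label (list
#'   input).
#' @param ratio geometric grouping ratio passed to [group_entries()].
#' @return An object of class `kmer_index`: list with `entries` (one per
#'   taxid: `taxid`, `label`, `filter`, `n_distinct`, `source_files`),
#'   `groups` (the [group_entries()] table) and `params`.
#' @examples
#' idx <- build_index(list(`101` = "ACGTACGTACGTACGT"),
#'                    params = skim_params(k = 8, z = 3, backend = "exact"))
#' @export
build_index <- function(x, params = skim_params(), labels = NULL, ratio = 2) {
  stopifnot(inherits(params, "skim_params"))
  if (is.data.frame(x)) {
    if (nrow(x) == 0L) stop("manifest is empty")
    taxids <- as.character(unique(as.integer(x$taxid)))
    seqs_of <- function(id) {
      paths <- x$path[as.character(x$taxid) == id]
      gather_seqs(paths)
    }
    files_of <- function(id) x$path[as.character(x$taxid) == id]
    labels <- setNames(
      vapply(taxids, function(id)
        as.character(x$label[as.character(x$taxid) == id][1L]), ""),
      taxids)
  } else if (is.list(x)) {
    if (length(x) == 0L) stop("manifest is empty")
    if (is.null(names(x))) stop("sequence list must be named by taxid")
    taxids <- as.character(as.integer(names(x)))
    seqs_of <- function(id) as.character(x[[which(taxids == id)[1L]]])
    files_of <- function(id) character(0)
    if (is.null(labels)) labels <- setNames(taxids, taxids)
  } else {
    stop("x must be a manifest data frame or a named list of sequences")
  }

  sets <- lapply(taxids, function(id) cpp_smer_set(seqs_of(id), params$s))
  names(sets) <- taxids
  counts <- vapply(sets, cpp_smer_set_size, numeric(1))
  groups <- group_entries(counts, fp = params$fp, ratio = ratio)

  entries <- lapply(taxids, function(id) {
    m <- groups$m[match(as.integer(id), groups$taxid)]
    if (params$backend == "bloom") {
      f <- skim_filter(k = params$k, z = params$z, fp = params$fp, m = m,
                       seed = params$seed, backend = "bloom")
      cpp_bloom_insert_set(f$ptr, sets[[id]])
    } else {
      f <- filter_from_set(sets[[id]], params$k, params$z, params$fp,
                           params$seed)
    }
    list(taxid = as.integer(id), label = unname(labels[id]), filter = f,
         n_distinct = unname(counts[id]), source_files = files_of(id))
  })
  names(entries) <- taxids
  structure(list(entries = entries, groups = groups, params = params),
            class = "kmer_index")
}

#' @export
print.kmer_index <- function(x, ...) {
  cat(sprintf("kmer_index: %d entries in %d group(s), k=%d z=%d fp=%g [%s]\n",
              length(x$entries), max(x$groups$group), x$params$k, x$params$z,
              x$params$fp, x$params$backend))
  invisible(x)
}

index_taxids <- function(index) {
  vapply(index$entries, `[[`, integer(1), "taxid")
}

#' Write / read an index directory
#'
#' The directory holds one filter file per entry (`<taxid>.skf`, see
#' [write_filter()]) plus a `groups.json` manifest with the grouping table,
#' parameters and entry metadata.
#'
#' @param index a `kmer_index`.
#' @param dir output directory (created if needed).
#' @return `dir` (or the re-loaded `kmer_index` for [read_index()]),
#'   invisibly.
#' @export
write_index <- function(index, dir) {
  stopifnot(inherits(index, "kmer_index"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (e in index$entries)
    write_filter(e$filter, file.path(dir, paste0(e$taxid, ".skf")))
  meta <- list(
    magic = "SKIMDEX-INDEX", version = 1L,
    params = unclass(index$params),
    groups = index$groups,
    entries = lapply(unname(index$entries), function(e)
      list(taxid = e$taxid, label = e$label, n_distinct = e$n_distinct,
           source_files = as.character(e$source_files))))
  jsonlite::write_json(meta, file.path(dir, "groups.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' @rdname write_index
#' @export
read_index <- function(dir) {
  metapath <- file.path(dir, "groups.json")
  if (!file.exists(metapath)) stop("not an index directory: ", dir)
  meta <- jsonlite::fromJSON(metapath, simplifyDataFrame = TRUE)
  if (!identical(meta$magic, "SKIMDEX-INDEX"))
    stop("not a skimdex index: ", dir)
  p <- meta$params
  params <- skim_params(k = p$k, z = p$z, fp = p$fp, t_c = p$t_c,
                        delta = p$delta, r = p$r, seed = p$seed,
                        backend = p$backend)
  ents <- meta$entries
  entries <- lapply(seq_len(nrow(ents)), function(i) {
    taxid <- ents$taxid[i]
    f <- read_filter(file.path(dir, paste0(taxid, ".skf")))
    list(taxid = as.integer(taxid), label = ents$label[i], filter = f,
         n_distinct = ents$n_distinct[i],
         source_files = unlist(ents$source_files[i]))
  })
  names(entries) <- as.character(ents$taxid)
  structure(list(entries = entries,
                 groups = as.data.frame(meta$groups), params = params),
            class = "kmer_index")
}
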