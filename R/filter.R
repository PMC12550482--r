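#' Bloom filter size for a target false-positive rate
#'
#' For a single-hash Bloom filter holding `n` distinct s-mers, the number of
#' bits needed to reach a false-positive rate `fp` is
#' `m = ceiling(-n / log(1 - fp))`: with one hash function the fill fraction
#' after `n` insertions is `1 - exp(-n/m)`, and solving
#' `1 - exp(-n/m) = fp` for `m` gives exactly this law.
#'
#' @param n number of distinct s-mers the filter will hold (`>= 0`).
#' @param fp target false-positive probability in (0, 1).
#' @return Integer-valued number of bits (`0` when `n = 0`).
#' @examples
#' required_bits(1000, 0.05)  # 19496
#' @export
required_bits <- function(n, fp) {
  if (!is.numeric(fp) || any(fp <= 0 | fp >= 1)) stop("fp must be in (0, 1)")
  if (!is.numeric(n) || any(n < 0)) stop("n must be >= 0")
  ifelse(n == 0, 0, ceiling(-n / log(1 - fp)))
}

#' Create an s-mer membership filter
#'
#' Constructs the membership primitive used for every index entry: a
#' single-hash Bloom filter over canonical s-mers of length `s = k - z + 1`,
#' or an exact hash-set with the same interface (`backend = "exact"`), which
#' has no false positives and serves as the ground-truth backend in tests.
#'
#' For the Bloom backend the bit-field size is `m` if given, otherwise
#' `required_bits(n_capacity, fp)`.  One hash function is used, seeded with
#' `seed`, matching the sizing law of [required_bits()].
#'
#' @param k,z query k-mer length and number of neighbouring s-mers per k-mer;
#'   the filter stores s-mers of length `k - z + 1`.
#' @param fp false-positive target used for sizing (Bloom backend).
#' @param n_capacity expected number of distinct s-mers (Bloom backend;
#'   ignored when `m` is given).
#' @param m bit-field size override.
#' @param seed integer hash seed, recorded in the filter.
#' @param backend `"bloom"` or `"exact"`.
#' @return An object of class `skim_filter`.
#' @examples
#' f <- skim_filter(k = 8, z = 3, n_capacity = 100, backend = "exact")
#' filter_insert(f, "ACGTAC")
#' filter_contains(f, c("ACGTAC", "GTACGT"))  # TRUE TRUE (GTACGT == rc)
#' @export
skim_filter <- function(k = 34L, z = 3L, fp = 0.05, n_capacity = NULL,
                        m = NULL, seed = 1L, backend = c("bloom", "exact")) {
  backend <- match.arg(backend)
  k <- as.integer(k); z <- as.integer(z)
  if (z < 1L || z >= k) stop("need 1 <= z < k")
  s <- k - z + 1L
  if (backend == "bloom") {
    if (is.null(m)) {
      if (is.null(n_capacity))
        stop("give either n_capacity or m for the bloom backend")
      m <- required_bits(n_capacity, fp)
    }
    ptr <- cpp_bloom_new(as.numeric(m), as.numeric(seed), s)
  } else {
    m <- NA_real_
    ptr <- cpp_smer_set_empty(s)
  }
  structure(
    list(backend = backend, ptr = ptr, k = k, z = z, s = s,
         fp_target = fp, m = as.numeric(m), hash_seed = as.integer(seed)),
    class = "skim_filter"
  )
}

# wrap an existing SmerSet pointer as an exact-backend filter
filter_from_set <- function(setptr, k, z, fp = 0.05, seed = 1L) {
  structure(
    list(backend = "exact", ptr = setptr, k = as.integer(k),
         z = as.integer(z), s = as.integer(k - z + 1), fp_target = fp,
         m = NA_real_, hash_seed = as.integer(seed)),
    class = "skim_filter"
  )
}

is_exact <- function(f) f$backend == "exact"

#' Insert s-mers into a filter
#'
#' Each s-mer is canonicalized before insertion, so a sequence and its
#' reverse complement are the same element.  Inserted s-mers can never be
#' reported absent afterwards (no false negatives).  For the Bloom backend
#' the insertion counter assumes the batch contains no s-mer already present;
#' the index builder always inserts a pre-deduplicated set.
#'
#' @param filter a [skim_filter()].
#' @param smers character vector of s-mers, all of length `filter$s`.
#' @return The filter, invisibly.
#' @export
filter_insert <- function(filter, smers) {
  stopifnot(inherits(filter, "skim_filter"))
  if (is_exact(filter)) cpp_smer_set_insert(filter$ptr, as.character(smers))
  else cpp_bloom_insert_smers(filter$ptr, as.character(smers))
  invisible(filter)
}

#' Test s-mer membership
#'
#' @param filter a [skim_filter()].
#' @param smers character vector of s-mers of length `filter$s`.
#' @return Logical vector; the Bloom backend may return false positives at
#'   roughly the `fp_target` rate but never false negatives.
#' @export
filter_contains <- function(filter, smers) {
  stopifnot(inherits(filter, "skim_filter"))
  if (is_exact(filter)) cpp_smer_set_contains(filter$ptr, as.character(smers))
  else cpp_bloom_contains(filter$ptr, as.character(smers))
}

#' Number of distinct s-mers recorded in a filter
#'
#' @param filter a [skim_filter()].
#' @return For the exact backend, the exact distinct count; for the Bloom
#'   backend, the insertion counter.
#' @export
filter_n <- function(filter) {
  stopifnot(inherits(filter, "skim_filter"))
  if (is_exact(filter)) cpp_smer_set_size(filter$ptr)
  else cpp_bloom_info(filter$ptr)$n_inserted
}

#' @export
print.skim_filter <- function(x, ...) {
  cat(sprintf(
    "skim_filter [%s]: k=%d z=%d s=%d, m=%s bits, n=%s s-mers, fp target %g\n",
    x$backend, x$k, x$z, x$s,
    if (is.na(x$m)) "-" else format(x$m, big.mark = ","),
    format(filter_n(x), big.mark = ","), x$fp_target))
  invisible(x)
}

#' Composite (findere-style) k-mer query
#'
#' A k-mer of length `k` is reported present only when all `z` of its
#' constituent s-mers (the `z` windows of length `s = k - z + 1` inside it,
#' canonicalized) are members of the filter.  Because a false positive
#' requires `z` independent spurious hits, the per-k-mer false-positive rate
#' is about `fp^z` -- `0.05^3 = 1.25e-4` at the defaults.
#'
#' @param filter a [skim_filter()].
#' @param kmers character vector of k-mers, each of length `filter$k`.
#' @return Logical vector of verdicts; k-mers containing ambiguous bases are
#'   reported absent.
#' @export
query_kmer_findere <- function(filter, kmers) {
  stopifnot(inherits(filter, "skim_filter"))
  cpp_query_kmers(as.character(kmers), filter$ptr, is_exact(filter),
                  filter$k, filter$z)
}

#' Shared k-mer count of reads against one filter
#'
#' For each read, counts the k-mer windows whose composite query
#' ([query_kmer_findere()]) is positive.  The count is bounded by the number
#' of windows `L - k + 1`; windows containing ambiguous bases never match.
#'
#' @param reads character vector of read sequences.
#' @param filter a [skim_filter()].
#' @return Integer vector of shared-k-mer counts, one per read.
#' @export
count_shared_kmers <- function(reads, filter) {
  stopifnot(inherits(filter, "skim_filter"))
  cpp_count_shared(as.character(reads), filter$ptr, is_exact(filter),
                   filter$k, filter$z)
}

#' Random k-mers
#'
#' Uniform random DNA strings, drawn through R's RNG (so reproducible under
#' `set.seed()`).  Used by the false-positive measurement helpers and tests.
#'
#' @param n number of strings.
#' @param length string length in bases.
#' @return Character vector of length `n`.
#' @export
random_kmers <- function(n, length) {
  cpp_random_kmers(as.numeric(n), as.integer(length))
}

#' Measure the empirical single-s-mer false-positive rate
#'
#' Probes a filter with random s-mers that are verified absent from the set
#' of truly inserted s-mers and reports the fraction answered present.  For a
#' Bloom filter sized by [required_bits()] this fraction should sit near the
#' `fp_target` (within binomial noise).
#'
#' @param filter the filter under test.
#' @param inserted character vector of the s-mers actually inserted (used to
#'   exclude accidental true members from the probe set), or a `skim_filter`
#'   with exact backend holding them.
#' @param n_probes number of random probes.
#' @param batch probes generated per chunk.
#' @return List with `fp_hat`, `positives` and `tested`.
#' @export
measure_bloom_fp <- function(filter, inserted, n_probes = 1e5, batch = 1e5) {
  truth <- truth_set(inserted, filter$s)
  pos <- 0; tested <- 0
  while (tested < n_probes) {
    nb <- min(batch, n_probes - tested)
    probes <- cpp_random_kmers(nb, filter$s)
    keep <- !cpp_smer_set_contains(truth, probes)
    probes <- probes[keep]
    pos <- pos + sum(filter_contains(filter, probes))
    tested <- tested + length(probes)
  }
  list(fp_hat = pos / tested, positives = pos, tested = tested)
}

#' Measure the empirical composite-k-mer false-positive rate
#'
#' Generates random k-mers whose constituent s-mers are all absent from the
#' truly inserted set, queries them through [query_kmer_findere()], and
#' reports the positive fraction.  With a per-s-mer rate `fp` this should be
#' close to `fp^z`.
#'
#' @inheritParams measure_bloom_fp
#' @param n_queries number of valid (fully non-member) k-mers to test.
#' @return List with `fp_hat`, `positives` and `tested`.
#' @export
measure_findere_fp <- function(filter, inserted, n_queries = 1e6, batch = 1e5) {
  truth <- truth_set(inserted, filter$s)
  pos <- 0; tested <- 0
  while (tested < n_queries) {
    nb <- min(batch, n_queries - tested)
    kq <- cpp_random_kmers(nb, filter$k)
    keep <- cpp_count_member_smers(kq, truth) == 0L
    kq <- kq[keep]
    pos <- pos + sum(query_kmer_findere(filter, kq))
    tested <- tested + length(kq)
  }
  list(fp_hat = pos / tested, positives = pos, tested = tested)
}

truth_set <- function(inserted, s) {
  if (inherits(inserted, "skim_filter")) {
    if (!is_exact(inserted)) stop("`inserted` filter must use the exact backend")
    return(inserted$ptr)
  }
  st <- cpp_smer_set_empty(as.integer(s))
  cpp_smer_set_insert(st, as.character(inserted))
  st
}

#' Write a filter to disk
#'
#' Binary container: an ASCII magic line, a JSON header (backend, k, z, m,
#' distinct count, fp target, hash seed) and the payload -- the raw bit field
#' for the Bloom backend, or the sorted canonical s-mers for the exact
#' backend.  Writing is deterministic: rebuilding the same entry from the
#' same inputs yields a byte-identical file.
#'
#' @param filter a [skim_filter()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_filter <- function(filter, path) {
  stopifnot(inherits(filter, "skim_filter"))
  con <- file(path, "wb")
  on.exit(close(con))
  header <- jsonlite::toJSON(list(
    magic = "SKIMDEX-FILTER", version = 1L, backend = filter$backend,
    k = filter$k, z = filter$z, s = filter$s, m = filter$m,
    n = filter_n(filter), fp_target = filter$fp_target,
    hash_seed = filter$hash_seed), auto_unbox = TRUE, digits = NA)
  writeLines(as.character(header), con)
  if (is_exact(filter)) {
    writeLines(cpp_smer_set_elements(filter$ptr), con)
  } else {
    writeBin(cpp_bloom_bits(filter$ptr), con)
  }
  invisible(path)
}

#' Read a filter written by [write_filter()]
#'
#' @param path file produced by [write_filter()].
#' @return A [skim_filter()].
#' @export
read_filter <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  header <- jsonlite::fromJSON(readLines(con, n = 1L))
  if (!identical(header$magic, "SKIMDEX-FILTER"))
    stop("not a skimdex filter file: ", path)
  if (identical(header$backend, "exact")) {
    smers <- readLines(con)
    ptr <- cpp_smer_set_empty(header$s)
    if (length(smers)) cpp_smer_set_insert(ptr, smers)
    f <- filter_from_set(ptr, header$k, header$z, header$fp_target,
                         header$hash_seed)
  } else {
    nbytes <- ceiling(header$m / 64) * 8
    bits <- readBin(con, what = "raw", n = nbytes)
    ptr <- cpp_bloom_from_bits(bits, header$m, header$hash_seed, header$n,
                               header$s)
    f <- structure(
      list(backend = "bloom", ptr = ptr, k = header$k, z = header$z,
           s = header$s, fp_target = header$fp_target, m = header$m,
           hash_seed = header$hash_seed),
      class = "skim_filter")
  }
  f
}
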