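#' Extract canonical k-mers from a sequence
#'
#' Slides a window of `length` bases over `seq` and returns each window in
#' canonical form: the lexicographic minimum of the window and its reverse
#' complement.  Windows containing a character outside `A/C/G/T` (for
#' instance `N`) are skipped rather than raising an error, since real FASTQ
#' data routinely contains ambiguous calls.  Input case is ignored.
#'
#' A sequence of length `L` has `max(0, L - length + 1)` windows, so an
#' N-free sequence yields exactly `L - length + 1` k-mers.
#'
#' @param seq a single DNA string.
#' @param length window length in bases (`>= 1`).
#' @return Character vector of canonical k-mers in window order (ambiguous
#'   windows omitted).
#' @examples
#' extract_kmers("ACGTA", 3)  # "ACG" "ACG" "GTA"
#' @export
extract_kmers <- function(seq, length) {
  if (!is.character(seq) || length(seq) != 1L || is.na(seq))
    stop("seq must be a single DNA string")
  length <- as.integer(length)
  if (is.na(length) || length < 1L) stop("k-mer length must be >= 1")
  cpp_canonical_kmers(seq, length)
}

#' Canonicalize k-mers
#'
#' Returns the canonical form (lexicographic minimum of a string and its
#' reverse complement) of each input; strings containing ambiguous bases map
#' to `NA`.
#'
#' @param x character vector of DNA strings.
#' @return Character vector of the same length.
#' @export
canonicalize_kmers <- function(x) {
  cpp_canonicalize(as.character(x))
}

# number of k-mer windows of a read, per the scoring convention:
# ambiguous windows still count towards the denominator
n_kmer_windows <- function(reads, k) {
  pmax(0L, nchar(reads) - as.integer(k) + 1L)
}
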