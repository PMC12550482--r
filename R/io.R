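#' Read sequences from FASTA/FASTQ
#'
#' Thin wrapper over [Biostrings::readDNAStringSet()]; the format is guessed
#' from the file extension (`.fq`/`.fastq`, optionally `.gz`, selects FASTQ).
#'
#' @param path sequence file, optionally gzip-compressed.
#' @return Named character vector of sequences.
#' @export
read_sequences <- function(path) {
  if (!file.exists(path)) stop("cannot read sequence file: ", path)
  base <- sub("\\.gz$", "", path, ignore.case = TRUE)
  fmt <- if (grepl("\\.(fq|fastq)$", base, ignore.case = TRUE)) "fastq"
         else "fasta"
  x <- Biostrings::readDNAStringSet(path, format = fmt)
  setNames(as.character(x), names(x))
}

#' Write reads to FASTQ or a genome to FASTA
#'
#' `write_fastq()` writes reads (a character vector or the data frame
#' produced by the simulators, which carries an `id` column) with constant
#' quality; `write_fasta()` writes named sequences.  Paths ending in `.gz`
#' are gzip-compressed.
#'
#' @param reads character vector of sequences, or a data frame with columns
#'   `id` and `seq`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  if (is.data.frame(reads)) {
    seqs <- reads$seq
    ids <- reads$id
  } else {
    seqs <- as.character(reads)
    ids <- names(reads)
    if (is.null(ids)) ids <- paste0("read_", seq_along(seqs))
  }
  x <- Biostrings::DNAStringSet(setNames(seqs, ids))
  qual <- Biostrings::BStringSet(vapply(nchar(seqs), function(n)
    paste(rep("I", n), collapse = ""), ""))
  Biostrings::writeXStringSet(x, path, format = "fastq", qualities = qual,
                              compress = grepl("\\.gz$", path))
  invisible(path)
}

#' @rdname write_fastq
#' @param seqs named character vector of sequences.
#' @export
write_fasta <- function(seqs, path) {
  ids <- names(seqs)
  if (is.null(ids)) ids <- paste0("seq_", seq_along(seqs))
  x <- Biostrings::DNAStringSet(setNames(as.character(seqs), ids))
  Biostrings::writeXStringSet(x, path, format = "fasta",
                              compress = grepl("\\.gz$", path))
  invisible(path)
}
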