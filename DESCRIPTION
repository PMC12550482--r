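Package: skimdex
Title: K-mer Indexing of Genome Skims for Taxonomic Annotation of Short
    Metagenomic Reads
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Builds per-species Bloom-filter k-mer indexes from unassembled
    low-coverage genome skims, cleans the skims of contaminant reads, and
    taxonomically annotates short (ancient) metagenomic reads by shared-k-mer
    scoring with composite-k-mer false-positive correction and
    lowest-common-ancestor resolution.  Ships simulators for random genomes,
    genome skims with sequencing error, and ancient-DNA-like fragmented reads
    with terminal deamination, together with tools that score assignments
    against known read origins.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    Biostrings,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
SystemRequirements: C++11
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
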