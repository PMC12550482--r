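# Synthetic data: random genomes, genome skims with sequencing error,
# ancient-DNA-like fragment sets, and related analytic expectations.
# All generators draw through R's RNG, so a single set.seed() call (or the
# `seed` arguments) makes every downstream artifact reproducible.

with_seed <- function(seed, expr) {
  if (!is.null(seed)) set.seed(seed)
  expr
}

#' Simulate a random genome
#'
#' Uniform iid bases (expected GC fraction 0.5).
#'
#' @param size genome length in bases (`>= 1`).
#' @param seed optional integer seed.
#' @return A single DNA string.
#' @export
simulate_genome <- function(size, seed = NULL) {
  with_seed(seed, cpp_simulate_genome(as.numeric(size)))
}

#' Simulate a genome skim
#'
#' Fixed-length reads placed uniformly over the genome, drawn from either
#' strand, with iid per-base substitution errors.  The read count is
#' `round(coverage * genome_size / read_length)` unless `n_reads` is given
#' directly.  The default error rate of 4.4e-3 is the per-base rate that
#' fits observed distinct-k-mer counts of Illumina genome skims.
#'
#' @param genome a single DNA string.
#' @param read_length read length in bases (default 101, a typical skim read
#'   length).
#' @param coverage expected fold-coverage (ignored when `n_reads` is given).
#' @param n_reads explicit read count.
#' @param error_rate per-base substitution probability.
#' @param seed optional integer seed.
#' @return Data frame with columns `id`, `seq`, `start`, `strand`.
#' @export
simulate_skim <- function(genome, read_length = 101L, coverage = NULL,
                          n_reads = NULL, error_rate = 4.4e-3, seed = NULL) {
  G <- nchar(genome)
  read_length <- as.integer(read_length)
  if (read_length > G) stop("read_length exceeds genome length")
  if (is.null(n_reads)) {
    if (is.null(coverage)) stop("give coverage or n_reads")
    n_reads <- round(coverage * G / read_length)
  }
  n_reads <- as.integer(n_reads)
  with_seed(seed, {
    if (n_reads == 0L)
      return(data.frame(id = character(0), seq = character(0),
                        start = integer(0), strand = character(0),
                        stringsAsFactors = FALSE))
    starts <- sample.int(G - read_length + 1L, n_reads, replace = TRUE)
    rc <- runif(n_reads) < 0.5
    reads <- cpp_extract_reads(genome, starts, read_length, rc)
    reads <- cpp_mutate_seqs(reads, error_rate)
    data.frame(id = sprintf("skim_%d", seq_len(n_reads)), seq = reads,
               start = starts, strand = ifelse(rc, "-", "+"),
               stringsAsFactors = FALSE)
  })
}

# Fragment lengths: shifted log-normal with a hard minimum.
# L = (min_length - 1) + X with X log-normal calibrated so E[L] equals the
# target mean; right-skewed with a floor at min_length, the shape of
# ancient-DNA fragment-size distributions once sub-k fragments are discarded.
sample_fragment_lengths <- function(n, mean_insert, min_length, sdlog) {
  offset <- min_length - 1
  target <- mean_insert - offset
  mu <- log(target) - sdlog^2 / 2
  pmax(1L, as.integer(round(rlnorm(n, mu, sdlog)))) + as.integer(offset)
}

#' Simulate ancient-DNA-like reads
#'
#' Short fragments whose lengths follow a right-skewed, shifted log-normal
#' distribution with a hard floor at `min_length` and mean calibrated to
#' `mean_insert`; fragments are drawn uniformly from either strand of the
#' genome.  Optionally, cytosine deamination is applied:
#' C->T substitutions with probability `deamination_5p * decay^d` at
#' distance `d` from the 5' end, and the mirrored G->A pattern from the 3'
#' end, reproducing the terminal damage profile of ancient DNA.  Deamination
#' is off by default, matching benchmarks built by length-reducing modern
#' reads.
#'
#' @param genome a single DNA string.
#' @param n number of fragments (`>= 0`).
#' @param mean_insert target mean fragment length in bases.
#' @param min_length shortest retained fragment (fragments below the query
#'   k-mer length cannot be scored, hence the default 34).
#' @param sdlog log-scale spread of the length distribution.
#' @param deamination_5p terminal deamination probability (0 disables).
#' @param deamination_decay per-base geometric decay of the damage
#'   probability away from the termini.
#' @param seed optional integer seed.
#' @return Data frame with columns `id`, `seq`, `start`, `strand`, `length`.
#' @export
simulate_ancient_reads <- function(genome, n, mean_insert = 35,
                                   min_length = 34L, sdlog = 0.6,
                                   deamination_5p = 0,
                                   deamination_decay = 0.6, seed = NULL) {
  n <- as.integer(n)
  if (n < 0L) stop("n must be >= 0")
  min_length <- as.integer(min_length)
  if (min_length < 1L) stop("min_length must be >= 1")
  if (mean_insert <= min_length)
    stop("mean_insert must exceed min_length")
  G <- nchar(genome)
  with_seed(seed, {
    if (n == 0L)
      return(data.frame(id = character(0), seq = character(0),
                        start = integer(0), strand = character(0),
                        length = integer(0), stringsAsFactors = FALSE))
    lens <- pmin(sample_fragment_lengths(n, mean_insert, min_length, sdlog),
                 G)
    starts <- 1L + as.integer(floor(runif(n) * (G - lens + 1L)))
    rc <- runif(n) < 0.5
    reads <- cpp_extract_reads(genome, starts, lens, rc)
    if (deamination_5p > 0)
      reads <- cpp_deaminate(reads, deamination_5p, deamination_decay)
    data.frame(id = sprintf("aDNA_%d", seq_len(n)), seq = reads,
               start = starts, strand = ifelse(rc, "-", "+"),
               length = lens, stringsAsFactors = FALSE)
  })
}

#' Simulate a clade of related reference genomes
#'
#' Generates one genus: a conserved "core" region shared identically by all
#' species, plus a private region per species.  Reads falling in the core
#' match every congener and resolve to the genus by LCA; reads in the
#' private region are species-diagnostic.  This mimics the conserved /
#' divergent structure that makes genus-level assignment the reliable level
#' for real skims, in an idealized form with a sharp core boundary.
#'
#' @param n_species number of species genomes to derive.
#' @param genome_size length of each species genome.
#' @param core_fraction fraction of the genome shared identically across the
#'   genus.
#' @param seed optional integer seed.
#' @return List with `core` (the shared region) and `genomes` (list of
#'   species genomes, core first then private sequence).
#' @export
simulate_clade <- function(n_species, genome_size, core_fraction = 0.5,
                           seed = NULL) {
  if (core_fraction < 0 || core_fraction >= 1)
    stop("core_fraction must be in [0, 1)")
  with_seed(seed, {
    core_len <- round(genome_size * core_fraction)
    core <- if (core_len > 0) cpp_simulate_genome(core_len) else ""
    genomes <- lapply(seq_len(n_species), function(i)
      paste0(core, cpp_simulate_genome(genome_size - core_len)))
    list(core = core, genomes = genomes)
  })
}

#' Simulate a reference community with its taxonomy
#'
#' Builds `n_genera` genera of `species_per_genus` species each via
#' [simulate_clade()], groups genera pairwise into families, and returns the
#' species genomes named by taxid together with the matching
#' `skim_taxonomy`.  Taxids: root 1, families 100 + f, genera 200 + g,
#' species 1000 + running index.
#'
#' @param n_genera number of genera.
#' @param species_per_genus species per genus (recycled across genera).
#' @param genome_size species genome length.
#' @param core_fraction within-genus shared fraction ([simulate_clade()]).
#' @param seed optional integer seed.
#' @return List with `genomes` (named by taxid), `taxonomy`, and `species`,
#'   a data frame of taxid / genus / family assignments.
#' @export
simulate_reference_community <- function(n_genera = 3L, species_per_genus = 3L,
                                         genome_size = 20000L,
                                         core_fraction = 0.5, seed = NULL) {
  species_per_genus <- rep_len(as.integer(species_per_genus), n_genera)
  with_seed(seed, {
    genomes <- list()
    rows <- list()
    sp <- 0L
    for (g in seq_len(n_genera)) {
      clade <- simulate_clade(species_per_genus[g], genome_size,
                              core_fraction)
      fam <- 100L + (g - 1L) %/% 2L + 1L
      for (i in seq_len(species_per_genus[g])) {
        sp <- sp + 1L
        taxid <- 1000L + sp
        genomes[[as.character(taxid)]] <- clade$genomes[[i]]
        rows[[sp]] <- data.frame(taxid = taxid, genus = 200L + g,
                                 family = fam)
      }
    }
    species <- do.call(rbind, rows)
    genera <- unique(species[, c("genus", "family")])
    families <- unique(species$family)
    tax <- rbind(
      data.frame(taxid = 1L, parent = 1L, rank = "no rank", name = "root"),
      data.frame(taxid = families, parent = 1L, rank = "family",
                 name = sprintf("Family%d", families - 100L)),
      data.frame(taxid = genera$genus, parent = genera$family,
                 rank = "genus", name = sprintf("Genus%d", genera$genus - 200L)),
      data.frame(taxid = species$taxid, parent = species$genus,
                 rank = "species",
                 name = sprintf("Species%d", species$taxid - 1000L)))
    list(genomes = genomes, taxonomy = as_taxonomy(tax), species = species)
  })
}

#' Expected number of distinct k-mers in a genome skim
#'
#' Analytic expectation for the distinct canonical k-mer count of a skim of
#' `n_reads` uniformly placed reads with iid per-base substitution errors,
#' combining three contributions:
#' \itemize{
#'   \item genome k-mers: each of the genome's distinct k-mers is collected
#'     when some read covers its window error-free, probability
#'     `1 - (1 - p_cov (1-e)^k)^n` with
#'     `p_cov = (L - k + 1) / (G - L + 1)`;
#'   \item single-error k-mers: each of the `3k` one-substitution variants
#'     of each genome window is seen when some covering read makes exactly
#'     that error, probability
#'     `1 - (1 - p_cov (e/3)(1-e)^(k-1))^n` -- repeated identical errors in
#'     different reads collapse onto the same variant, which is what bends
#'     the curve below linear growth;
#'   \item multi-error k-mers: windows with two or more errors are
#'     essentially never produced twice, contributing
#'     `n (L-k+1) P(>= 2 errors in a window)` distinct k-mers.
#' }
#' With `error_rate = 0` the curve saturates monotonically at the genome's
#' distinct k-mer count; with error the curve keeps climbing past
#' saturation, which is the observed behaviour of real skims.
#'
#' @param n_reads number of reads (vectorized).
#' @param genome_size genome length in bases.
#' @param read_length read length in bases.
#' @param k k-mer length (`<= read_length`).
#' @param error_rate per-base substitution probability.
#' @param genome_distinct distinct canonical k-mers of the genome; defaults
#'   to `genome_size - k + 1`, the expectation for a random genome.
#' @return Numeric vector of expected distinct k-mer counts.
#' @export
expected_distinct_kmers <- function(n_reads, genome_size, read_length = 101L,
                                    k = 31L, error_rate = 0,
                                    genome_distinct = NULL) {
  if (k > read_length) stop("k must be <= read_length")
  e <- error_rate
  G <- genome_size
  L <- read_length
  w <- L - k + 1
  W <- G - k + 1
  D <- if (is.null(genome_distinct)) W else genome_distinct
  p_cov <- w / (G - L + 1)
  clean <- (1 - e)^k
  single <- (e / 3) * (1 - e)^(k - 1)
  p_multi <- 1 - (1 - e)^k - k * e * (1 - e)^(k - 1)
  hit <- function(p_once) -expm1(n_reads * log1p(-pmin(p_once, 1)))
  D * hit(p_cov * clean) +
    3 * k * W * hit(p_cov * single) +
    n_reads * w * p_multi
}
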