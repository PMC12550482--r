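test_that("genome simulation is seed-deterministic with balanced bases", {
  g1 <- simulate_genome(10000, seed = 60)
  g2 <- simulate_genome(10000, seed = 60)
  g3 <- simulate_genome(10000, seed = 61)
  expect_identical(g1, g2)
  expect_false(identical(g1, g3))
  expect_equal(nchar(g1), 10000)
  freq <- table(strsplit(g1, "")[[1]]) / 10000
  sigma <- sqrt(0.25 * 0.75 / 10000)
  expect_true(all(abs(freq - 0.25) < 3 * sigma))
  expect_error(simulate_genome(0), "size")
})

test_that("skims have the right read count, placement and error rate", {
  genome <- simulate_genome(1e5, seed = 62)
  skim <- simulate_skim(genome, read_length = 100, coverage = 1, seed = 63)
  expect_equal(nrow(skim), 1000)
  expect_true(all(nchar(skim$seq) == 100))
  expect_true(all(skim$start >= 1 & skim$start <= 1e5 - 99))

  # empirical per-base mismatch rate against the source ~ error_rate
  e <- 0.01
  skim_e <- simulate_skim(genome, read_length = 100, n_reads = 400,
                          error_rate = e, seed = 64)
  src <- substring(genome, skim_e$start, skim_e$start + 99)
  src[skim_e$strand == "-"] <- o_revcomp(src[skim_e$strand == "-"])
  mism <- mapply(function(a, b)
    sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]]), skim_e$seq, src)
  rate <- sum(mism) / (400 * 100)
  se <- sqrt(e * (1 - e) / (400 * 100))
  expect_lt(abs(rate - e), 3 * se)

  # error-free saturation: deep coverage recovers the genome's k-mer set
  # (up to the terminal windows that uniform placement rarely covers)
  small <- simulate_genome(5000, seed = 65)
  deep <- simulate_skim(small, read_length = 100, coverage = 30,
                        error_rate = 0, seed = 66)
  genome_set <- o_smer_set(small, 21)
  skim_set <- o_smer_set(deep$seq, 21)
  expect_true(all(skim_set %in% genome_set))  # no spurious k-mers
  expect_gte(length(skim_set) / length(genome_set), 0.999)
})

test_that("ancient fragments match the configured length law", {
  genome <- simulate_genome(5e4, seed = 67)
  a <- simulate_ancient_reads(genome, 5000, mean_insert = 35,
                              min_length = 34, seed = 68)
  expect_true(all(a$length >= 34))
  expect_true(all(nchar(a$seq) == a$length))
  se <- sd(a$length) / sqrt(5000)
  expect_lt(abs(mean(a$length) - 35), 3 * se)
  expect_gt(mean(a$length > 35), 0.05)  # right tail exists
  # deamination off: fragments are exact substrings of either strand
  hits <- vapply(seq_len(50), function(i) {
    s <- a$seq[i]
    grepl(s, genome, fixed = TRUE) || grepl(o_revcomp(s), genome, fixed = TRUE)
  }, logical(1))
  expect_true(all(hits))
})

test_that("deamination concentrates C->T at the 5' terminus and decays", {
  set.seed(69)
  # C-rich template so position-wise rates are well estimated
  genome <- paste(sample(c("C", "A", "T", "G"), 6e4, replace = TRUE,
                         prob = c(0.4, 0.2, 0.2, 0.2)), collapse = "")
  n <- 20000
  p5 <- 0.3; decay <- 0.6
  a <- simulate_ancient_reads(genome, n, mean_insert = 45, min_length = 40,
                              deamination_5p = p5, deamination_decay = decay,
                              seed = 70)
  src <- substring(genome, a$start, a$start + a$length - 1)
  src[a$strand == "-"] <- o_revcomp(src[a$strand == "-"])
  ct_rate <- function(pos) {
    s <- substring(src, pos, pos)
    r <- substring(a$seq, pos, pos)
    sum(s == "C" & r == "T") / max(sum(s == "C"), 1)
  }
  r1 <- ct_rate(1); r2 <- ct_rate(2); r6 <- ct_rate(6); r15 <- ct_rate(15)
  expect_lt(abs(r1 - p5), 0.03)
  expect_lt(abs(r2 - p5 * decay), 0.03)
  expect_gt(r1, r6)
  expect_gt(r6, r15)
  expect_lt(r15, 0.02)
})

test_that("the expected-distinct-k-mer curve has the right limits and ordering", {
  G <- 1e5; L <- 101; k <- 31
  expect_equal(expected_distinct_kmers(0, G, L, k, 0), 0)
  n <- round(c(0.1, 0.5, 1, 2, 5, 20) * G / L)
  e0 <- expected_distinct_kmers(n, G, L, k, 0)
  expect_true(all(diff(e0) > 0))                 # monotone in reads
  expect_true(all(e0 <= G - k + 1))
  expect_gt(e0[length(e0)] / (G - k + 1), 0.99)  # saturates at the genome
  # error curve dominates the error-free curve, increasingly with coverage
  ee <- expected_distinct_kmers(n, G, L, k, 4.4e-3)
  expect_true(all(ee > e0))
  expect_true(all(diff(ee - e0) > 0))
  # monotone in the error rate
  rates <- c(0, 1e-3, 4.4e-3, 1e-2)
  at_1x <- vapply(rates, function(r)
    expected_distinct_kmers(round(G / L), G, L, k, r), numeric(1))
  expect_true(all(diff(at_1x) > 0))
})

test_that("clade genomes share the genus core and nothing else", {
  clade <- simulate_clade(3, 4000, core_fraction = 0.5, seed = 71)
  expect_length(clade$genomes, 3)
  expect_true(all(vapply(clade$genomes, nchar, numeric(1)) == 4000))
  expect_true(all(startsWith(unlist(clade$genomes), clade$core)))
  s <- 21
  priv <- lapply(clade$genomes, function(g) o_smer_set(substring(g, 2001), s))
  expect_length(intersect(priv[[1]], priv[[2]]), 0)
  comm <- simulate_reference_community(2, 2, genome_size = 3000, seed = 72)
  expect_length(comm$genomes, 4)
  expect_s3_class(comm$taxonomy, "skim_taxonomy")
  expect_equal(rank_of(comm$taxonomy, comm$species$taxid[1]), "species")
})
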