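test_that("distinct s-mer counting is exact and strand-invariant", {
  set.seed(30)
  s <- 15
  one <- o_random_dna(1, s)
  expect_equal(estimate_distinct_smers(one, s), 1)
  seqs <- o_random_dna(5, 60)
  expect_equal(estimate_distinct_smers(c(seqs, o_revcomp(seqs)), s),
               estimate_distinct_smers(seqs, s))
  # 1x error-free skim of a random genome vs brute-force set construction
  genome <- simulate_genome(10000, seed = 31)
  skim <- simulate_skim(genome, read_length = 100, coverage = 1,
                        error_rate = 0, seed = 32)
  expect_equal(estimate_distinct_smers(skim$seq, 21),
               length(o_smer_set(skim$seq, 21)))
})

test_that("the sampling estimator lands within 5% on large inputs", {
  genome <- simulate_genome(1.2e6, seed = 33)
  exact <- estimate_distinct_smers(genome, 21, method = "exact")
  est <- estimate_distinct_smers(genome, 21, method = "sample",
                                 sample_bits = 6)
  expect_gt(exact, 1e6)
  expect_lt(abs(est - exact) / exact, 0.05)
})

test_that("grouping cuts sorted counts into geometric bins sized by the max", {
  counts <- c(`1` = 100, `2` = 100, `3` = 100)
  g1 <- group_entries(counts, fp = 0.05)
  expect_equal(max(g1$group), 1L)
  expect_true(all(g1$m == required_bits(100, 0.05)))

  g2 <- group_entries(c(`7` = 10, `8` = 11, `9` = 1e6), fp = 0.05, ratio = 2)
  expect_equal(g2$group[g2$taxid %in% c(7, 8)], c(1L, 1L))
  expect_false(g2$group[g2$taxid == 9] %in% g2$group[g2$taxid %in% c(7, 8)])

  # realized fp of every member never exceeds the target:
  # m_group >= required_bits(n_member, fp) for all members
  set.seed(34)
  counts <- setNames(10^runif(40, 1, 6), seq_len(40))
  g3 <- group_entries(counts, fp = 0.05, ratio = 2)
  expect_true(all(g3$m >= required_bits(g3$n_distinct, 0.05)))
  expect_setequal(g3$taxid, as.integer(names(counts)))  # exactly one group each
  # groups are contiguous ranges of the sorted counts
  expect_true(all(diff(g3$group) >= 0))
})

test_that("build_index makes one entry per taxid and pools multi-file species", {
  comm <- make_fixture_community()
  params <- skim_params(backend = "exact")

  # file-manifest path: two files for one taxid -> union of both files' s-mers
  dir <- tempfile(); dir.create(dir)
  gA <- comm$genomes[["1001"]]
  halves <- c(substring(gA, 1, 6000), substring(gA, 5900, 12000))
  f1 <- file.path(dir, "a1.fasta"); f2 <- file.path(dir, "a2.fasta")
  write_fasta(c(part1 = halves[1]), f1)
  write_fasta(c(part2 = halves[2]), f2)
  manifest <- data.frame(taxid = c(1001L, 1001L), label = "spA",
                         path = c(f1, f2))
  idx <- build_index(manifest, params = params)
  expect_length(idx$entries, 1L)
  probe_s <- o_kmers(substring(gA, 1, 200), params$s)
  probe_e <- o_kmers(substring(gA, 11800, 12000), params$s)
  expect_true(all(filter_contains(idx$entries[["1001"]]$filter, probe_s)))
  expect_true(all(filter_contains(idx$entries[["1001"]]$filter, probe_e)))

  # union property: A+B answers everything A alone answers
  idxA <- build_index(list(`1001` = halves[1]), params = params)
  smersA <- o_smer_set(halves[1], params$s)
  expect_true(all(filter_contains(idx$entries[["1001"]]$filter, smersA)))
  expect_true(all(filter_contains(idxA$entries[["1001"]]$filter, smersA)))

  # 3-species toy database: each species' own reads query positive
  idx3 <- build_index(comm$genomes[1:3], params = params)
  for (id in names(comm$genomes)[1:3]) {
    reads <- simulate_skim(comm$genomes[[id]], read_length = 80, n_reads = 20,
                           error_rate = 0, seed = 35)
    expect_true(all(count_shared_kmers(reads$seq, idx3$entries[[id]]$filter) ==
                      nchar(reads$seq) - params$k + 1))
  }

  expect_error(build_index(list(), params = params), "empty")
  expect_error(build_index(data.frame(taxid = integer(0), label = character(0),
                                      path = character(0)),
                           params = params), "empty")
})

test_that("index directories round-trip and rebuilds are byte-identical", {
  comm <- make_fixture_community()
  params <- skim_params(backend = "bloom")
  idx <- build_index(comm$genomes[1:4], params = params)
  d1 <- tempfile(); d2 <- tempfile()
  write_index(idx, d1)
  idx2 <- build_index(comm$genomes[1:4], params = params)
  write_index(idx2, d2)
  for (f in list.files(d1)) {
    expect_identical(readBin(file.path(d1, f), "raw", file.size(file.path(d1, f))),
                     readBin(file.path(d2, f), "raw", file.size(file.path(d2, f))),
                     info = f)
  }
  back <- read_index(d1)
  expect_equal(names(back$entries), names(idx$entries))
  expect_equal(back$params$k, params$k)
  reads <- simulate_skim(comm$genomes[[1]], read_length = 80, n_reads = 30,
                         error_rate = 0, seed = 36)
  expect_identical(shared_kmer_matrix(reads$seq, back),
                   shared_kmer_matrix(reads$seq, idx))
})
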