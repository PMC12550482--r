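# The candidate-selection / LCA rule, exercised both through prebuilt count
# matrices (assign_from_counts) and end-to-end (assign_batch).

toy_tree <- function() {
  as_taxonomy(data.frame(
    taxid = c(1L, 10L, 11L, 12L, 20L, 21L),
    parent = c(1L, 1L, 10L, 10L, 1L, 20L),
    rank = c("no rank", "genus", "species", "species", "genus", "species"),
    name = c("root", "GenX", "SpX1", "SpX2", "GenY", "SpY1")))
}

test_that("the decision rule follows the shared-k-mer algorithm step by step", {
  tree <- toy_tree()
  p <- skim_params()  # t_c = 0.7, delta = 0.1
  N_Q <- 20L
  run <- function(S) {
    assign_from_counts(matrix(S, nrow = 1), N_Q, c(11L, 12L, 21L), tree, p)
  }
  # two sibling species at 1.0 and 0.95 >= t_min = 0.9 -> genus call
  r <- run(c(20L, 19L, 0L))
  expect_equal(r$taxid, 10L)
  expect_equal(r$n_candidates, 2L)
  expect_equal(r$t_max, 1)
  # second entry at 0.85 < t_min -> single candidate, species call
  r <- run(c(20L, 17L, 0L))
  expect_equal(r$taxid, 11L)
  expect_equal(r$n_candidates, 1L)
  # t_max = 0.65 < t_c -> unidentified
  r <- run(c(13L, 0L, 0L))
  expect_equal(r$taxid, 0L)
  expect_equal(r$n_candidates, 0L)
  # boundary tie: S_min = (1 - 0.1) * 20 = 18 exactly is a candidate
  r <- run(c(20L, 18L, 0L))
  expect_equal(r$n_candidates, 2L)
  expect_equal(r$taxid, 10L)
  # candidates spanning both genera resolve to the root
  r <- run(c(20L, 0L, 19L))
  expect_equal(r$taxid, 1L)
})

test_that("short reads are unidentified, not errors", {
  comm <- make_fixture_community()
  idx <- build_index(comm$genomes[1:3], params = skim_params(backend = "exact"))
  r <- assign_read(substring(comm$genomes[[1]], 1, 20), idx, comm$taxonomy)
  expect_equal(r$taxid, 0L)
  expect_equal(r$n_kmers, 0L)
  expect_true(is.na(r$t_max))
})

test_that("batch assignment is an order-preserving map of the per-read rule", {
  comm <- make_fixture_community()
  tree <- comm$taxonomy
  p <- skim_params(backend = "exact")
  idx <- build_index(comm$genomes, params = p)
  reads <- simulate_ancient_reads(comm$genomes[["1004"]], 80, mean_insert = 45,
                                  seed = 40)
  empty <- assign_batch(character(0), idx, tree)
  expect_equal(nrow(empty), 0L)
  batch <- assign_batch(reads$seq, idx, tree, ids = reads$id)
  expect_equal(batch$read_id, reads$id)
  single <- do.call(rbind, lapply(seq_len(nrow(reads)), function(i)
    assign_read(reads$seq[i], idx, tree, ids = reads$id[i])))
  expect_equal(batch, single)
  # permutation invariance
  set.seed(41)
  perm <- sample(nrow(reads))
  shuffled <- assign_batch(reads$seq[perm], idx, tree, ids = reads$id[perm])
  expect_equal(shuffled, batch[perm, ], ignore_attr = TRUE)
})

test_that("assignment agrees with the brute-force oracle on random databases", {
  set.seed(42)
  comm <- make_fixture_community(seed = 43, genome_size = 3000)
  tree <- comm$taxonomy
  tax_df <- community_tax_df(tree)
  p <- skim_params(k = 16L, z = 3L, backend = "exact")
  idx <- build_index(comm$genomes, params = p)
  taxids <- as.integer(names(comm$genomes))
  smer_sets <- lapply(comm$genomes, o_smer_set, s = p$s)
  for (i in 1:60) {
    src <- sample(names(comm$genomes), 1)
    st <- sample(2500, 1)
    read <- substring(comm$genomes[[src]], st, st + sample(20:60, 1))
    if (runif(1) < 0.5) read <- o_mutate(read, 0.02)
    S <- vapply(smer_sets, function(ss) o_count_shared(read, ss, p$k, p$z),
                integer(1))
    want <- o_assign(S, max(0L, nchar(read) - p$k + 1L), taxids, tax_df,
                     p$t_c, p$delta)
    got <- assign_read(read, idx, tree, p)
    expect_equal(got$taxid, want$taxid)
    if (!is.na(want$t_max)) expect_equal(got$t_max, want$t_max)
    expect_equal(got$n_candidates, length(want$cand))
  }
})

test_that("raising t_c never decreases the unidentified count; delta widens LCAs", {
  comm <- make_fixture_community(core_fraction = 0.7)
  tree <- comm$taxonomy
  p <- skim_params(backend = "exact")
  idx <- build_index(comm$genomes, params = p)
  reads <- simulate_ancient_reads(comm$genomes[["1001"]], 150, mean_insert = 40,
                                  seed = 44)
  reads$seq <- o_mutate(reads$seq, 0.01)
  counts <- shared_kmer_matrix(reads$seq, idx)
  nk <- pmax(0L, nchar(reads$seq) - p$k + 1L)
  unid <- function(tc) {
    q <- p; q$t_c <- tc
    sum(assign_from_counts(counts, nk, as.integer(names(comm$genomes)),
                           tree, q)$taxid == 0L)
  }
  u <- vapply(c(0.3, 0.5, 0.7, 0.9, 1.0), unid, numeric(1))
  expect_true(all(diff(u) >= 0))
  ncand <- function(delta) {
    q <- p; q$delta <- delta
    assign_from_counts(counts, nk, as.integer(names(comm$genomes)),
                       tree, q)$n_candidates
  }
  expect_true(all(ncand(0.2) >= ncand(0.05)))
})

test_that("the abundance cutoff keeps a taxon only above r of total reads", {
  asg <- data.frame(
    read_id = sprintf("r%d", 1:30),
    n_kmers = 2L, s_max = 2L, t_max = 1, n_candidates = 1L,
    taxid = c(rep(101L, 11L), rep(102L, 10L), rep(103L, 5L), rep(0L, 4L)))
  total <- 1e6
  out <- filter_low_abundance(asg, r = 1e-5, total_reads = total)
  expect_true(all(out$taxid[1:11] == 101L))   # 11 / 1e6 > 1e-5: retained
  expect_true(all(out$taxid[12:21] == 0L))    # 10 / 1e6 == 1e-5: dropped
  expect_true(all(out$taxid[22:26] == 0L))    # 5 / 1e6 <= 1e-5: dropped
  expect_identical(out[c("read_id", "t_max", "n_candidates")],
                   asg[c("read_id", "t_max", "n_candidates")])
  # r = 0 retains every assigned taxon
  all_kept <- filter_low_abundance(asg, r = 0, total_reads = total)
  expect_identical(all_kept$taxid, asg$taxid)
  expect_error(filter_low_abundance(asg, r = 1e-5, total_reads = 10),
               "total_reads")
})

test_that("assignment TSV output carries one formatted row per read", {
  comm <- make_fixture_community()
  idx <- build_index(comm$genomes[1:3], params = skim_params(backend = "exact"))
  reads <- simulate_ancient_reads(comm$genomes[["1001"]], 25, seed = 45)
  asg <- assign_batch(reads$seq, idx, comm$taxonomy, ids = reads$id)
  path <- tempfile(fileext = ".tsv")
  write_assignments(asg, path)
  back <- read.delim(path)
  expect_equal(nrow(back), 25L)
  expect_named(back, c("read_id", "t_max", "n_candidates", "taxid"))
  expect_equal(back$taxid, asg$taxid)
})
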