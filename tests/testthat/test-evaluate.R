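eval_tree <- function() {
  as_taxonomy(data.frame(
    taxid = c(1L, 500L, 510L, 511L, 512L, 513L, 520L, 521L, 600L, 610L, 611L),
    parent = c(1L, 1L, 500L, 510L, 510L, 511L, 500L, 520L, 1L, 600L, 610L),
    rank = c("no rank", "family", "genus", "species", "species", "subspecies",
             "genus", "species", "family", "genus", "species"),
    name = c("root", "FamP", "GenP1", "SpP1a", "SpP1b", "SpP1a-sub",
             "GenP2", "SpP2a", "FamQ", "GenQ1", "SpQ1a")))
}

test_that("the eight categories follow lineage containment", {
  tree <- eval_tree()
  cat1 <- function(a, t) as.character(categorize_assignments(a, t, tree))
  expect_equal(cat1(511, 511), "target_species")
  expect_equal(cat1(510, 511), "target_genus")     # correct genus only
  expect_equal(cat1(500, 511), "target_family")    # correct family only
  expect_equal(cat1(1, 511), "higher_target")      # correct, above family
  expect_equal(cat1(512, 511), "incorrect_species")  # congener species
  expect_equal(cat1(521, 511), "incorrect_genus")    # confamilial, other genus
  expect_equal(cat1(520, 511), "incorrect_genus")
  expect_equal(cat1(611, 511), "incorrect_family")   # other family
  expect_equal(cat1(600, 511), "incorrect_family")
  expect_equal(cat1(0, 511), "unidentified")
  # uncommon ranks resolve by containment: a subspecies of the target is
  # inside the correct species; the same node against a congener truth is a
  # within-genus misassignment
  expect_equal(cat1(513, 511), "target_species")
  expect_equal(cat1(513, 512), "incorrect_species")
  # vectorized with per-read truths, and the partition property
  set.seed(80)
  a <- sample(c(0L, 511L, 512L, 510L, 521L, 611L, 1L), 200, replace = TRUE)
  cats <- categorize_assignments(a, 511L, tree)
  expect_equal(sum(table(cats)), 200)
  expect_error(categorize_assignments(9999L, 511L, tree), "not in taxonomy")
})

test_that("category counts partition real assignment batches", {
  comm <- make_fixture_community()
  idx <- build_index(comm$genomes, params = skim_params(backend = "exact"))
  reads <- simulate_ancient_reads(comm$genomes[["1001"]], 200, seed = 81)
  asg <- assign_batch(reads$seq, idx, comm$taxonomy, ids = reads$id)
  cc <- category_counts(asg, 1001, comm$taxonomy)
  expect_equal(sum(cc), 200)
  expect_named(cc, assignment_categories(), ignore.order = TRUE)
  cm <- confusion_matrix(rep(1001L, nrow(asg)), asg$taxid)
  expect_equal(sum(cm), nrow(asg))
})

test_that("a one-point sweep reproduces a plain assignment run", {
  comm <- make_fixture_community()
  tree <- comm$taxonomy
  p <- skim_params(backend = "exact")
  idx <- build_index(comm$genomes, params = p)
  reads <- simulate_ancient_reads(comm$genomes[["1002"]], 150, seed = 82)
  sw <- sweep_parameters(reads$seq, idx, tree, 1002,
                         t_c_grid = 0.7, delta_grid = 0.1, params = p)
  expect_equal(nrow(sw$table), 1L)
  asg <- assign_batch(reads$seq, idx, tree, p)
  cc <- category_counts(asg, 1002, tree)
  for (nm in assignment_categories())
    expect_equal(sw$table[[nm]], unname(cc[nm]))
})

test_that("sweeping finds the zero-off-target optimum on clean reads", {
  comm <- make_fixture_community()
  tree <- comm$taxonomy
  p <- skim_params(backend = "exact")
  idx <- build_index(comm$genomes, params = p)
  reads <- simulate_ancient_reads(comm$genomes[["1003"]], 200, seed = 83)
  sw <- sweep_parameters(reads$seq, idx, tree, 1003,
                         t_c_grid = c(0.5, 0.7, 1.0),
                         delta_grid = c(0.05, 0.1), params = p)
  # error-free reads from an indexed species: nothing off target anywhere
  expect_true(all(sw$table$off_target == 0))
  expect_true(all(sw$table$target_species + sw$table$target_genus +
                    sw$table$unidentified == 200))
  # the reported optimum matches exhaustive enumeration of the grid table
  ratio <- ifelse(sw$table$off_target == 0, Inf,
                  sw$table$target_species / sw$table$off_target)
  best_rows <- which(ratio == max(ratio))
  expect_true(sw$best$t_c %in% sw$table$t_c[best_rows])
})

test_that("coverage titration grows correct calls with diminishing returns", {
  set.seed(84)
  target <- simulate_genome(3e5)
  others <- setNames(lapply(1:2, function(i) simulate_genome(1e5)),
                     c("2001", "2002"))
  tree <- as_taxonomy(data.frame(
    taxid = c(1L, 2000L, 1001L, 2001L, 2002L),
    parent = c(1L, 1L, 2000L, 1L, 1L),
    rank = c("no rank", "genus", "species", "species", "species"),
    name = c("root", "GenT", "SpT", "Bg1", "Bg2")))
  pool <- simulate_skim(target, read_length = 101, coverage = 4,
                        error_rate = 4.4e-3)$seq
  query <- simulate_ancient_reads(target, 2000, mean_insert = 40)$seq
  p <- skim_params()
  tt <- coverage_titration(pool, others, c(0, 0.25, 0.5, 1), query, 1001L,
                           tree, p)
  expect_equal(tt$target_species[tt$fraction == 0], 0)
  correct <- tt$target_species + tt$target_genus
  expect_true(all(diff(correct) >= 0))
  expect_true(all(diff(tt$n_distinct) > 0))
  expect_true(all(diff(tt$unidentified) <= 0))
})
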