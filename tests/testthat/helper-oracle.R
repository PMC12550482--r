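# Independent oracles used to cross-check the compiled implementation.
# These are deliberately written against different machinery: Biostrings for
# reverse complements, plain substring() for window extraction, R hash sets
# (%in%) for membership, and an ancestor-set intersection for the LCA.

o_revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

o_canonical <- function(x) {
  x <- toupper(x)
  rc <- o_revcomp(x)
  ifelse(x <= rc, x, rc)
}

# all windows of `seq`, NA where the window holds a non-ACGT character
o_windows <- function(seq, len) {
  seq <- toupper(seq)
  n <- nchar(seq) - len + 1
  if (n < 1) return(character(0))
  w <- substring(seq, seq_len(n), seq_len(n) + len - 1)
  w[grepl("[^ACGT]", w)] <- NA_character_
  w
}

o_kmers <- function(seq, len) {
  w <- o_windows(seq, len)
  w <- w[!is.na(w)]
  if (length(w) == 0) return(character(0))
  o_canonical(w)
}

o_smer_set <- function(seqs, s) {
  unique(unlist(lapply(seqs, o_kmers, len = s), use.names = FALSE))
}

# shared-k-mer count of one read against a true s-mer set
o_count_shared <- function(read, smer_set, k, z) {
  s <- k - z + 1
  w <- o_windows(read, s)
  member <- !is.na(w) & o_canonical(ifelse(is.na(w), "A", w)) %in% smer_set
  nk <- nchar(read) - k + 1
  if (nk < 1) return(0L)
  sum(vapply(seq_len(nk), function(j) all(member[j:(j + z - 1)]), logical(1)))
}

# LCA by ancestor-set intersection (deepest common ancestor)
o_lca <- function(tax_df, taxids) {
  parent <- setNames(as.integer(tax_df$parent), as.character(tax_df$taxid))
  root <- tax_df$taxid[tax_df$taxid == tax_df$parent]
  anc <- function(id) {
    path <- id
    while (id != root) {
      id <- parent[[as.character(id)]]
      path <- c(path, id)
    }
    path
  }
  paths <- lapply(unique(as.integer(taxids)), anc)
  common <- Reduce(intersect, paths)
  depth <- vapply(common, function(a) length(anc(a)), integer(1))
  common[which.max(depth)]
}

# step-by-step reimplementation of the per-read decision, used to check
# assign_from_counts / assign_batch against precomputed true counts
o_assign <- function(S, N_Q, taxids, tax_df, t_c, delta) {
  if (N_Q < 1) return(list(taxid = 0L, t_max = NA_real_, cand = integer(0)))
  S_max <- max(S)
  t_max <- S_max / N_Q
  if (t_max < t_c) return(list(taxid = 0L, t_max = t_max, cand = integer(0)))
  S_min <- (t_max - delta) * N_Q
  cand <- which(S >= S_min - 1e-9 & S <= S_max)
  list(taxid = o_lca(tax_df, taxids[cand]), t_max = t_max, cand = cand)
}

# taxonomy of a simulated reference community, as the plain data frame the
# oracles consume
community_tax_df <- function(tree) {
  data.frame(taxid = as.integer(names(tree$parent)),
             parent = as.integer(tree$parent),
             stringsAsFactors = FALSE)
}

# small random DNA through the oracle path (independent of cpp_random_kmers)
o_random_dna <- function(n, len) {
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = ""),
    character(1))
}

# standard small fixture: 3 genera x 3 species, 2 families
make_fixture_community <- function(seed = 101, genome_size = 12000,
                                   core_fraction = 0.5) {
  simulate_reference_community(n_genera = 3, species_per_genus = 3,
                               genome_size = genome_size,
                               core_fraction = core_fraction, seed = seed)
}

# plain-R substitution mutator (input generation for randomized tests)
o_mutate <- function(seqs, rate) {
  vapply(seqs, function(s) {
    ch <- strsplit(s, "", fixed = TRUE)[[1]]
    hit <- runif(length(ch)) < rate & ch %in% c("A", "C", "G", "T")
    ch[hit] <- vapply(ch[hit], function(b)
      sample(setdiff(c("A", "C", "G", "T"), b), 1), character(1))
    paste(ch, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# Vectorized brute-force shared-k-mer matrix: every read's s-mer windows are
# extracted with substring(), canonicalized through Biostrings, and checked
# against each entry's true s-mer set; a k-mer window counts when its z
# consecutive s-mers are all members.
o_shared_matrix <- function(reads, entry_sets, k, z) {
  s <- k - z + 1
  L <- nchar(reads)
  w <- pmax(0L, L - s + 1L)
  nk <- pmax(0L, L - k + 1L)
  S <- matrix(0L, length(reads), length(entry_sets))
  if (sum(w) == 0) return(S)
  readidx <- rep(seq_along(reads), w)
  pos <- sequence(w)
  smer <- substring(reads[readidx], pos, pos + s - 1L)
  ok <- !grepl("[^ACGT]", smer)
  canon <- rep(NA_character_, length(smer))
  if (any(ok)) {
    u <- unique(smer[ok])
    canon[ok] <- o_canonical(u)[match(smer[ok], u)]
  }
  is_kmer_start <- pos <= nk[readidx]
  for (j in seq_along(entry_sets)) {
    m <- ok & canon %in% entry_sets[[j]]
    allz <- m
    for (t in seq_len(z - 1))
      allz <- allz & c(m[-seq_len(t)], rep(FALSE, t))
    v <- as.integer(allz & is_kmer_start)
    agg <- rowsum(v, readidx)
    S[as.integer(rownames(agg)), j] <- agg[, 1]
  }
  S
}

# Vectorized oracle for the full per-read decision, LCA via ancestor-set
# intersection.
o_assign_batch <- function(S, nk, taxids, tax_df, t_c, delta) {
  n <- nrow(S)
  s_max <- do.call(pmax, as.data.frame(S))
  t_max <- ifelse(nk > 0, s_max / nk, NA_real_)
  taxid <- integer(n)
  ncand <- integer(n)
  idd <- which(!is.na(t_max) & t_max >= t_c)
  if (length(idd)) {
    s_min <- (t_max[idd] - delta) * nk[idd]
    memb <- S[idd, , drop = FALSE] >= (s_min - 1e-9)
    ncand[idd] <- as.integer(rowSums(memb))
    keys <- apply(memb, 1, function(r) paste(which(r), collapse = ","))
    for (key in unique(keys)) {
      cols <- as.integer(strsplit(key, ",", fixed = TRUE)[[1]])
      taxid[idd[keys == key]] <- o_lca(tax_df, taxids[cols])
    }
  }
  data.frame(t_max = t_max, n_candidates = ncand, taxid = taxid)
}
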