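---
title: "Annotating short metagenomic reads against unassembled genome skims"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Annotating short metagenomic reads against unassembled genome skims}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(skimdex)
```

## The problem

Shotgun sequencing of environmental DNA — in particular sedimentary ancient
DNA — produces very short reads (a few tens of bases) that must be assigned
to taxa against a reference database.  Assembled reference genomes are too
sparse taxonomically; low-coverage genome skims of voucher specimens cover
far more species, but assembling them into contigs discards most of their
information, because at 0.5–1× depth the majority of the genome is covered
by isolated reads that never assemble.  skimdex therefore indexes the skims
*unassembled*: each reference species becomes the set of k-mers of its raw
reads, stored in a Bloom filter, and query reads are scored by how many of
their k-mers each reference set contains.

## The data structures

**Single-hash Bloom filter.**  Each index entry is a bit field of `m` bits
with one seeded hash function.  After inserting `n` distinct s-mers the
expected fill fraction is `1 - exp(-n/m)`, which is also the false-positive
probability of a random membership query.  Solving for a target rate `fp`
gives the sizing law implemented by `required_bits()`:

```
m = ceiling(-n / log(1 - fp))       # e.g. n = 1000, fp = 0.05 -> 19,496 bits
```

One hash function is used deliberately: it is the configuration under which
this law is exact.  Filters can never return a false negative.

**Composite k-mer queries.**  Queries do not test a k-mer directly.  A
k-mer of length `k = 34` is decomposed into its `z = 3` constituent s-mers
(the windows of length `s = k - z + 1 = 32` inside it) and is reported
present only when all three are members.  A composite false positive
requires `z` independent spurious hits, so the per-k-mer rate drops from
`fp = 0.05` to about `fp^z = 1.25e-4`.  Both rates are measured empirically
by `measure_bloom_fp()` / `measure_findere_fp()` and recomputed by
`scripts/acceptance.R`.

**Canonical form.**  Every s-mer and k-mer is replaced by the lexicographic
minimum of itself and its reverse complement before hashing or set
membership, because query reads come from either strand.  Windows containing
a non-ACGT character are skipped during extraction but still count toward a
read's window total `N_Q` — an ambiguous window cannot support a match.

## Index construction

`build_index()` pools all sequences mapped to one taxid into one entry
(several skims of a species form a single entry), counts its distinct
canonical s-mers exactly with a hash set, and then groups entries by that
k-mer diversity before sizing the filters.  Grouping uses geometric bins
(ratio 2 by default): entries are sorted by their distinct counts and an
entry with count `n` joins bin `floor(log2(n / n_min))`.  All entries in a
bin receive the bin's common bit size, computed from the bin's *largest*
count, so smaller members are over-provisioned and their realized rate
falls below the 0.05 target — storage is traded for never exceeding the
target.  The bin rule itself is this package's choice; only the fact of
diversity-based same-size grouping is fixed by the design.

For large inputs `estimate_distinct_smers(method = "sample")` offers a
one-in-2^b hash-sampled cardinality estimate (relative error about
`1/sqrt(distinct / 2^b)`); the exact counter remains the default because
desk-scale inputs do not need the approximation and exactness is testable.

## The assignment rule

For a query read `Q` of length `L_Q`, with `N_Q = L_Q - k + 1` k-mer
windows and `S_G` shared k-mers against each entry `G`:

1. `S_max = max(S_G)`, `t_max = S_max / N_Q`;
2. reads with `t_max < t_c` (default 0.7) are *unidentified* — they are
   still emitted, with taxid 0, so output rows equal input reads;
3. otherwise every entry with `S_G` in the closed interval
   `[(t_max - delta) * N_Q, S_max]` (default `delta` 0.1) is a candidate,
   with the lower bound kept real-valued — no rounding — and inclusive, so
   boundary ties enter the candidate set (a small numeric tolerance guards
   the floating-point product `delta * N_Q`);
4. the read is assigned the lowest common ancestor of all candidate taxids.

Reads shorter than `k` have `N_Q = 0` and are unidentified by definition,
never an error, since real short-fragment data contains them.  After a
batch, `filter_low_abundance()` resets to unidentified every taxon that
received no more than a proportion `r = 1e-5` of the *total queried* reads
(not merely the assigned ones — the stricter denominator), absorbing the
spray of composite false positives expected at the `1.25e-4` per-k-mer
rate.

The same rule drives contaminant cleaning (`clean_skim()`): bacteria,
fungi, algae and human references and the target clade are each one entry
under a flat root.  Reads assigned to a contaminant entry are discarded;
unidentified reads and reads whose near-best matches span the target (LCA
at the root) are kept.  Keeping ambiguous reads is a deliberate asymmetry:
a plant-genome read wrongly discarded is lost forever, while a contaminant
read wrongly kept is unlikely to survive the later per-k-mer scoring.
Cleaning uses the same `t_c`/`delta` defaults as querying but accepts its
own parameter set, since nothing forces the two stages to share them.

## Synthetic data: what it emulates, and what not

The simulators generate the full study: `simulate_genome()` (uniform
random bases), `simulate_skim()` (fixed-length reads, uniform placement,
both strands, iid substitutions at a default per-base rate of 4.4e-3 — the
rate that fits observed distinct-k-mer counts of Illumina skims),
`simulate_ancient_reads()` (short fragments, mean 35, minimum 34, optional
terminal deamination), and `simulate_reference_community()` (genera built
from a shared "core" plus species-private sequence, with a matching
taxonomy).

Choices worth recording:

* **Fragment lengths** are a *shifted* log-normal:
  `L = (min_length - 1) + X` with `X` log-normal and `E[L]` equal to
  `mean_insert`.  A log-normal truncated at the minimum was considered and
  rejected: with a mean of 35 and a floor of 34 the truncated-mean
  calibration has its root ~30 standard deviations into the tail, where
  the CDF underflows and the sampler degenerates to a point mass.  The
  shifted form keeps the right-skewed shape, the hard floor, and an exact
  mean.
* **Deamination** is a geometric profile: C→T with probability
  `p * decay^d` at distance `d` from the 5' end, mirrored as G→A from the
  3' end — the double-stranded damage pattern.  It is off by default
  because the benchmark reads it mimics are length-reduced modern reads,
  not damage-injected ones.
* **Community structure** is idealized: within a genus, species share an
  identical core region and are unrelated elsewhere.  Real congeners
  diverge continuously, so real species-level calls are noisier than the
  fixture suggests; what the fixture isolates is the LCA logic (core reads
  must resolve to the genus, private reads to the species).  Passing tests
  demonstrate the algorithm, not field-realistic error rates.
* Random genomes have no repeats, so cross-entry k-mer collisions are
  essentially absent outside designed cores; real plant genomes are
  repeat-rich and shift more reads toward higher-rank LCAs.

## The expected distinct k-mer curve

`expected_distinct_kmers()` gives the analytic expectation for the
distinct canonical k-mer count of a skim, the quantity that governs how
reference completeness grows with sequencing effort.  Three terms:
collection of the genome's own k-mers (each needs a covering read with an
error-free window), single-error variants (`3k` per genome window, each
needing a covering read with exactly that substitution — identical errors
in different reads collapse, which is what bends the curve), and
multi-error k-mers (effectively never repeated, hence linear).  The model
is validated against direct simulation at a 1 Mb scale and matches within
2% between 0.1× and 5× coverage at the 4.4e-3 error rate; with the error
rate at zero it saturates monotonically at the genome's k-mer count.  It
is derived here from first principles and is not claimed to be bit-equal
to any external formulation.

## Problem sizes and numerical choices

The test-suite experiments run at desk scale, chosen so the whole suite
stays in the minutes range while every qualitative regime (sub-saturation,
saturation, error-dominated growth) is visited: 1 Mb genomes for the
distinct-k-mer curve, a 2 Mb target titrated from 0× to 5× for the
coverage experiment, 10-entry communities of 20 kb species for parameter
recovery, and 50 randomized databases of 1–50 kb genomes for oracle
equivalence.  Monte-Carlo false-positive estimates use 1e5 inserted
s-mers, 1e5 single probes and 1e7 composite queries, which put three
binomial standard errors well inside the quantities being verified.

Other numerical points: the candidate lower bound uses a `1e-9` absolute
tolerance; hash seeds are recorded in every filter header and default to
1, so rebuilding an index from the same inputs is byte-identical;
`t_max` at exactly `t_c` counts as identified (the cutoff is inclusive,
and documented as such since the boundary case is not otherwise fixed).

## Known limitations

A single substitution near the centre of a short read removes nearly all
of its k-mer windows, so centre-damaged reads are lost to k-mer scoring —
they would need a mapping-based rescue, which is out of scope.  Taxa whose
reference entries are absent produce unidentified reads rather than false
positives (the exclusion tests quantify this), but the fixed abundance
cutoff `r` is known to mis-handle strongly skewed metagenomes, where reads
of a dominant taxon's relatives can exceed `r` while genuinely present
rare taxa fall below it.  Paired-end handling is out of scope: inputs are
assumed merged.
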