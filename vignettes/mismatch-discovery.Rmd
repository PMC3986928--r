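---
title: "Quality-based cleaning and mismatch discovery in pooled 454 transcriptome assemblies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quality-based cleaning and mismatch discovery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(contigvar)
```

## The problem

De novo 454 (pyrosequencing) transcriptome projects in non-model organisms
typically pool cDNA from a small number of diploid individuals, assemble the
reads into contigs, and then mine the padded multiple alignments for
candidate SNPs. Two artefact classes dominate such alignments: false
insertions caused by homopolymer miscalls (the signature 454 error mode,
which appears as pad-only columns in the padded assembly), and spurious
substitution "variants" carried by one or two low-quality base calls.
Relaxed in-silico variant picking from this kind of data is known to produce
candidate lists whose validation rate at the genotyping stage is poor, so
the whole pipeline is built around stringent, auditable filtering.

`contigvar` implements the post-assembly stages: masking, cleaning, IUPAC
consensus editing, mismatch calling with a binomial false-positive filter,
density summaries, a contaminant screen for blast hit tables, a permutation
test for organ-level over-expression of GO-term contig groups, a rarefaction
bootstrap (RaBoT) for comparing contig counts between unevenly sequenced
libraries, and a ground-truth simulator that exercises every stage.

## The filtering model

### Masking

Bases in a padded contig alignment are masked (annotated, never deleted)
column by column, by the first rule that fires:

1. **singleton** — a variant state (a base or gap differing from the column
   majority) supported by exactly one read;
2. **low_freq** — a variant state whose frequency among the column's
   unmasked non-N bases is below `freq_min` (default 0.1);
3. **low_qual** — at columns still polymorphic after the first two rules,
   any base with quality below `qual_min` (default 20);
4. **is_N** — N calls are always masked.

Each rule is evaluated on the column state left by the previous one, in a
single pass. Iterating the rules to a fixpoint could cascade masks well
beyond what the rule list describes (masking a variant lowers the
denominator, which can push another state under the threshold, and so on),
so the single pass is deliberate. Three choices here were genuinely open and
are fixed as follows:

* **Frequency denominator**: all unmasked non-N bases in the column,
  including the variant itself (so 2 copies among 21 bases is 0.095 and is
  masked; 2 among 20 is exactly 0.1 and survives).
* **Ties for "majority"**: when two states tie, the state earliest in the
  order `A < C < G < T < *` is deemed the reference and the others are
  variants. The choice is arbitrary but deterministic; a real base wins a
  tie against the gap state.
* **Gap states are states**: the frequency and singleton rules treat pads
  like any other variant state, and a column is "polymorphic" for the
  quality rule when it has at least two distinct unmasked states, pads
  included. Whether the original pipeline applied the frequency rule to gap
  variants is not documented; applying it uniformly is the simpler model
  and treats the dominant 454 error mode on the same footing.

### Pad qualities

Assemblers give no quality for pads. A pad inherits the minimum quality of
its nearest non-pad neighbours on each side (one-sided at read ends). A pad
is thereby never more trusted than its local context, which matters because
pads participate in the per-base quality rule and in mean-quality reporting.

### Cleaning and consensus

The cleaning step deletes every column whose unmasked content contains no
real base (A/C/G/T) — columns made of pads and masked bases only. This is
where homopolymer false-insertion columns disappear. The surviving column
indices (`kept_cols`) keep the provenance map back to original padded
coordinates; all reports are 1-based in cleaned-column space.

The consensus is edited per kept column as the IUPAC code of the unmasked
real-base states with frequency at least 0.1 among unmasked real bases.
Columns where unmasked pads outnumber unmasked real bases are reported in
lowercase, flagging a likely deletion; a kept column always has at least one
unmasked real base, so `N` appears only for degenerate inputs.

### Mismatch records and the binomial filter

Every kept column with two or more distinct unmasked states yields one
record: states and counts, unmasked depth (pads included), per-state mean
qualities, minor allele frequency, and a class — *transition* (A/G, C/T),
*transversion* (other substitution pairs), *indel* (a gap state among two
states), or *multiallelic* (more than two states; transitions and
transversions are tallied over biallelic substitutions only).

The probabilistic filter reasons from the sequencing design: with `g`
genotypes pooled, `2N = 2g` gametes were sequenced, so a genuine variant has
expected pool frequency at least `p = 1/2N` (0.25 for the default two
genotypes). For a site with minor count `t` at depth `x`, the cumulative
binomial probability

$$P(K \le t) = \sum_{k=0}^{t} \binom{x}{k} p^k (1-p)^{x-k}$$

measures how improbably rare the observation would be for a true
minimum-frequency variant; records with `P < 0.05` are flagged as likely
false positives. The worked configurations: 3 of 29 gives `P = 0.0455 < 0.05`
(discarded), while 2 of 8 — the minimal configuration at the 8-read depth
cutoff — has point probability 0.31, far above the threshold. (The source
study quotes 0.31, which is the point probability of exactly 2 of 8; the
cumulative value is 0.679. Both functions are provided; the worked example
is reproduced with the point probability, and the filter itself always uses
the cumulative one.)

Two further flags: **adjacent** marks *all* members of any run of records at
consecutive cleaned positions (adjacent mismatches are typical misassembly
signatures; the rule list does not single out either member, so both are
flagged), and **low_depth** marks records below `depth_min = 8`.
Post-filtering is non-destructive — every record is returned with its flags,
and `passed` is true when none fired.

### Density summaries

The summary mirrors the per-species mismatch table layout: the adjacency and
depth filters apply in both blocks, and the "after" block additionally drops
binomial failures — the table's before/after axis is the binomial test.
Mismatch density is mismatches per 100 bp with the denominator restricted to
kept columns of unmasked depth at least `depth_min`, so the before/after
densities share a denominator and filtering can only lower the density.
`Ti/Tv` is reported as `NA` when no transversions remain.

## The annotation screen

The contaminant screen consumes a precomputed blast hit table: a contig is
*clean* when at least one of its `k = 10` lowest-e-value hits below
`e_max = 1e-25` comes from a green-plant genus, *contaminant* when
informative hits exist but none of the top-10 is green-plant, and
*no_informative_hit* otherwise (kept, unannotated). The genus lookup is a
user-supplied offline table, and a genus missing from it is an error rather
than a silent non-plant. "Informative" descriptions are defined by a
configurable blacklist (defaults: unknown / hypothetical / predicted protein
/ unnamed) since no formal definition exists; the original screen was
semi-automated with human verification, and this implementation is fully
automatic.

## The GO permutation test

Read counts per contig and organ proxy expression level. For a GO term the
observed statistic is the mean count over the term's contigs with nonzero
counts in that organ. The organ's count vector is permuted over *all*
contigs (zeros stay in the pool; the zero-exclusion is re-applied after
assignment, mirroring the observed statistic) 1000 times, and a term is
called over-expressed when the observed mean exceeds more than 95% of its
permuted means. A `pool = "nonzero"` variant permutes only among expressed
contigs for sensitivity analysis. The test is one-sided by design;
under-expression shows up descriptively in the permuted-difference
quantiles. No multiple-testing correction is applied by default (matching
the original analysis); Benjamini–Hochberg adjusted permutation p-values are
available behind a flag. All terms are evaluated against the same
permutation stream, so term-to-term independence of the calls is *not*
claimed; permutations within each organ make the test immune to unequal
library sizes. Permutations where every contig assigned to a term draws a
zero have an undefined mean and are dropped from that term's denominator.

## RaBoT

The rarefaction bootstrap compares the number of contigs reached by the
smaller library with the distribution of the same statistic over
equal-sized, without-replacement subsamples of the larger library (100 by
default). The reported P-value is the fraction of bootstrapped values
*strictly* above the empirical one; ties count as not above, so identical
libraries give `P = 0`. Because subsamples are not independent, no
parametric test is attempted. One approximation is documented and
deliberate: contig membership comes from the fixed assembly's read-to-contig
map rather than reassembling every subsample (which would be
assembler-dependent and computationally infeasible); the two coincide
whenever assembly membership is stable under subsampling.

## The simulated world

The generator emulates the study's data structures with defaults stated
once:

* two diploid genotypes pooled, hence 4 gametes and planted variant
  frequencies `k/4` with `k ∈ {1, 2}` (0.25 and 0.5);
* contig lengths around 460 ± 60 bp (the study's per-species means span
  414–523 bp), 6.5 reads per contig on average with a negative-binomial
  right tail (the study reports 6–7), read lengths 280 ± 60 bp;
* per-base substitution error 0.5%; homopolymer over/under-calls per read
  and per run of length `L` with probability `min(0.02, 0.004·(L−1))`,
  emitted as pad columns (insertions) or in-read pads (deletions), split
  evenly — rates chosen as typical of 454 chemistry where indel errors
  dominate and grow with run length;
* qualities with mean 32 decaying quadratically by 12 toward the read 3'
  end (s.d. 4, clipped to [4, 40]), written in original read orientation so
  reverse-strand attachment is exercised;
* organ proportions dominated by roots (54%), with a small untagged
  fraction, mirroring the library partitioning.

Reads are emitted pre-aligned — the simulator plays the assembler — and
coverage is forced contiguous (the contig is truncated to the covered span),
since assembler contigs cannot contain internal zero-coverage columns.

What a green test does and does not establish: the simulator plants variants
as substitutions only, errors are independent across reads, paralog
collapse/misassembly is not simulated, and qualities are uninformative about
whether a call is actually erroneous. Consequently recovery tests validate
the bookkeeping (coordinates through masking, cleaning and padding; filter
decisions; summary arithmetic), not the field error model. One property of
any finite-coverage world is worth stating plainly: in depth-1 stretches an
error in the lone covering read is uncorrectable by masking rules — the
consensus faithfully copies it — so consensus-equals-reference holds at
every position *not* touched by a simulated error event, and the truth set
records exactly which positions those are.

## Numerical and degenerate-input choices

* Binomial probabilities go through `stats::dbinom`/`pbinom`; the test suite
  cross-checks them against term-wise brute-force summation for all
  `t ≤ x ≤ 60` at three values of `p` (max abs error below 1e−12).
* Record flags are order-independent: records are sorted by contig and
  cleaned position before adjacency is computed, and re-ordering the input
  cannot change any flag.
* Empty cases: a contig with no polymorphic columns yields an empty record
  table; a zero density denominator reports `NA`; a GO term whose contigs
  are all zero reports an `NA` observed mean and is never significant.
* Determinism: every stochastic stage (permutations, bootstrap, simulation)
  takes an explicit seed and is bit-reproducible under it; pipeline reports
  regenerate identically from the same inputs and seeds.

## Limitations

* The pipeline consumes assemblies; it never produces or corrects them.
  Misassembly is only addressed indirectly (the adjacency flag).
* Genotype calls per individual, SNP assay design and validation are out of
  scope; records are candidates, not validated SNPs.
* The GO test inherits the original design's multiplicity behaviour: at 200
  terms and the 95% rule, roughly 5% false positives are expected on null
  data (the calibration test pins this within the exact binomial 99%
  interval).
* The RaBoT map-based statistic equals the original resampling statistic
  only under stable assembly membership (see above).
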