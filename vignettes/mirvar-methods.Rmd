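---
title: "miRNA quantification and variation analysis with mirvar: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{miRNA quantification and variation analysis with mirvar}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirvar)
```

mirvar quantifies known and novel miRNAs from small RNA-seq libraries and
classifies the sequence variation — isomiRs, 3' non-templated tails,
editing candidates, arm switching — that most count-only pipelines
discard.  This vignette is the package's own account of its models,
parameters, numerical choices, and limits.

## Preprocessing

**Quality filtering** is whole-read: a read is kept iff the fraction of
bases with Phred ≥ `min_quality` (default 20) is at least `min_fraction`
(default 0.95), boundary inclusive.  No quality trimming is done — a
miRNA read is short enough that partial salvage is not worth the end
ambiguity it introduces.

**Adapter trimming** tolerates at most one error base (`max_errors = 1`,
unit-cost mismatch/insertion/deletion), requires at least 10 adapter
bases present (`min_adapter_len`), and drops inserts shorter than 15 nt
(`min_read_len`, the length of the shortest annotated mature miRNA).  An
occurrence is either the complete adapter internal to the read or an
adapter prefix running to the read's 3' end.  Among qualifying
occurrences the one with the **fewest errors** wins, ties going to the
leftmost.  Ordering by position first sounds natural but is subtly
wrong: whenever an insert's last base equals the adapter's first base
(a quarter of random inserts), a spurious one-error occurrence exists one
position left of the true one, and leftmost-first would truncate every
such read by one base.  Fewest-errors-first restores exact insert
recovery, which the test suite asserts on 350 randomized cases.  For the
same reason an occurrence may not *begin* with an insertion edit.  `N`
matches nothing anywhere in the package.

**Adapter detection** (when no adapter is supplied) tallies 10-mers in
the 3' half of up to 1e5 reads, takes the most frequent as an anchor if
at least 20 % of reads contain it, and extends it rightward while ≥ 80 %
of reads agree on the next base.  The caller decides acceptance; the
pipeline refuses to guess silently.

**Collapsing** replaces identical sequences by one record with a support
count; uids are `rank-count` with deterministic ordering (count
descending, then sequence), so identical inputs give identical outputs.

## The hairpin aligner

Collapsed reads are aligned to each precursor hairpin by an affine-gap
semi-global dynamic program written in C++:

* mismatch 30; a gap of length L costs 40 + 6·L (opening fee plus
  per-base extension); matches are free;
* total penalty capped at 60.  Two corollaries follow from the
  arithmetic and are asserted analytically: at most 2 mismatches
  (2 × 30 = 60) and at most one 3-base gap (40 + 18 = 58 ≤ 60 < 64);
* terminal soft clips of the read are free of penalty; hairpin overhangs
  are always free; only the sense strand is searched (mature reads are
  sense to their hairpins);
* the aligned core must keep at least `min_core = 15` read bases —
  without this floor, free clips would make a 1-base "alignment"
  optimal for any read.

With free clips a pure penalty objective is degenerate: a perfect
22-mer alignment ties with every clipped sub-alignment at penalty 0.
mirvar therefore uses **lexicographic optimality**: minimum penalty
first, then minimum clipped bases.  A clip is taken exactly when it
lowers the penalty — terminal mismatches always clip (0 < 30), internal
ones never do.  All alignments attaining the optimum are enumerated by a
tie-aware traceback (deduplicated by start and operation string,
truncated with a flag beyond 200 ties), across hairpins and across loci
within one hairpin.  Leading and trailing gaps are excluded: a terminal
gap duplicates the role of a clip or reference offset and is never
strictly optimal under these costs.

The DP is verified against an independent brute-force oracle that
enumerates every (clip pair, offset, single-gap placement) — a complete
enumeration *because* of the cap corollaries — on 500 random read/hairpin
pairs per run; agreement is exact.

## Quantification without over-counting

Canonical mature loci are found by exact substring search of each mature
in its id-paired hairpin (`xxx-miR-9-5p` pairs with `xxx-mir-9`,
case-insensitively; the arm label comes from the id suffix, else the
locus midpoint).  A mapping is **qualified** when:

1. *position check*: both end shifts of the aligned core against a
   canonical locus are ≤ `max_shift` (default 3 nt); among passing loci
   the smallest total shift wins, ties to the 5p arm;
2. *seed check* (optional, default on): no 5' clip, the read starts
   exactly at the locus start, and read positions 2–8 align as matches
   only — no mismatch, insertion, or deletion touches the seed window.

Each collapsed read contributes its count exactly once: a unique
qualified mapping takes all of it; with several, the subset minimising
total soft-clipped bases (best priority) shares the count evenly.
Fractional counts are held as integer numerators over the least common
multiple of the observed share sizes, so conservation
(Σ fractional = counted reads) and half-away-from-zero rounding are
exact, with no floating drift at `.5` boundaries.  Family counts sum the
matures of each family's hairpins; matures of unassigned hairpins form
singleton families, so family totals always equal mature totals.

## isomiR taxonomy

Every counted mapping is classified along four dimensions: internal
mismatches, indels, end shifts, and non-templated tails (soft-clipped
terminal bases, which by optimality either disagree with the adjacent
hairpin bases or run past the hairpin end).  No active dimension is
`canonical`; exactly one active dimension with a single expression gives
`mismatch`, `insertion`, `deletion`, `super5`/`sub5`/`super3`/`sub3`,
`nta3`, or `nta5`; everything else — including a shift at both ends, or
both an insertion and a deletion — is `mixture`.  The category of a read
whose only variation is a 5' soft clip (`nta5`) exists so the
seed-check invariant is visible in the output: with the check on, the
`super5`, `sub5` and `nta5` rows are structurally zero.

3' tails classify as poly(A) (all A), poly(U) (all T in DNA space;
labelled U because the molecule is RNA), or other.  Tails of ≥ 5 nt
matching an adapter prefix within one edit are flagged as probable
adapter remnants and excluded from the tail sub-table while remaining
counted reads.  The editing indicator is deliberately narrow: a read
flags `a_to_g_only` when it has mismatches, no indels, and *every*
mismatch is hairpin-A/read-G; the reported fraction is over
mismatch-only reads.  Fractions are weighted by read counts, not by
distinct collapsed reads, matching a "% of mature miRNA reads" reading.

## Arm switching

For hairpins with both arms annotated, a library's dominant form needs
count fold-change **strictly** greater than 2 *and* count difference
strictly greater than 10 (with a zero denominator the fold criterion
reduces to a positive numerator).  A treatment has a defined form only
when all its replicates agree on a non-none form; a call requires two
treatments with defined, differing forms.  Raw integer counts are
compared, as the thresholds are count-scale; users comparing libraries
of very different depth should normalise first or expect the difference
criterion to bite asymmetrically.

## Read cataloguing

Genome alignments (SAM; primary records only) are resolved against GTF
features in union mode: the set of gene ids overlapped by any aligned
base decides gene / `no_feature` / `ambiguous`; unmapped and
below-quality records get their own buckets; collapsed uids are expanded
by their support counts.  Gene counts are summed by `gene_biotype`
(falling back to `biotype`, then the GTF source column), and percentages
are over **total clean reads**, mapped or not.  Counting is unstranded
by default; a strict-strand mode flips only strand-discordant reads.

## Novel precursor nomination

Perfect genome mappings of 18–25 nt reads with ≤ 5 loci are merged into
stacks by overlap; each stack is excised in both orientations with a
10 nt mature-side and 70 nt loop-side flank (configurable); signatures
are perfect re-mappings of reads (18–25 nt) and known matures onto each
candidate; the top signature stack becomes the mature only if its count
strictly exceeds twice the runner-up (accepted outright when alone).
Candidates whose selected mature *is* a known mature are the known locus
and are dropped.  Overlapping candidates then compete — one precursor
per region, strongest signature first, ties leftmost then plus strand —
because both excision windows of a stack, and both strands of a
perfect-stem region, describe the same locus.  Folding and probabilistic
scoring are delegated to a pluggable backend (`function(sequence)` →
structure + score); scored candidates must have score > 0, unscored ones
pass through flagged, and a structure from any source activates a sanity
filter (the mature may not base-pair with itself).  Names unify across
libraries by genomic coordinates (`XXX-novel-mir-N` in chrom/start/strand
sort order); novel matures are re-quantified per library with perfect
mapping only and the usual checks.

## The synthetic generator, and what passing tests mean

`make_hairpins()` builds stem-loops in sequence space: a random 5' arm,
its exact reverse complement as the 3' arm, a loop, and short
single-stranded flanks so templated 5'/3' extensions of either mature
exist.  Three constraints make every planted variant provably the unique
optimal alignment: arms carry no two adjacent equal bases (a planted
indel then has a unique gap placement, and any ungapped alternative
mismatches at every shifted position); loop and flank boundaries start
with C so a planted A/T/G tail can never be templated; and two pinned
arm positions give both matures an interior A for editing reads.
Planted mismatch and indel sites sit in the clip-protected centre of the
read (positions 8–15 of a 22-mer), where removing them by clipping would
push the core below 15 nt.

`make_library()` allocates reads to hairpins, arms, and variant
categories by largest remainder from a `variant_profile()` (defaults:
40 % canonical, 22 % super3, 8 % sub3, 5 % mismatch+edit, 2 % each
indel class, 16 % tails, 5 % mixture — a deeply 3'-variable composition
typical of animal libraries), appends the adapter (every 10th read with
one planted adapter error), and adds planted quality failures (5 %) and
too-short inserts (2 %) on top.  The manifest is the oracle for every
closed-loop test: counts, categories, arm dominance, and the embedded
novel hairpin are all recovered **exactly** at the tested sizes (up to
1e4 reads).

What passing does *not* show: the generator has uniform base
composition, error-free sequencing outside the planted classes, a flat
quality model, perfect stems, and no cross-mapping homology between
hairpin families.  Real libraries have position-dependent error,
bulged precursors, paralogous families with near-identical matures (the
even-division rule then matters far more), and adapter dimers.  Exact
recovery here validates the bookkeeping — conservation, category
partition, threshold boundaries — not robustness to those confounders.

## Numerical and edge-case choices

* All internal coordinates are 0-based half-open; only the format
  readers/writers convert (GTF and SAM are 1-based on disk).
* DNA is the internal alphabet (U→T on input); RNA-facing outputs
  (precursor FASTA, DBN) convert back on write.
* Tie-breaks are total orders everywhere (sequence order in collapsing,
  5p before 3p, leftmost-then-strand in novel competition), so every
  output is byte-reproducible; the pipeline test asserts identical CSVs
  across reruns.
* Degenerate inputs: empty FASTQ → empty outputs; reads below 15 nt are
  unalignable by construction; an empty annotation sends every mapped
  read to `no_feature`; a family file is optional (all singletons).
* Test problem sizes (chosen to exercise every path at desk scale):
  500-pair oracle battery, libraries of 600–2000 reads per module test,
  one 1e4-read recovery run, three-hairpin references.

## Known limitations

Only sense-strand hairpin alignment; no base-quality-aware scoring; no
paired-end support; genome mapping for novel prediction is exact-match
(an external aligner's SAM can stand in for large genomes); the
miRDeep2-style probabilistic score, randfold, and fold-based filtering
live behind the backend interface rather than in the package; arm-switch
calls carry no significance statistics — they are candidates for
inspection, not hypothesis tests.
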