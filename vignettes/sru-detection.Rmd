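---
title: "Calling solitary CRISPR repeat units: model, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling solitary CRISPR repeat units}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(srutools)
```

## The problem and the model

CRISPR arrays in host chromosomes consist of alternating direct repeats and
spacers. A *solitary repeat unit* (SRU) is a single repeat-like sequence on
a mobile genetic element — not part of an array, not accompanied by partial
repeat copies — and is a candidate RNA anti-CRISPR: a transcript that mimics
the cognate repeat and titrates the host's surveillance complex. Detection
is therefore an exclusion problem as much as a search problem. The caller's
null expectation is that a repeat-like hit on an MGE is a degenerate or
horizontally acquired array fragment; only a hit that survives every
"array-ness" filter is reported.

The cascade (mask → search → overlap-resolve → cluster → mini-array →
flank → threshold → subtype) is deliberately sequential, and each candidate
carries the verdict of every stage, so a call is traceable to the one stage
that removed it. The stages partition all full matches: array member,
mini-array, flank-rejected, threshold-rejected, or final SRU. This
partition is asserted in the test suite on every scan.

## Parameters

| parameter | default | units | role |
|---|---|---|---|
| ORF confidence | ≥ 80 | % | mask CDS features at or above this caller confidence |
| word size | 6 | bp | exact seed length of the short-word search |
| scoring | +1/−3, gap 5/2 | — | short-query nucleotide scheme |
| min identity | ≥ 90 | % | per-alignment identity filter (inclusive) |
| full / partial coverage | ≥ 90 / [50, 90) | % of repeat length | per-alignment query coverage classes |
| array gap | ≤ 100 | bp | single-linkage clustering distance, and mini-array proximity |
| mini-array identity | ≥ 90 | % | mutual identity of solitary and nearby partial |
| flank length | 100 | bp | window either side of a candidate |
| flank identity | > 70 discards | % of candidate length | self-similarity cut-off (strict) |
| bit-score threshold | ≥ 41.1 | bits | final filter, calibrated on an intergenic/intragenic contrast |
| acr score / E-value | > 0.5 / ≤ 0.01 | — | acr hit screening (strict / inclusive) |
| proximity window | 1,000 | bp | acr-within-window count |
| permutations | 1,000 | — | both permutation tests |

Boundary inclusivity follows the verbal definitions exactly: identity 90.0
is kept, coverage 90.0 is full, confidence 80 masks, 41.1 bits passes, an
acr score of exactly 0.5 fails, an E-value of exactly 0.01 passes, mutual
identity 90.0 flags a mini-array, and flank identity 70.0 is retained.
The boundary tests in `tests/testthat/` pin each of these.

## Alignment and score conventions

**Distances.** "Within 100 bp" and "within 1 kb" bound the *gap*: the
number of bases strictly between two intervals, with overlapping or
adjacent intervals at distance 0. Coordinates are 0-based half-open
internally; output files are 1-based inclusive, converted only in the
readers/writers.

**Identity.** Search-stage identity is identical positions divided by
alignment columns (gaps included), as tabular search tools report it.
Mini-array mutual identity divides matches by the *shorter* sequence
length, so a cleanly truncated partial copy of a repeat can reach 100%.
Flank identity divides by the *candidate* length: a short perfect seed in
a flank cannot inflate it, and "70%" reads as "70% of the repeat recurs
nearby". The filter alignments use the light scheme match +1, mismatch 0,
gap open/extend 1 — global with free end gaps for the mini-array
comparison, local for the flank comparison.

**Coverage** is per single local alignment (aligned query span / repeat
length), not summed across alignments of the same repeat. Summed coverage
would let two 45% fragments masquerade as a full match.

**Bit scores.** The internal backend is a seed-and-extend Smith–Waterman:
exact word-size-6 seeds, a cheap ungapped diagonal prefilter, then full
local dynamic programming on banded candidate windows. Raw scores convert
to bits with λ = 1.374, K = 0.711 — the published Karlin–Altschul constants
for the +1/−3 scheme — which makes internal bit scores numerically
identical to those of the BLAST+ `blastn` short-query task for the same
alignments (a cross-backend test asserts this). The 41.1-bit production
threshold therefore applies to both backends without re-calibration. Like
any seeded search, matches with no exact 6-mer seed are invisible; that is
a modelling feature, not only an optimisation — the flank filter exists
precisely because heavily mutated copies escape the seeded search.
E-values are computed with the standard iterative length adjustment and
are carried for reporting only; no stage filters on them.

**Overlap resolution** is greedy by bit score (ties: lower start, then
lexicographic repeat id) across repeats and strands; it equals brute-force
highest-score elimination, verified on 1,000 random instances. HSP-style
culling is also applied within a repeat/strand, so a clipped sub-alignment
of a stronger hit is never reported alongside it.

## Threshold calibration

`calibrate_threshold()` implements the one-feature special case of a CART
stump: candidate cut points are midpoints between consecutive distinct
sorted bit scores; the split minimising weighted Gini impurity wins; ties
go to the lowest midpoint, and a single-valued score vector returns the
degenerate threshold with baseline impurity. Binding a full
recursive-partitioning package for one numeric feature would only obscure
the arithmetic; instead the test suite cross-checks the stump against
`rpart` with `maxdepth = 1`. The shipped default threshold remains 41.1
bits regardless of local calibration: it reproduces the production
setting, which was fitted on a database-scale intergenic/intragenic
contrast that a desk-scale run cannot re-create.

## Permutation statistics

The acr test relocates every SRU independently and uniformly on its own
replicon each replicate, preserving length and contig; relative SRU–SRU
spacing is not preserved (most MGE genomes carry a single SRU, so the
distinction is usually moot). The statistic counts unique acr genes within
the window of *any* SRU. The P value uses strict exceedance with add-one
smoothing, `P = (#{perm > obs} + 1)/(n + 1)`, so it lives in
`[1/(n+1), 1]` and is never zero. The subtype test shuffles the SRU
subtype label multiset across hosts without replacement; its permuted mean
converges to the analytic expectation Σ_i m_i / N², where m_i counts
labels matching host *i*'s subtype set — asserted by full enumeration at
N ≤ 6. All randomness flows from one user-supplied seed; identical seeds
reproduce results bitwise.

## The synthetic benchmark: what it emulates, and what it does not

`generate_benchmark()` builds i.i.d.-base genomes (default 50 genomes ×
50 kb, GC 0.5) and plants, per genome: one true SRU at 95% identity to a
database repeat, one three-repeat array with 25–40-bp spacers (mirroring
natural repeat–spacer architecture and guaranteeing within-100-bp gaps),
one mini-array (full copy plus an exact-prefix truncation at 60–80%
length within one spacer), one intragenic decoy (a repeat copy inside a
confidence-95 ORF), one flank decoy (a repeat whose upstream flank holds a
75%-identity degraded copy), and one acr interval 500 bp from the SRU.
Features are separated by ≥ 500 bp so no feature can contaminate
another's flanks or cluster window.

Two generator decisions matter for interpreting results:

- Planted identities are realised as *evenly spaced interior*
  substitutions. A substitution within a few bases of a copy's end is
  clipped by any local aligner (the terminal matches beyond it are worth
  less than the mismatch penalty), silently demoting a planted full copy
  to a partial match; and randomly placed substitutions in a 75% flank
  decoy occasionally leave a conserved sub-window that the primary search
  finds, turning an intended flank-filter case into a mini-array case.
  Even spacing makes each planted feature fail or pass at the stage its
  class predicts, which is what a stage-level confusion matrix requires.
  Boundary-exact identities (90.0, 70.0) are deliberately absent from the
  benchmark and exercised in dedicated unit tests instead, a ±2-point
  margin avoiding rounding flakiness.
- The mini-array's truncated copy is an exact prefix of the reference
  repeat, so its query coverage is exactly its length fraction and cannot
  be clipped below the 50% partial floor.

The benchmark does **not** emulate real phage genome architecture: no gene
density or codon structure (ORFs exist only where a decoy needs one), no
insertion sequences, no compositional heterogeneity, no sequencing error.
Passing it demonstrates that the implementation applies the stated rules
exactly — planted truth is recovered at 100% sensitivity with zero false
calls under generous score margins — not that those rules have any
particular sensitivity on real MGE data, where repeat divergence,
atypical spacers and annotation noise dominate. Chance background matches
do occur (a ~10–15-bp exact match to some repeat appears every few tens of
kilobases) and are correctly reported as partial matches; they never
survive the full-coverage and bit-score filters.

## Degenerate inputs and numerical conventions

Flanks truncated by contig edges are used as-is; an absent flank
contributes identity 0 and never discards a candidate by itself. A fully
masked input yields an empty scan with a warning rather than an error.
Substitution counts in the generator round half-up
(`floor(x + 0.5)`), giving the documented nearest-achievable identity with
granularity 100/length. The repeat database de-duplicates exact
forward-strand string duplicates only; reverse complements stay distinct
(the search scans both strands, so orientation redundancy is harmless),
and a sequence that is a strict substring of another is *not* collapsed —
"100% identity and coverage" is read as string equality.

## Problem sizes

The shipped tests run the full 50 × 50 kb benchmark once (about two to
three minutes with the internal backend on one CPU), 1,000-instance oracle
comparisons for overlap resolution and clustering, 200 planted-copy
recovery searches, full permutation enumeration at N ≤ 6, and 100
calibration recoveries; these sizes were chosen to give the property-based
assertions enough repetitions to be meaningful while staying comfortable
on a laptop.

## Known limitations

- The internal backend reports one alignment per candidate window; two
  distinct matches of the same repeat closer than ~10 bp on near-identical
  diagonals would collapse to the stronger one. Natural repeat spacing
  (≥ 20-bp spacers) keeps this out of reach.
- E-values are approximations (iterative length adjustment against the
  single contig); they are reported but never filtered on.
- Subtype assignment is by best bit score; a hit equally close to repeats
  of two subtypes resolves by score tie-break, not by phylogenetic
  placement.
- The acr screening consumes a precomputed tabular hit file; running the
  protein search itself, and the machine-learning acr predictor, are out
  of scope.
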