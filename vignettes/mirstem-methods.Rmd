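---
title: "Methods: models, criteria and design choices in mirStem"
author: "mirStem authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, criteria and design choices in mirStem}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

mirStem analyses a pair of small RNA libraries ("BR" and "BS" below,
after the browning-resistant/-sensitive design it was built around)
through six stages: read classification, ncRNA filtering, known miRNA
profiling, novel miRNA discovery, differential expression, and target
prediction. This vignette explains the statistical models and the
procedural conventions behind each stage, the tunable parameters with
their defaults and units, what the synthetic-data generator does and
does not emulate, and the numerical choices that make every run
deterministic.

## Read classification and trimming

A read is first screened on mean Phred quality (`qualityFloor`,
default 20). High-quality reads are then assigned to exactly one
category, in this precedence order: 5' adapter contaminant (5' adapter
at the read start), insert-null (3' adapter at position 1, i.e. an
adapter dimer), adapter3-null, poly(A) (trimmed insert at least 80%
adenine), smaller-than-minimum, clean. Adapter detection is
seed-and-extend: the adapter's first 8 nt must match exactly, and the
remaining overlap may mismatch once. The category counts always sum to
the high-quality total — this conservation identity is asserted on
every run.

Two conventions deserve comment:

* **Clean length window.** The default is 18–30 nt. Small RNA library
  preps size-select roughly this range, gel cuts are commonly described
  as 15–30 nt, and the short-fragment removal category is conventionally
  "smaller than 18 nt"; 18–30 is the self-consistent combination, and
  both bounds are configurable (`minLen`, `maxLen`).
* **Reads without a 3' adapter.** A read in which no adapter is found
  and which is longer than `maxLen` cannot be a complete insert and is
  discarded as adapter3-null. A read without an adapter whose full
  length already lies inside the clean window is treated as an
  untrimmed insert and classified onward. This makes trimming
  idempotent: re-running the classifier on already-clean tags returns
  them all as clean and unchanged, which is the property a
  collapse/re-analyse workflow needs.

Poly(A) is defined as ≥ 80% adenine after trimming; library-prep
documentation rarely defines the category precisely, so the threshold
is explicit and fixed.

## ncRNA filtering and known miRNA profiling

Tags matching rRNA, tRNA, snRNA or snoRNA records are removed before
miRNA identification. Matching is perfect-substring on either strand —
the conservative, exactly reproducible reading of a BLASTn-based
filter; `maxMismatch` loosens it if desired. A tag hitting several
classes is annotated with the highest-precedence class
(rRNA > tRNA > snRNA > snoRNA); the order is a fixed convention, since
multi-class hits are ties of bookkeeping, not biology.

Known miRNA assignment compares each tag to every database entry of
equal length by Hamming distance with at most two mismatches (the
conventional tolerance for cross-species mature matching). There is no
indel or length-variant (isomiR) matching: the comparison the tolerance
was defined for is ungapped and equal-length. A tag matching several
entries goes to its minimum-distance entry, ties broken
lexicographically by family then id, so assignment is deterministic.

The family table reports members (distinct matched database entries),
per-library read sums, their total, and the BS/BR ratio rounded
half-away-from-zero to two decimals. Two edge conventions are taken
from how such tables are conventionally printed: a family absent from
BR (ratio undefined) prints an em dash; a family absent from BS prints
0.00.

## The folding model

Novel-miRNA evaluation needs a secondary-structure folder. The built-in
one is a deliberately simple, fully specified stacking-energy dynamic
program:

* a base pair contributes energy only when stacked directly on an
  adjacent inner pair: GC/CG −3.0, AU/UA −2.0, GU/UG −1.0 kcal/mol per
  stacked pair;
* unpaired bases are free; hairpin loops contain at least 3 nt;
  structures are nested (no pseudoknots);
* the all-unpaired structure has energy 0, so MFE ≤ 0 always;
* co-optimal ties are resolved by maximal pair count, then 5'-most
  pairing, making the output deterministic.

The recursion tracks, per interval, the optimum with and without the
closing pair, so the stacking dependency is exact; the implementation
is O(n³) in C++ and is verified against exhaustive enumeration of all
nested structures for sequences up to 14 nt (energies agree exactly;
pair counts agree among co-optima).

This model is a stability *threshold*, not a thermodynamic predictor:
the pipeline only asks whether a candidate folds at or below an energy
bound. Printed MFE values from Mfold/RNAfold are not reproduced — that
would require the full Turner parameter set — and any external folder
can be plugged in through `mirnaCriteria(folder = ...)` (a function
from sequence to dot-bracket plus energy, used verbatim), in which case
its energies replace the built-in ones throughout.

A consequence of the simplified model worth knowing: random sequence
folds into dense ladders of stacked pairs more readily than under a
thermodynamic model with loop penalties. About 2% of arbitrary mapped
tags produce a window that passes all duplex criteria below (a rate
pinned by a property test); with a thermodynamic plug-in folder the
rate is far lower. This is the main reason the default simulation
draws its siRNA-like background from loci outside the reference set —
see "What the generator emulates" below.

## Duplex statistics and the hairpin criteria

For a folded precursor and a mature interval, `duplexStats` reports:

* `overlap_bp` — mature positions with a pairing partner;
* the star interval — the minimal interval covering those partners,
  extended by the canonical 2-nt Dicer 3' overhang at its 3' end;
* `n_bulges` — maximal unpaired runs strictly inside the duplex, on
  either strand (a symmetric internal loop counts once per strand);
  "bulge" is not defined in most pipeline descriptions, so the
  definition is fixed here;
* `monotone` — whether the partners decrease monotonically along the
  mature, i.e. whether the duplex is one antiparallel helix rather
  than fragments of several;
* `loop_gap` — the unpaired span between mature and star (the
  terminal-loop side);
* `flagged` — the mature is unpaired or spans the terminal loop.

`evaluateCandidate` accepts a candidate iff all of: mature length in
18–25 nt; mature on a stem arm with a coherent (monotone) duplex;
`overlap_bp` ≥ 16; `n_bulges` ≤ 4; star-span asymmetry ≤ 4 nt;
`loop_gap` ≤ 35 nt; MFE ≤ −18 kcal/mol; total mature reads ≥ 5.
Everything is configurable in `mirnaCriteria()`. Rationale for the
defaults:

* The 16-bp overlap, ≤ 4 bulges, ≤ 4 nt asymmetry and ≤ 35 nt
  mature–star distance are the conventional stem-loop prediction
  criteria for plant small RNA data (the MIREAP defaults).
* The energy bound is read as MFE ≤ **−18** kcal/mol. Stated energy
  criteria are sometimes printed unsigned ("maximum free energy of
  18 kcal/mol"), but folding energies of real precursors are negative
  throughout, so the stability reading is the only consistent one.
* The mature length gate is 18–25 nt; 20–23 nt is the typical range of
  real matures and is what the simulator samples, but the gate itself
  follows the wider prediction convention. Both are configurable.
* **Star reads are recorded, not required.** Passenger strands are
  degraded in vivo and detected for only a minority of genuine miRNAs
  (in typical datasets roughly one in six), so requiring them would
  discard most true positives; `requireStar = TRUE` enforces the
  strict reading.
* The read-depth floor (`minReads` = 5 across both libraries) is the
  usual guard against single-copy background tags.

Candidate windows are excised around each perfect-match position with
the two arm hypotheses — `[start − 10, end + 160]` (tag as 5p arm) and
`[start − 160, end + 10]` (tag as 3p) — clipped to the reference;
windows that clip below 50 nt are discarded with a logged reason. After
the first fold locates the duplex, the candidate is trimmed to the
duplex extent plus a 5-nt pad and re-folded, iterating until the extent
is stable (at most 4 rounds); the reported LP and MFE therefore
describe the hairpin itself, not the arbitrary excision window.
Multiple windows for one tag are deduplicated by best (lowest) MFE, and
records whose precursor intervals overlap on the same reference are
arms of one hairpin and share a locus number. Coordinates are 0-based
half-open internally and 1-based inclusive in every report.

## Differential expression

Counts are normalized to reads per million of the library's clean-read
total; a normalized value of zero is replaced by 0.01 (the substitution
applies to the normalized expression, not the raw count, which is where
the convention places it). miRNAs below 1 RPM in both libraries are
skipped before testing. The fold change is
`fc = log2(rpm_BR / rpm_BS)`, so positive values mean up-regulation in
the BR library.

The p-value is the exact conditional (Audic–Claverie) test: under the
null of equal relative abundance, the second count given the first is

$$P(Y = y \mid x) = \left(\frac{N_2}{N_1}\right)^y
  \frac{(x+y)!}{x!\,y!\,(1+N_2/N_1)^{x+y+1}},$$

which is negative binomial with size $x+1$ and success probability
$N_1/(N_1+N_2)$. The tails are therefore evaluated with `pnbinom`
(log-space internally), not by explicit factorial summation; a
brute-force summation oracle in the test suite confirms agreement to
10 decimal places. The two-sided p-value doubles the smaller tail,
each tail including the observed count, capped at 1; `sided = 1` gives
the one-sided version.

Two statistical notes:

* **Swap symmetry is approximate.** The doubled-tail p is not exactly
  invariant under exchanging the libraries — the observed point mass
  enters the two conditionings differently — and the discrepancy is
  bounded by twice the point probabilities (it vanishes as counts
  grow). The test suite asserts exactly that bound. The fold change is
  exactly antisymmetric.
* **No multiple-testing correction enters the calls**, mirroring the
  plain p ≤ 0.05 convention of two-library small RNA studies; a
  Benjamini–Hochberg column is emitted for users who want it.

Calls: `up` iff fc ≥ 1 and p ≤ 0.05; `down` iff fc ≤ −1 and p ≤ 0.05;
`skipped_low` under the skip rule; otherwise `ns`. Library totals are
the post-preprocessing clean totals (whether published pipelines
exclude ncRNA reads from "total clean reads" is typically unstated;
clean totals are the default here and the totals are arguments, so
either convention is available).

At moderate expected counts the doubled-tail exact test holds its size:
on 2,000 null pairs with log-normal expected counts (median 200) the
fraction with p ≤ 0.05 sits near 0.045; strong discreteness at very
low counts makes it conservative, which is the expected behaviour of
an exact test.

## Target prediction

Plant miRNAs direct cleavage through near-perfect complementarity, so
target prediction is a penalty alignment, not a seed match. The
expectation score E of a miRNA–site duplex sums: mismatch 1.0, G:U
wobble 0.5, gap or bulged site base 2.0 — doubled when the column
touches miRNA positions 2–13 from the 5' end (the region whose
complementarity cleavage requires). A bulged site base is attributed
to the adjacent miRNA position on its 5' side. Sites with E ≤ 3
(default) are reported; the scan is a banded dynamic program over
every window with at most `maxGap` (default 1) gaps, verified against
exhaustive alignment enumeration. Overlapping windows are collapsed to
the best-scoring site. The inhibition call is `translation` iff a
mismatch or gap touches miRNA positions 9–11, else `cleavage` — the
central region is where cleavage occurs, so its disruption implies
translational repression instead. These constants are the canonical
plant target-scoring scheme; all are arguments.

## What the generator emulates — and what it does not

`simulateLibraries` produces two libraries with a complete truth table,
so every pipeline stage can be validated against known ground truth.
Its defaults are the package's reference study conditions:

* depth 100,000 reads per library; 30 known families × 2 members;
  10 novel hairpins embedded into 20 references of 2,000 nt, 3 of them
  with sequenced star reads (about the observed minority rate of star
  detection);
* mature lengths sampled 20–23 nt (21 nt modal); hairpin loops
  6–14 nt; 0–3 single-base star-side bulges per duplex, placed so the
  inserted base cannot pair with its neighbours;
* per-miRNA abundances log-normal (heavy-tailed, as real family tables
  are), with each member also emitting an 8% single-mismatch variant
  (sequencing noise that still matches within the two-mismatch
  tolerance);
* a balanced fold-change plan: four known members and four novel
  miRNAs at log2 fold changes +1, −1, +2, −2, everything else 0.
  Balance matters: per-library counts are multinomial at fixed depth,
  so an unbalanced plan would distort every expectation ratio through
  the compositional constraint; with a balanced plan each planted
  expectation ratio is exactly $2^{fc}$. Planted DE miRNAs get
  expected counts of several hundred so that fold-change recovery is
  limited by counting noise, not rarity;
* removal-category proportions matching a typical run: ~1% reads
  without a 3' adapter, 0.2% adapter dimers, 0.05% 5' contaminants,
  2.7% short fragments, 0.05% poly(A), 5% ncRNA fragments, 0.5%
  low-quality reads. A chi-square goodness-of-fit test at the full
  depth confirms the realized proportions;
* a 52% siRNA-like background class of 23–25 nt tags (24 nt modal),
  which makes 24 nt the modal read length with 21 nt second, the
  canonical plant length profile. These tags are drawn from loci
  *outside* the reference set: a small EST/GSS reference set captures
  a tiny fraction of the siRNA-producing genome, so most such tags
  would not map — and under the simplified folder, mapped random tags
  would occasionally (≈ 2%) satisfy the hairpin criteria, which is a
  property of the folder, not of the discovery logic. An optional
  `mapped` background fraction exists precisely to stress that
  specificity, and a property test pins the rate.

Hairpins are verified twice: once in isolation at construction (the
built-in fold must reproduce the planted duplex exactly — all mature
bases paired, the planted bulge count, MFE ≤ −18) and again in genomic
context at planting (excise–fold–evaluate; flanking sequence can
perturb the minimum-energy structure, so placements that break the
duplex are re-drawn). The generator therefore guarantees that every
planted hairpin satisfies the acceptance criteria under the same folder
the pipeline uses — recovery tests measure the pipeline, not luck.

What the generator does **not** emulate: position-dependent sequencing
error or quality profiles (qualities are constant except for a
configurable low-quality fraction); isomiR length variants;
multi-locus miRNA families with shared matures; genome-scale reference
sets; and realistic unique-tag diversity (a simulated library contains
a few thousand distinct read sequences, real ones contain millions —
the read-versus-unique-tag distinction is exercised, but at compressed
scale). Passing the recovery tests therefore shows the pipeline is
correct and calibrated under these conditions; it does not by itself
demonstrate performance on full-scale field data.

T is used in all file output (DNA space); U is accepted on input and
mapped to T, matching how mature sequences are conventionally printed.

## Numerical and reproducibility choices

* Ratios are rounded half-away-from-zero (with a 1e-9 guard against
  binary representation of exact halves); base R's `round` would
  round-half-even and disagree with printed tables.
* Fold energies are integers in kcal/mol by construction of the energy
  model, so DP comparisons are exact; the combined DP objective packs
  (energy, −pairs) into one integer key.
* Target-scan penalties are multiples of 0.5, exactly representable in
  floating point, so traceback equality tests are safe.
* All randomness flows from a single seed: `simulationConfig(rngSeed)`
  determines libraries, truth table and written files byte-for-byte;
  the pipeline itself uses no random numbers, so re-running it on the
  same inputs is byte-identical (asserted by tests).
* Test problem sizes: the folding oracle is checked on 200 random
  sequences up to 14 nt (exhaustive enumeration above that is
  combinatorial); null calibration on 2,000 count pairs at library
  size 10^6; recovery on the full 100,000-read simulation; the target
  oracle on ~150-nt transcripts (the enumeration oracle is quadratic
  in transcript length times alignments per window).

## Known limitations

* The built-in energy model has no loop penalties, so its specificity
  for hairpin discovery on mapped background is limited (≈ 2% of
  arbitrary mapped tags pass; see above). For discovery on real
  genome-scale references, plug in a thermodynamic folder.
* Equal-length Hamming matching will miss known miRNAs that differ
  from the database by indels or length (isomiRs).
* The exact count test is conservative at very low counts; combined
  with the 1-RPM skip rule this is rarely consequential, but very rare
  miRNAs are undercalled by construction.
* Novel-miRNA family grouping (clustering novels into families) and
  GO/KEGG annotation of predicted targets are out of scope; outputs
  carry the identifiers needed to do both externally.
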