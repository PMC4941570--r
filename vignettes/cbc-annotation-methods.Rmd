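---
title: "Methods: multiplexed amplicon annotation for community-based culture collections"
author: "cbcmux"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multiplexed amplicon annotation for CBCs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

A community-based culture collection (CBC) stores picked colonies — each
possibly a single organism or a small community — in 96-well plates. To
annotate such a collection, near-full-length 16S rRNA amplicons are tagged
by a two-step PCR with a combinatorial barcode scheme (a 9-nt plate
barcode plus 8-nt row and column barcodes), pooled into one tube and
sequenced as long circular consensus reads (CCSs). The desk-side problem
this package solves is: given the CCS FASTA, a sidecar of per-read subread
nucleotide totals, and the barcode manifest, (i) trace every read back to
its well, (ii) discard artifact reads, (iii) call per-well OTUs with
taxonomy, and (iv) estimate what fraction of a culture-independent
community profile the collection captures.

The construct layout on the plus strand is fixed:

```
[row bc 8] [fwd transposase 14] [16S insert] [univ reverse primer 16]
[plate bc 9] [rev transposase 15] [col bc 8]
```

# One identity definition

Every threshold in the pipeline (97% reliability, OTU radius and
cross-reference threshold; 75% nonspecific floor) refers to a single
pairwise identity definition: a *fit* alignment in which the shorter
sequence is aligned over its whole length, end gaps of the longer sequence
are free and unscored, internal gap columns count as non-matches, and `N`
matches nothing. Identity is `100 * matches / columns` over that
alignment, so the scored columns always cover at least the shorter
sequence.

Two non-obvious consequences motivated this choice. First, a short V4
fragment (~250 nt) contained in a near-full-length CCS scores 100, which
the recovery module requires. Second, a fully "overlap" alignment (end
gaps free on both ends of both sequences) is unusable here: for two
unrelated full-length sequences its optimum collapses onto a tiny perfect
corner overlap, reporting identity near 100 where ~50% background is the
meaningful answer. The fit semantics keeps unrelated pairs near
background, so 75%/97% thresholds are actually decisive.

Scoring is fixed: match +1, mismatch −2, gap −4 for the first gap column
and −1 per additional column. The scheme is ordinary for nucleotide work;
results near the thresholds are driven by the match/column counting, not
by the gap scores.

The aligner, the ungapped oligo scanner and a k-mer presence bitset used
for candidate screening are implemented in C++ inside the package, because
the identity definition itself is part of the package's contract and is
exercised millions of cells at a time. Database searches shortlist
candidates by shared distinct 8-mers with a provable bound: a pair at
identity ≥ *t* over a shorter length *L* can lose at most
`k * floor(L * (1 - t/100))` of its `L - k + 1` words to edits; we halve
that bound as a safety margin against repeated words, and skip only
references below it. The search equals the exhaustive scan on every test
database, and `prescreen = FALSE` disables it.

# Demultiplexing

Anchors are located by ungapped scanning on both strands with at most 3
substitutions; the strand with more anchors wins (ties go to plus). Each
barcode interval is predicted from its flanking anchor; when that anchor
is missing, the interval is recovered from the other anchors or from the
read ends (the 5′ block sits at position 0, the 3′ block at fixed offsets
from the read end). Barcodes are then called by *exact* match only: one
distinct barcode within ±4 nt of the predicted start is a
position-consistent call; two distinct exact matches in the window is no
call; an exact match found only elsewhere is recorded but leaves the read
unassigned. A read is assigned iff all three classes have consistent
calls.

The ±4 nt tolerance absorbs indel drift between an anchor and its barcode
in long noisy reads and is configurable. Because barcodes within a class
are generated (and validated) at pairwise Hamming distance ≥ 2, a single
substitution can never convert one barcode into another; together with
exact matching this is what makes misassignment essentially impossible —
the property the tests assert as zero misassigned reads.

Assigned reads are re-oriented to the construct plus strand and trimmed to
their insert (between the forward transposase anchor and the universal
reverse primer). Without trimming, the ~70 nt of barcode/anchor
scaffolding — which matches no 16S reference — depresses every downstream
identity by roughly 5 points, putting even error-free reads below a 97%
threshold. The original consensus length is kept in the metadata
(`ccs_length`) and is what the over-length filter inspects.

# The QC cascade

Order: over-length → chimera → nonspecific → reliability; each filter only
moves read status forward, so all filters are idempotent and the run
ledger balances exactly:

* `assembled = demultiplexed + non_demultiplexed`
* `usable = demultiplexed − over_length − chimeric − nonspecific`
* `usable = reliable + error_prone`, `reliable = db_hits + dataset_hits`

**Over-length.** Consensus length strictly greater than 1,600 nt is
discarded.

**Chimera.** A read is explained either by one reference or by a
two-segment model: a prefix from parent A and a suffix from parent B
joined at a crossover. Candidate parents are shortlisted by shared 8-mers
over the whole read, each half, and the two outer quarters — the
multi-region screen matters because a bimera's minor parent is otherwise
crowded out of a whole-read ranking by the major parent's close relatives.
For each candidate we compute a cumulative match profile along the query
from a *global* alignment (a fit alignment of a half-matching pair
collapses instead of covering the matching half, which is why the profile
uses the global mode). With `pm_A[c]` the matches of A up to query
position `c` and `tot_B` the total matches of B, the two-segment score at
crossover `c` is `pm_A[c] + tot_B − pm_B[c]`; both `I1 = max single` and
`I2 = max two-segment` are normalized by the query length. The verdict is
chimeric iff `I2 − I1 ≥ 2.0` identity points and `I2 ≥ 97`. The 2-point
gain is configurable; it cannot be produced by sequencing noise (2 points
≈ 28 excess matches on a 1,400-nt read) while a genuine between-genus
bimera gains 10–25 points. Bimeras whose two parents are from the same
genus (≥ 97% mutual identity) frequently stay below the gain and are
missed — at the simulator's parent-draw rules that is ~8% of chimeras,
which keeps the realized discard fraction within sampling error of the
injected rate.

**Nonspecific.** No alignment, or best identity strictly below 75%,
discards the read (a read at exactly 75.0 passes).

**Reliability.** A read is kept if it aligns at ≥ 97% to a curated
reference (`database_hit`), or — only for database misses — at ≥ 97% to
any *other* read in the dataset (`dataset_hit`, self-hits excluded; reads
from the same well count, since redundancy anywhere in the collection is
evidence). Everything else is error-prone and discarded. A conventional
≥ 10× coverage filter is computed alongside purely for comparison; it
never changes read status. On simulated data the reliability filter
retains every high-coverage read plus most low-coverage reads (their
2.3%-error identities sit near 97.6% against the true reference), which is
the qualitative point of the comparison: reliability-filtered retention
dominates coverage-filtered retention.

# OTU clustering

Greedy centroid clustering at 97% within each well: reads sorted by
coverage descending (ties: length descending, then id — a total order, so
the result is independent of input order), each read joins the *first*
existing centroid at ≥ 97% or founds a new OTU. The coverage-descending
sort is the abundance-surrogate convention of greedy centroid
clusterers — the established pipelines name the approach without fixing
the processing order, so the order is pinned down here. Every
member is ≥ 97% to its centroid by construction and the tests re-assert it
post-hoc. Well OTU centroids are then re-clustered (sorted by OTU size
descending) into collection OTUs, yielding the redundancy map of which
wells share an organism. On small wells the greedy result matches a
branch-and-bound optimal 97% partition oracle; with chains of borderline
pairs (a–b and b–c at 97 but a–c below) greedy can in principle use one
more cluster than optimal, which is inherent to every greedy centroid
clusterer of this family.

# Taxonomy

A word-presence (Bernoulli) naive-Bayes classifier over 8-mers with an
RDP-style word-specific prior `Pi(w) = (n(w)+0.5)/(N+1)`. One deliberate
departure from the textbook smoothing: genus word frequencies are
size-normalized, `P(w|g) = (f_g(w)·S + Pi(w)) / (S+1)` with `f_g` the
within-genus word frequency and `S` the median genus training size. With
the unnormalized `(m+Pi)/(M_g+1)` form, the unseen-word penalty
`log(M_g+1)` depends on genus size, so the smallest genus mechanically
wins every low-information query — random sequences would receive
*confident* calls. With normalization, low-information queries scatter
across genera under the bootstrap and fall below the report rule.

Confidence: 100 bootstrap subsamples of `floor(L/8)` of the query's words
(with replacement, seeded); per rank, the fraction of subsample winners
lying inside the full call's taxon at that rank. The genus is reported
only when its confidence exceeds 0.95 (strict). Queries shorter than
`8 × k = 64` nt are unassigned with zero confidence.

# Recovery estimation

Every profile representative (a short V4-style fragment) is aligned
against every collection sequence; pairs at ≥ 97% enter the hit table, and
per compartment the recovery estimate is the sum of relative abundances of
profile OTUs with at least one hit — each OTU counted once regardless of
how many collection sequences hit it, hence monotone in the collection.
The fragment is the query and is scored over its own length inside the
near-full-length sequence, which the fit-alignment semantics provides
directly.

# The simulator

The generator emits everything the pipeline consumes plus a per-read
truth table, under one global seed (derived sub-seeds per stage keep each
stage individually reproducible; the caller's RNG state is never
disturbed). Its defaults are the study conditions the pipeline targets:

* five pooled 96-well plates; per plate 93 sample wells, H10 a positive
  control carrying a dedicated control taxon, H11/H12 negative controls
  emitting nothing;
* a reference pool of 40 taxa in genera of ≥ 3 (ancestors are independent
  random sequences, members carry ~0.8% substitutions, so within-genus
  identity sits near 98.4% and between-genus identity near background),
  inserts 1,350–1,450 nt;
* community sizes per well drawn from {1: 0.45, 2: 0.30, 3: 0.15,
  4: 0.10} — over half of the occupied wells host two or more organisms;
* integer coverage from 2–40 with 74.7% of mass above 9×, and per-base
  error rates by coverage class: 2.3% below 5×, 0.7% at 5–9×, 0.3% above
  9× (errors i.i.d., 80% substitutions / 20% indels — the aggregate rates
  are the calibrated quantity, the mix is a recorded choice);
* 12.3% chimeras (two parents from the same plate's taxa, crossover
  uniform in the middle 60% of the insert so detectors can see it), 0.14%
  off-target random inserts, 5% reads with one barcode mutated at one
  position, ~50% of reads reverse-complemented;
* 2–6 reads per occupied well (~1,900 reads per five-plate run), and
  subread totals of `coverage × length ± <0.4 × length` jitter so that
  recomputing coverage from the sidecar reproduces the true value exactly.

What it deliberately does not model: quality scores, PCR abundance bias,
chimeras longer than the amplicon range (the over-length filter is
exercised independently of the chimera filter), degenerate primer
mismatches, or real 16S secondary-structure conservation. Passing tests
therefore demonstrate the pipeline's logic and calibration under its
stated error model, not performance on any real sequencing run.

# Numerical choices and degenerate inputs

* Coverage rounding: nearest integer, ties half away from zero, computed
  in exact integer arithmetic.
* Boundary semantics are strict per their definitions: > 1,600 discarded,
  < 75 discarded (75.0 passes), ≥ 97 reliable, confidence > 0.95 reported.
* Ties everywhere break deterministically: database-search ties by input
  order then plus strand, greedy clustering by the total sort order,
  classifier ties by genus order, crossover ties leftmost.
* Empty inputs produce valid empty outputs and an all-zero ledger; an
  empty database or profile is a configuration error; duplicate read ids
  are rejected at construction.
* Problem sizes used by the test-suite: the shared acceptance run is one
  default five-plate simulation (~1,900 reads, full-length inserts); unit
  tests use a 12-taxon pool with ~400-nt inserts, which exercises
  identical code paths at a fraction of the alignment cost.

# Known limitations

* The bundled manifest's barcodes and anchors are synthetic stand-ins of
  the documented lengths; real runs must supply their own manifest.
* The chimera model is a two-parent (bimera) model; multi-parent chimeras
  are flagged only insofar as a two-segment explanation already clears the
  gain threshold.
* Same-genus bimeras below the gain threshold are not detectable in
  principle under this scorer.
* The dataset-hit stage of the reliability filter is quadratic in dataset
  size in the worst case (all reads missing the database); the k-mer
  screen keeps the practical cost near-linear.
* Recovery estimates depend on which collection sequences are offered
  (well centroids by default); collection-level centroids give a cheaper
  but slightly coarser estimate.
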