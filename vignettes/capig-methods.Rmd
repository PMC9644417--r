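---
title: "Methods: capture-based immunoglobulin sequencing analysis with capig"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: capture-based immunoglobulin sequencing analysis with capig}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(capig)
```

## The problem

Multiple myeloma genomes carry two classes of clone-defining
rearrangements at the immunoglobulin loci: primary translocations that
fuse IGH/IGK/IGL to partner oncogenes (t(4;14), t(11;14), t(14;16) and
relatives), and the V(D)J rearrangement whose junction (CDR3) is a
sequence barcode unique to the malignant clone. Both are stable through
the disease course, which makes them ideal markers for minimal residual
disease (MRD) tracking in bone marrow and cell-free DNA. A hybrid-capture
panel over the immunoglobulin loci can recover both marker classes, plus
somatic mutations, from a single DNA aliquot.

`capig` implements the informatics for this assay: capture-probe design
from a germline segment reference, translocation calling from discordant
mate pairs with soft-clip refinement (CluMP, "clustering of mate pairs"),
clonotype filtering of MiXCR-style clone tables, a deterministic encoding
of the manual-review confirmation rules, limit-of-detection statistics,
and a seeded simulator that makes the entire stack testable without
sequencing data.

## Probe design

Capture probes are 120-nt single-stranded sequences. V genes are probed at
their 3' ends and J genes at their 5' ends, because a fragment captured at
either end of the rearranged gene then has a high chance of spanning the
V(D)J junction itself; constant-region (C) exons are tiled whole because
class-switch recombination errors within them are a recurrent source of
translocation breakpoints. Probes are emitted in segment (coding)
orientation — capture hybridization is strand-agnostic, and genomic strand
is carried separately when coordinates are available (`probe_bed()`).

Design rules (`design_probes()`), with the open choices resolved as
follows:

* Segments shorter than the probe length yield one full-length probe
  rather than being dropped; only segments under `min_segment_len`
  (40 nt) are skipped. Keeping short alleles maximizes recall at no cost.
* C segments longer than one probe are tiled from the 5' end; a final
  partial tile is kept when it is at least `min_segment_len` long.
* Probes identical in sequence (alleles sharing a gene end) are
  deduplicated, keeping the lexicographically smallest identifier, so
  output is order-independent.
* The promiscuity screen (`screen_promiscuity()`) flags a probe when more
  than `promiscuity_max_hits` (5) other probes share at least one exact
  `promiscuity_k`-mer (k = 25) with it. Cross-hybridizing probes in the
  original panel were removed after empirical off-target measurements; the
  k-mer screen is this package's deterministic stand-in for that
  judgement, and its two parameters are design choices, not measured
  values.

## Translocation calling (CluMP)

The caller consumes coordinate-sorted aligned paired-end records and
proceeds in four stages.

**1. Discordant-pair extraction.** A template is discordant when its mates
map to different chromosomes or when the insert size is at least
`min_insert` (default 5,000 bp, inclusive); both mates must reach mapping
quality `min_mapq` (Q30) and neither may be a flagged duplicate. The
5,000 bp default reflects the assay's configuration; anything smaller is
within the reach of ordinary structural polymorphism and capture-fragment
geometry.

**2. Clustering.** Pairs supporting the same rearrangement are grouped by
single-linkage clustering within each (chromosome pair, orientation class)
stratum: two pairs join when both A anchors and both B anchors are within
`cluster_window` (1,000 bp). The window is a design choice sized to
typical capture-fragment spread around one junction; orientation
stratification keeps reciprocal breakpoints of a balanced translocation
from merging.

**3. Soft-clip evidence.** Within each cluster window (padded by
`breakpoint_pad`, 500 bp), reads qualify as breakpoint evidence when their
mean base quality reaches `min_baseq` (Phred 20), mapping quality reaches
Q30, and the fraction of bases not matching the reference is at least
`min_mismatch_frac` (0.33). That fraction counts soft-clipped bases plus
the aligned-segment edit distance (NM) over the full read length: a
junction-spanning read is "one third foreign" under any aligner that
clips the partner-locus bases. Beyond the duplicate flag, clip reads with
identical (start, CIGAR) are collapsed, since PCR duplicates form stacks
with the same endpoints while genuinely independent fragments have
staggered ends.

**4. Refinement.** Per side, the breakpoint is the modal clip coordinate
(ties to the smallest coordinate, so results are deterministic); the
consensus clip sequence is the per-position majority base over the clips
at that coordinate, aligned at the junction, with ties broken to the
lexicographically smallest base. Clip sequences and consensi are reported
junction-anchored, reading away from the breakpoint (left-side clips are
reversed); this makes concordance between any two clips a plain
common-prefix comparison regardless of which side they were sequenced
from. With no clips the call falls back to window resolution at the
cluster midpoint.

Region filtering (`filter_events()`) marks — never deletes — calls in
blacklisted repetitive regions, calls entirely inside the immunoglobulin
loci (V(D)J rearrangements, which the clonotype arm handles instead), and
clusters below `min_pairs` with no clip support. Coordinates are 1-based
internally (SAM convention); all BED input/output is 0-based half-open,
converted only at the I/O boundary.

## Verification rules

Manual review of candidate rearrangements follows two explicit rules,
which `verify_event()` encodes as a total, deterministic classifier:

1. **Confirmed** when both partners have at least two mutually concordant,
   non-duplicate clipped reads.
2. **Confirmed** when a matched sample (targeted or WGS) is available,
   each partner has at least one clip concordant with the matched
   sample's clips, and the matched sample has at least five non-duplicate
   clips at one partner.
3. Otherwise **equivocal** when any clip evidence exists (a single read is
   suggestive but not definitive), else **absent**.

Concordance is exact agreement over the junction-anchored overlap, with a
minimum overlap of 10 nt — the original criterion is "the same misaligned
sequences" with no stated tolerance, so exact matching is the faithful
reading, and the 10-nt floor merely prevents trivially short overlaps from
counting. A coverage drop at an unbaited partner breakpoint is a useful
visual cue during review, but the confirmation rules do not require it, so
the classifier records it without using it. The equivocal category is
defined here as exactly "some clip evidence, neither rule fires".

## Clonotype filtering

Clone tables arrive in MiXCR export format (counts, fractions, V/D/J hits,
CDR3 sequences); `capig` treats that purely as a file format and never
re-implements clone assembly. The filtering pipeline
(`call_candidates()`) runs in a fixed order:

1. pseudogene removal (the pseudogene list is an input, typically IMGT
   functionality annotations);
2. clonal-fraction recomputation — a clone's fraction is its read count
   over the total at the same locus in the same sample;
3. fraction filter: keep clones with fraction **strictly** above 0.10;
4. cohort-specificity filter: keep clones whose exact CDR3 nucleotide
   sequence occurs in at most 5 samples of the cohort. Occurrences are
   counted among the *post-fraction-filter* candidates, matching the order
   in which the thresholds were derived; replicate samples from one donor
   are deliberately not collapsed;
5. count filter: keep clones with count strictly above 50 (cell lines) or
   10 (patient samples, where sensitivity is preferred).

All inequalities are strict because the thresholds were stated as ">".
Output is stable-sorted by decreasing count then CDR3, so the pipeline is
invariant to input row order, and an audit table records per-stage drop
counts per sample.

## Sensitivity and limit-of-detection statistics

`sensitivity_ci()` reproduces the assay validation tables' arithmetic
exactly: the point estimate is detected/total rounded to two decimals, the
95% interval is the Wald normal approximation `p ± 1.96·sqrt(p(1−p)/n)`
computed *from the rounded point estimate*, and bounds are rounded but not
truncated to [0, 1] — with n as small as 2 this prints bounds like −0.19
and 1.19, which is precisely how the source tables read. This recipe is a
reconstruction (the tables do not name their CI method); it reproduces
every printed interval except one 3/4 row, where the recipe gives
(0.33, 1.17) against a printed (0.35, 1.15) — that row is treated as a
typographical inconsistency and documented rather than matched.

`detection_matrix()` scores tracked markers across dilutions or
timepoints: translocation markers match a verified call when both
breakpoints agree within ±10 bp (base-pair-resolved calls on simulated
data match exactly; the tolerance covers window-resolution calls),
clonotype markers by exact CDR3 identity. `lowest_detected_dilution()`
reports the most dilute detection without requiring contiguity, because
real dilution series show gaps when single informative fragments happen to
be sampled.

## The simulator

`simulate_translocation_reads()` emits aligned records directly — no
aligner runs in the loop — so the caller is tested against exactly the
evidence classes it consumes (inter-chromosomal mate pairs and soft-clips
at the junction) without inheriting aligner idiosyncrasies. A derived
haplotype `chromA[1..posA] + chromB[posB..]` represents the rearranged
tumor chromosome; each template is tumor-derived with probability
`tumor_fraction` (independent Bernoulli draws, so dilution series are
sampling-limited exactly as a real series is at fixed input mass).
Defaults mirror the assay's conditions: 300 ± 30 bp fragments (sheared
genomic DNA; 150 bp emulates cell-free DNA), 150-bp paired-end reads,
duplicates injected at 2%, base qualities Normal(35, 3) clamped to
[2, 40], dilutions 1/10 … 1/10⁶ with per-dilution seeds derived from the
master seed.

Capture enrichment is emulated by drawing tumor fragments from a ±2 kb
window around the planted junction (the probe footprint); normal
background fragments fall uniformly across the reference. Reads spanning
the junction are soft-clipped at the exact junction coordinate on the side
holding the majority of their bases, with correct CIGAR, mate and flag
fields; the truth set records the planted coordinates and junction
sequences, so any caller output can be scored without re-simulation.

`simulate_clone_cohort()` emulates the statistical structure of a
filtered repertoire cohort: one dominant planted clone per sample (counts
300–900), twenty low-count artifact clones (counts 1–45, fractions
skewed low), and a configurable set of artifact CDR3 sequences recurring
across more samples than the specificity filter tolerates. Shared
artifacts are sized at 40% of the sample's IGH count total so that, by
construction, they clear the fraction and count gates and are removed
only by the specificity filter — the failure mode they exist to exercise.

What the simulator does **not** model: sequencing errors beyond the base
quality channel, capture-efficiency or GC bias, somatic hypermutation of
the rearranged alleles, barcode/UMI structure, and chimeric-read
artifacts. Passing tests on this substrate therefore demonstrate the
correctness of the algorithms' logic — gating arithmetic, clustering,
tie-breaking, threshold boundaries, truth recovery under sampling — not
robustness to every artifact class of real libraries, where the manual
review that the verification module encodes remains the final arbiter.

## Numerical choices and degenerate inputs

* Tie-breaks everywhere are "smallest coordinate, then lexicographically
  smallest sequence", so every output is deterministic for a fixed input.
* Inclusive boundaries: insert size ≥ 5,000 counts as large; cohort
  occurrence ≤ 5 passes. Strict boundaries: clonal fraction > 0.10, clone
  count > 50 / > 10.
* Per-locus fraction groups sum to 1 within 1e-9; the filtering pipeline
  equals a brute-force predicate evaluation on randomized cohorts (tested
  property).
* Empty inputs (no reads, empty clone table, empty marker list, empty
  dilution list) yield empty outputs, not errors; malformed inputs (BED
  lines, clone-table columns, non-nucleotide characters) fail hard with
  the offending record named.
* R's default Mersenne-Twister RNG drives all simulation; per-stream seeds
  are small offsets from the master seed so adding one output stream never
  perturbs another.

## Problem sizes used in the shipped checks

The test suite and `scripts/acceptance.R` run the full caller on a
2 × 50 kb reference with 20,000 fragments per run (≈2,500× depth over the
capture window, comparable to the assay's target depth) across 20 seeds
and four dilutions (1/10 … 1/10⁴), and the clonotype pipeline on
hundreds of randomized 3–10-sample cohorts. These sizes were chosen so the
whole suite completes in a few minutes on one core while leaving every
detection decision dominated by the same sampling statistics that limit a
real dilution series; at 1/10⁴ with 20,000 fragments the expected number
of junction-spanning fragments is below one, and detection collapses for
exactly the reason deeper sequencing would rescue it.

## Known limitations

* Orientation handling assumes the simple fusion geometry the simulator
  generates (A-forward to B-forward); inversions at the junction would
  appear as separate orientation classes but are not exercised.
* The caller reports one breakpoint pair per cluster; complex events with
  co-located junctions under 1 kb apart in the same orientation class
  would merge.
* `min_insert` interacts with capture design: targets smaller than the
  threshold make same-chromosome rearrangements invisible to the pair
  channel (the clip channel still sees them).
* The Wald interval is known to undercover at small n; it is used here
  because it is what the validation tables print, not because it is the
  best interval. For downstream use, a score or exact interval would be
  preferable.
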