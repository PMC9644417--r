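# capig

Analysis toolkit for hybrid-capture immunoglobulin (Ig) sequencing of
multiple myeloma.

Recurrent translocations that fuse the immunoglobulin loci (IGH, IGK,
IGL) to partner oncogenes — t(4;14), t(11;14), t(14;16) and relatives —
and the clone-specific V(D)J junction (CDR3) are stable genomic barcodes
of the malignant plasma-cell clone. A capture panel targeting the 3′ ends
of V genes, the 5′ ends of J genes, constant-region exons and known
translocation hotspots recovers both marker classes (plus somatic
mutations) from one DNA aliquot of bone marrow or cell-free DNA, enabling
clonotyping, translocation detection and minimal-residual-disease
tracking in a single assay.

`capig` implements the informatics side of that assay for analysts
working with targeted capture data (or evaluating callers without it):

* **Probe design** — parse an IMGT-style germline segment reference and
  derive the 120-nt capture panel: 3′-anchored V probes, 5′-anchored J
  probes, tiled C-exon probes, exact-sequence deduplication and a shared
  k-mer promiscuity screen (`parse_segment_fasta()`, `design_probes()`,
  `screen_promiscuity()`).
* **CluMP translocation calling** — "clustering of mate pairs": extract
  discordant read pairs (different chromosomes, or insert ≥ 5,000 bp, both
  mates ≥ Q30, non-duplicate), cluster them by single linkage within
  1 kb windows, collect soft-clipped reads (mean base quality ≥ Phred 20,
  ≥ 33% of bases mismatching the reference) and refine each breakpoint to
  the modal clip coordinate with a majority-base consensus of the clipped
  sequences (`call_translocations()`).
* **Verification** — the manual-review confirmation rules as a
  deterministic classifier: confirmed with ≥ 2 concordant non-duplicate
  clips at both partners, or with 1 + 1 clips concordant with a matched
  sample that has ≥ 5; single reads are equivocal, never confirmatory
  (`verify_event()`, `verify_batch()`).
* **V(D)J clonotype filtering** — MiXCR-style clone tables filtered by
  clonal fraction (> 0.10 of the locus), cohort specificity (CDR3 in ≤ 5
  samples) and absolute count (> 50 cell lines / > 10 patients)
  (`load_clone_table()`, `call_candidates()`).
* **Sensitivity and limit of detection** — Wald intervals in the exact
  rounding convention of the validation tables, pooled detection rates,
  and marker × dilution/timepoint detection matrices
  (`sensitivity_ci()`, `aggregate_detection()`, `detection_matrix()`).
* **Simulation** — seeded generation of capture-like aligned reads around
  planted inter-chromosomal junctions at tumor fractions down to 1/10⁶,
  and clone-table cohorts with planted dominant clones and recurrent
  artifacts, with full ground truth (`simulate_translocation_reads()`,
  `simulate_clone_cohort()`).

A command-line entry point wraps the same functions:

```sh
capig design-probes --segments ref.fa --out probes.fa
capig call-sv --reads in.bam --min-insert 5000 --min-mapq 30 --out calls.tsv
capig filter-clones --cohort tables/ --mode cell_line --out candidates/
capig verify --calls calls.json --paired wgs_calls.json --out verified.json
capig stats ci --detected 10 --total 14
capig run --out toy_run/
```

## Worked example

Simulate a t(4;14)-like junction at 10% tumor fraction, call and verify
it, and compute the assay's summary statistics:

```r
library(capig)

cfg <- sim_config(
  seed = 7,
  ref_spec = list(list(chrom = "chr4",  length = 50000),
                  list(chrom = "chr14", length = 50000)),
  breakpoints = list(list(chromA = "chr14", posA = 30000,
                          chromB = "chr4",  posB = 25000)),
  tumor_fraction = 0.1, n_fragments = 20000)
sim <- simulate_translocation_reads(cfg)

verified <- verify_batch(call_translocations(sim$reads))
verified[, c("chromA", "posA", "chromB", "posB", "n_pairs",
             "n_clip_A", "n_clip_B", "resolution", "status")]
#>   chromA  posA chromB  posB n_pairs n_clip_A n_clip_B resolution    status
#> 1  chr14 30000   chr4 25000      94       13       16  base_pair confirmed

substr(verified$consensus_clip_A, 1, 30)        # consensus clipped bases
#> [1] "GCTACTATATATGAAATGAGCACTTAACGC"
substr(sim$truth$breakpoints$junction_seq_A, 1, 30)  # planted truth
#> [1] "GCTACTATATATGAAATGAGCACTTAACGC"

sensitivity_ci(10, 14)
#>   detected total point ci_low ci_high    z
#> 1       10    14  0.71   0.47    0.95 1.96

aggregate_detection(list(c(20, 20), c(14, 20), c(17, 20)))
#> [1] 0.85
```

Reading the output: 94 discordant mate pairs and 13 + 16 qualifying
soft-clip reads support a single cluster; the refined breakpoints land on
the planted coordinates exactly (base-pair resolution), the clip
consensus reproduces the planted junction sequence, and with ≥ 2
concordant clips on both sides the call is confirmed. `sensitivity_ci()`
shows the detection-sensitivity arithmetic used for validation cohorts —
10 of 14 cell lines gives 0.71 (0.47–0.95) — and the pooled rate across
the three major translocation families is 85%.

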