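#' Configuration objects
#'
#' Constructors for the parameter sets used across the package. Defaults
#' encode the published assay configuration: probe length 120 nt, minimum
#' insert size 5,000 bp, mapping quality Q30, mean base quality Phred 20,
#' mismatch fraction 0.33, clonal fraction threshold 0.10 (strict), cohort
#' occurrence threshold 5 (inclusive), clone count thresholds 50 (cell
#' lines) / 10 (patients), and Wald z = 1.96.
#'
#' @name capig-config
NULL

stop_if <- function(cond, ...) if (isTRUE(cond)) stop(sprintf(...), call. = FALSE)

#' @describeIn capig-config Probe design parameters.
#' @param probe_len Probe length in nt (default 120).
#' @param min_segment_len Segments shorter than this are skipped (default 40).
#' @param promiscuity_k k-mer size for the cross-hybridization screen
#'   (default 25).
#' @param promiscuity_max_hits a probe sharing a k-mer with more than this
#'   many other probes is flagged as promiscuous (default 5).
#' @return A classed list of validated parameters.
#' @export
probe_config <- function(probe_len = 120L, min_segment_len = 40L,
                         promiscuity_k = 25L, promiscuity_max_hits = 5L) {
  cfg <- list(
    probe_len = as.integer(probe_len),
    min_segment_len = as.integer(min_segment_len),
    promiscuity_k = as.integer(promiscuity_k),
    promiscuity_max_hits = promiscuity_max_hits  # may be Inf
  )
  stop_if(!(cfg$probe_len >= cfg$min_segment_len &&
              cfg$min_segment_len >= cfg$promiscuity_k &&
              cfg$promiscuity_k >= 1L),
          "probe_config requires probe_len >= min_segment_len >= promiscuity_k >= 1")
  structure(cfg, class = c("probe_config", "capig_config"))
}

#' @describeIn capig-config CluMP translocation-calling parameters.
#' @param min_insert Minimum insert size (bp, inclusive) for a same-chromosome
#'   pair to count as discordant (default 5000).
#' @param min_mapq Minimum mapping quality for both mates / clip reads
#'   (default 30).
#' @param min_baseq Minimum mean Phred base quality for clip reads
#'   (default 20).
#' @param min_mismatch_frac Minimum (soft-clipped bases + edit distance) /
#'   read length for a read to contribute clip evidence (default 0.33).
#' @param cluster_window Single-linkage window (bp) joining discordant pairs
#'   on both anchors (default 1000).
#' @param min_pairs Minimum supporting pairs for an unclipped candidate
#'   (default 2).
#' @param breakpoint_pad Padding (bp) around cluster windows when collecting
#'   clip reads (default 500).
#' @export
clump_config <- function(min_insert = 5000L, min_mapq = 30L, min_baseq = 20,
                         min_mismatch_frac = 0.33, cluster_window = 1000L,
                         min_pairs = 2L, breakpoint_pad = 500L) {
  cfg <- list(
    min_insert = as.integer(min_insert), min_mapq = as.integer(min_mapq),
    min_baseq = as.numeric(min_baseq), min_mismatch_frac = as.numeric(min_mismatch_frac),
    cluster_window = as.integer(cluster_window), min_pairs = as.integer(min_pairs),
    breakpoint_pad = as.integer(breakpoint_pad)
  )
  stop_if(any(unlist(cfg) <= 0), "clump_config values must all be positive")
  stop_if(!(cfg$min_mismatch_frac > 0 && cfg$min_mismatch_frac <= 1),
          "min_mismatch_frac must be in (0, 1]")
  structure(cfg, class = c("clump_config", "capig_config"))
}

#' @describeIn capig-config V(D)J clonotype filtering parameters.
#' @param min_fraction Clonal-fraction threshold, strict `>` (default 0.10).
#' @param max_cohort_occurrences Cohort specificity threshold, inclusive `<=`
#'   (default 5).
#' @param min_count_cell_line Clone-count threshold for cell-line mode,
#'   strict `>` (default 50).
#' @param min_count_patient Clone-count threshold for patient mode, strict
#'   `>` (default 10).
#' @param mode `"cell_line"` or `"patient"`.
#' @export
filter_config <- function(min_fraction = 0.10, max_cohort_occurrences = 5L,
                          min_count_cell_line = 50L, min_count_patient = 10L,
                          mode = c("cell_line", "patient")) {
  mode <- match.arg(mode)
  cfg <- list(
    min_fraction = as.numeric(min_fraction),
    max_cohort_occurrences = as.integer(max_cohort_occurrences),
    min_count_cell_line = as.integer(min_count_cell_line),
    min_count_patient = as.integer(min_count_patient),
    mode = mode
  )
  stop_if(cfg$min_fraction <= 0 || cfg$max_cohort_occurrences <= 0 ||
            cfg$min_count_cell_line <= 0 || cfg$min_count_patient <= 0,
          "filter_config thresholds must be positive")
  structure(cfg, class = c("filter_config", "capig_config"))
}

#' @describeIn capig-config Count threshold implied by the filtering mode.
#' @param cfg A `filter_config`.
#' @export
min_count_threshold <- function(cfg) {
  if (cfg$mode == "cell_line") cfg$min_count_cell_line else cfg$min_count_patient
}

#' @describeIn capig-config Simulation parameters. `ref_spec` is a list of
#'   `list(chrom =, length =, ig_locus = c(start, end))` entries (`ig_locus`
#'   optional, 1-based closed); `breakpoints` a list of
#'   `list(chromA =, posA =, chromB =, posB =)`.
#' @param seed Master RNG seed.
#' @param ref_spec Reference chromosome specification (see above).
#' @param breakpoints Planted inter-chromosomal junctions (see above).
#' @param tumor_fraction Probability a fragment is tumor-derived.
#' @param n_fragments Number of template fragments to simulate.
#' @param frag_len_mean,frag_len_sd Fragment length distribution (bp);
#'   300 +/- 30 emulates sheared genomic DNA, 150 emulates cell-free DNA.
#' @param read_len Read length (bp, default 150).
#' @param dup_rate PCR duplicate injection rate (default 0.02).
#' @param baseq_mean Mean Phred base quality (default 35).
#' @param capture_pad Half-width (bp) of the capture footprint around each
#'   planted junction from which tumor fragments are drawn (default 2000).
#' @export
sim_config <- function(seed = 1L, ref_spec = list(), breakpoints = list(),
                       tumor_fraction = 0.1, n_fragments = 10000L,
                       frag_len_mean = 300, frag_len_sd = 30,
                       read_len = 150L, dup_rate = 0.02, baseq_mean = 35,
                       capture_pad = 2000L) {
  cfg <- list(
    seed = as.integer(seed), ref_spec = ref_spec, breakpoints = breakpoints,
    tumor_fraction = as.numeric(tumor_fraction),
    n_fragments = as.integer(n_fragments),
    frag_len_mean = as.numeric(frag_len_mean),
    frag_len_sd = as.numeric(frag_len_sd),
    read_len = as.integer(read_len), dup_rate = as.numeric(dup_rate),
    baseq_mean = as.numeric(baseq_mean), capture_pad = as.integer(capture_pad)
  )
  stop_if(cfg$tumor_fraction < 0 || cfg$tumor_fraction > 1,
          "tumor_fraction must be in [0, 1]")
  stop_if(cfg$read_len > cfg$frag_len_mean,
          "read_len must not exceed frag_len_mean")
  lens <- setNames(
    vapply(ref_spec, function(r) as.numeric(r$length), numeric(1)),
    vapply(ref_spec, function(r) as.character(r$chrom), character(1))
  )
  for (bp in cfg$breakpoints) {
    stop_if(!(bp$chromA %in% names(lens)) || !(bp$chromB %in% names(lens)),
            "breakpoint chromosome not in ref_spec")
    stop_if(bp$posA < 1 || bp$posA > lens[[bp$chromA]] ||
              bp$posB < 1 || bp$posB > lens[[bp$chromB]],
            "breakpoint position outside chromosome bounds")
  }
  structure(cfg, class = c("sim_config", "capig_config"))
}
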