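#' Build a seeded toy reference
#'
#' Generates random-but-seeded chromosome sequences according to
#' `cfg$ref_spec`, together with any declared Ig-locus intervals. Output is
#' a deterministic function of the configuration: the same seed always
#' yields the same bytes.
#'
#' @param cfg A [sim_config()].
#' @return `list(seqs = named character vector of chromosome sequences,
#'   lengths = named integer vector, ig_loci = tibble(chrom, start, end))`
#'   with `ig_loci` in 0-based half-open (BED) coordinates.
#' @export
make_reference <- function(cfg) {
  stop_if(length(cfg$ref_spec) == 0L, "ref_spec is empty")
  set.seed(cfg$seed)
  seqs <- vapply(cfg$ref_spec, function(r) {
    paste(sample(c("A", "C", "G", "T"), r$length, replace = TRUE),
          collapse = "")
  }, character(1))
  names(seqs) <- vapply(cfg$ref_spec, function(r) r$chrom, character(1))
  ig <- purrr::map_dfr(cfg$ref_spec, function(r) {
    if (is.null(r$ig_locus)) return(NULL)
    tibble(chrom = r$chrom, start = as.integer(r$ig_locus[1] - 1L),
           end = as.integer(r$ig_locus[2]))
  })
  if (nrow(ig) == 0L) {
    ig <- tibble(chrom = character(), start = integer(), end = integer())
  }
  list(seqs = seqs, lengths = setNames(nchar(seqs), names(seqs)),
       ig_loci = ig)
}

#' @rdname make_reference
#' @param ref Reference from [make_reference()].
#' @param fasta_path Output FASTA path.
#' @param bed_path Optional output BED path for the Ig loci (0-based
#'   half-open).
#' @export
write_reference <- function(ref, fasta_path, bed_path = NULL) {
  x <- Biostrings::DNAStringSet(ref$seqs)
  Biostrings::writeXStringSet(x, fasta_path, width = 80L)
  if (!is.null(bed_path)) {
    write.table(ref$ig_loci, bed_path, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  }
  invisible(fasta_path)
}

#' Simulate capture-like aligned reads around planted translocations
#'
#' Emits aligned paired-end records directly (no aligner in the loop).
#' Each template fragment is tumor-derived with probability
#' `tumor_fraction`. Tumor fragments are drawn from a derived haplotype
#' (`chromA[1..posA] + chromB[posB..]`) restricted to a window of
#' `capture_pad` bp around the junction, emulating hybrid-capture
#' enrichment of the probe footprint; normal fragments are drawn uniformly
#' across the reference. Reads spanning the junction are soft-clipped at
#' the exact junction coordinate on the side with the majority of aligned
#' bases; mates landing on opposite sides of the junction become
#' inter-chromosomal pairs. PCR duplicates are injected at `dup_rate` as
#' flagged record copies. Base qualities are drawn Normal(`baseq_mean`, 3)
#' and clamped to \[2, 40\].
#'
#' @param cfg A [sim_config()] with at least one breakpoint.
#' @param ref Optional pre-built reference (from [make_reference()] with
#'   the same `cfg`); built on the fly when `NULL`.
#' @return `list(reads = coordinate-sorted aligned-read tibble,
#'   truth = list(breakpoints, origins, n_tumor_fragments), ref = ref)`.
#'   `truth$breakpoints` carries the planted coordinates and the expected
#'   junction-anchored clip sequences for each side (`junction_seq_A` reads
#'   into the partner B sequence from `posB`; `junction_seq_B` reads away
#'   from the junction into the A side, i.e. reversed genomic orientation).
#' @export
simulate_translocation_reads <- function(cfg, ref = NULL) {
  if (is.null(ref)) ref <- make_reference(cfg)
  rl <- cfg$read_len
  for (bp in cfg$breakpoints) {
    stop_if(bp$posA < rl || (ref$lengths[[bp$chromB]] - bp$posB + 1L) < rl,
            "junction within read_len of a chromosome end: %s:%d / %s:%d",
            bp$chromA, bp$posA, bp$chromB, bp$posB)
  }
  der <- lapply(cfg$breakpoints, function(bp) {
    lenB <- ref$lengths[[bp$chromB]]
    list(bp = bp, junction = bp$posA,
         seq = paste0(substr(ref$seqs[[bp$chromA]], 1L, bp$posA),
                      substr(ref$seqs[[bp$chromB]], bp$posB, lenB)))
  })

  set.seed(cfg$seed + 1L)
  n <- cfg$n_fragments
  tumor <- runif(n) < cfg$tumor_fraction
  if (length(der) == 0L) tumor[] <- FALSE
  L <- pmax(rl, as.integer(round(rnorm(n, cfg$frag_len_mean, cfg$frag_len_sd))))

  # fragment placement
  src_idx <- integer(n)      # >0: derived haplotype index; 0: normal
  src_chrom <- character(n)
  start <- integer(n)
  n_norm <- sum(!tumor)
  if (n_norm > 0) {
    pr <- ref$lengths / sum(ref$lengths)
    ch <- sample(names(ref$lengths), n_norm, replace = TRUE, prob = pr)
    hi <- pmax(1L, ref$lengths[ch] - L[!tumor] + 1L)
    src_chrom[!tumor] <- ch
    start[!tumor] <- 1L + as.integer(floor(runif(n_norm) * hi))
  }
  n_tum <- sum(tumor)
  if (n_tum > 0) {
    bi <- sample(length(der), n_tum, replace = TRUE)
    src_idx[tumor] <- bi
    J <- vapply(der, function(d) d$junction, numeric(1))[bi]
    dlen <- vapply(der, function(d) nchar(d$seq), numeric(1))[bi]
    lo <- pmax(1, J - cfg$capture_pad)
    hi <- pmax(lo, pmin(dlen - L[tumor] + 1, J + cfg$capture_pad))
    start[tumor] <- as.integer(lo + floor(runif(n_tum) * (hi - lo + 1)))
  }

  qname <- sprintf("f%07d", seq_len(n))
  baseq <- matrix(pmin(40, pmax(2, round(rnorm(2L * n, cfg$baseq_mean, 3)))),
                  ncol = 2)

  map_read <- function(frag_sel, offset_start) {
    # offset_start: vector of read start positions in source coordinates
    sel_tumor <- tumor[frag_sel]
    di <- src_idx[frag_sel]
    s <- offset_start
    e <- s + rl - 1L
    out <- tibble(chrom = character(length(s)), pos = integer(length(s)),
                  cigar = sprintf("%dM", rl), seq = character(length(s)),
                  nm = 0L, clipped_prefix = "", clipped_suffix = "")
    if (any(!sel_tumor)) {
      i <- which(!sel_tumor)
      ch <- src_chrom[frag_sel][i]
      out$chrom[i] <- ch
      out$pos[i] <- s[i]
      out$seq[i] <- substring(ref$seqs[ch], s[i], e[i])
    }
    if (any(sel_tumor)) {
      i <- which(sel_tumor)
      d <- di[i]
      J <- vapply(der, function(x) x$junction, numeric(1))[d]
      bpA_chrom <- vapply(der, function(x) x$bp$chromA, character(1))[d]
      bpB_chrom <- vapply(der, function(x) x$bp$chromB, character(1))[d]
      bpB_pos <- vapply(der, function(x) x$bp$posB, numeric(1))[d]
      dseq <- vapply(der, function(x) x$seq, character(1))[d]
      rseq <- substring(dseq, s[i], e[i])
      nA <- pmin(pmax(J - s[i] + 1, 0), rl)  # A-side bases in read
      nB <- rl - nA
      full_A <- nA == rl
      full_B <- nA == 0
      anchor_A <- !full_A & !full_B & nA >= nB
      anchor_B <- !full_A & !full_B & nA < nB
      on_A <- full_A | anchor_A
      chrom_t <- ifelse(on_A, bpA_chrom, bpB_chrom)
      pos_t <- ifelse(on_A, s[i],
                      ifelse(full_B, bpB_pos + (s[i] - J - 1), bpB_pos))
      cigar_t <- rep(sprintf("%dM", rl), length(i))
      cigar_t[anchor_A] <- sprintf("%dM%dS", nA[anchor_A], nB[anchor_A])
      cigar_t[anchor_B] <- sprintf("%dS%dM", nA[anchor_B], nB[anchor_B])
      suf_t <- rep("", length(i))
      suf_t[anchor_A] <- substring(rseq[anchor_A], nA[anchor_A] + 1L, rl)
      pre_t <- rep("", length(i))
      pre_t[anchor_B] <- substring(rseq[anchor_B], 1L, nA[anchor_B])
      out$seq[i] <- rseq
      out$chrom[i] <- chrom_t
      out$pos[i] <- as.integer(pos_t)
      out$cigar[i] <- cigar_t
      out$clipped_suffix[i] <- suf_t
      out$clipped_prefix[i] <- pre_t
    }
    out
  }

  all_frags <- seq_len(n)
  r1 <- map_read(all_frags, start)
  r2 <- map_read(all_frags, start + L - rl)

  end1 <- r1$pos + cigar_ref_len(r1$cigar) - 1L
  end2 <- r2$pos + cigar_ref_len(r2$cigar) - 1L
  same <- r1$chrom == r2$chrom
  insert <- ifelse(same, pmax(end1, end2) - pmin(r1$pos, r2$pos) + 1L, 0L)
  proper <- same & r1$cigar == sprintf("%dM", rl) & r2$cigar == sprintf("%dM", rl)

  build <- function(r, mate, first, bq) {
    tibble(qname = qname, chrom = r$chrom, pos = r$pos,
           strand = if (first) "+" else "-", mapq = 60L, cigar = r$cigar,
           seq = r$seq, mean_baseq = as.numeric(bq),
           mate_chrom = mate$chrom, mate_pos = mate$pos,
           mate_strand = if (first) "-" else "+",
           insert_size = as.integer(insert), is_first = first,
           is_proper = proper, is_duplicate = FALSE, nm = r$nm,
           clipped_prefix = r$clipped_prefix,
           clipped_suffix = r$clipped_suffix, read_len = rl)
  }
  reads <- bind_rows(build(r1, r2, TRUE, baseq[, 1]),
                     build(r2, r1, FALSE, baseq[, 2]))

  dup <- runif(n) < cfg$dup_rate
  if (any(dup)) {
    dup_q <- qname[dup]
    dups <- reads[reads$qname %in% dup_q, , drop = FALSE]
    dups$qname <- paste0(dups$qname, "d")
    dups$is_duplicate <- TRUE
    reads <- bind_rows(reads, dups)
  }
  reads <- reads[order(match(reads$chrom, names(ref$lengths)), reads$pos), ]

  truth_bp <- purrr::map_dfr(der, function(d) {
    bp <- d$bp
    lenB <- ref$lengths[[bp$chromB]]
    tibble(chromA = bp$chromA, posA = as.integer(bp$posA),
           chromB = bp$chromB, posB = as.integer(bp$posB),
           junction_seq_A = substr(ref$seqs[[bp$chromB]], bp$posB,
                                   min(lenB, bp$posB + rl - 1L)),
           junction_seq_B = stringi::stri_reverse(
             substr(ref$seqs[[bp$chromA]], max(1L, bp$posA - rl + 1L),
                    bp$posA)))
  })
  list(reads = reads,
       truth = list(breakpoints = truth_bp,
                    origins = tibble(qname = qname, tumor = tumor),
                    n_tumor_fragments = sum(tumor)),
       ref = ref)
}

#' Simulate a dilution series
#'
#' Runs [simulate_translocation_reads()] once per dilution with a
#' per-dilution seed derived from the master seed (`seed + index`), sharing
#' the reference and planted breakpoints. When `out_dir` is given, each
#' run's reads are written as SAM together with a `manifest.json`.
#'
#' @param cfg A [sim_config()]; its `tumor_fraction` is overridden per run.
#' @param dilutions Numeric vector of tumor fractions, e.g.
#'   `10^-(1:6)` for the 1/10 .. 1/10^6 design.
#' @param out_dir Optional output directory.
#' @return `list(runs = named list of simulation results, manifest = tibble)`.
#' @export
simulate_dilution_series <- function(cfg, dilutions, out_dir = NULL) {
  ref <- make_reference(cfg)
  runs <- list()
  manifest <- tibble(label = character(), tumor_fraction = numeric(),
                     seed = integer(), file = character())
  for (i in seq_along(dilutions)) {
    cfg_i <- cfg
    cfg_i$tumor_fraction <- dilutions[i]
    cfg_i$seed <- cfg$seed + i
    label <- sprintf("dilution_%g", dilutions[i])
    sim <- simulate_translocation_reads(cfg_i, ref = ref)
    path <- NA_character_
    if (!is.null(out_dir)) {
      dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
      path <- file.path(out_dir, paste0(label, ".sam"))
      write_alignments(sim$reads, ref$lengths, path)
    }
    runs[[label]] <- sim
    manifest <- bind_rows(manifest,
                          tibble(label = label,
                                 tumor_fraction = dilutions[i],
                                 seed = cfg_i$seed, file = path))
  }
  if (!is.null(out_dir)) {
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         dataframe = "rows", pretty = TRUE)
  }
  list(runs = runs, manifest = manifest)
}

random_cdr3 <- function(n, len_range = c(36L, 60L)) {
  lens <- sample(seq(len_range[1], len_range[2], by = 3L), n, replace = TRUE)
  vapply(lens, function(l) {
    paste(sample(c("A", "C", "G", "T"), l, replace = TRUE), collapse = "")
  }, character(1))
}

#' Simulate a clone-table cohort with planted truth
#'
#' Generates per-sample MiXCR-style clone tables emulating the statistical
#' structure of a filtered repertoire experiment: each sample carries one
#' dominant planted clone per configured locus (high count, high clonal
#' fraction) plus low-count artifact clones whose fractions skew low; a
#' configurable subset of artifact CDR3 sequences recurs across more than
#' `shared_samples` samples to exercise the cohort-specificity filter.
#'
#' @param n_samples Number of samples in the cohort.
#' @param planted_spec `list(count_range = c(lo, hi), locus =)` for the
#'   planted dominant clone (defaults: counts 300-900 on IGH).
#' @param artifact_spec `list(n_per_sample =, count_range =, n_shared =,
#'   shared_samples =, shared_rel_count =)` for artifacts (defaults: 20
#'   artifacts/sample with counts 1-45; 2 shared sequences planted into 8
#'   samples). Shared artifacts are sized at `shared_rel_count` (default
#'   0.4) times the sample's IGH clone-count total so that they clear the
#'   clonal-fraction and count thresholds by construction and are removed
#'   only by the cohort-specificity filter — the failure mode they exist to
#'   exercise.
#' @param seed RNG seed.
#' @return `list(tables = named list of per-sample clone tibbles (MiXCR
#'   export column names), truth = tibble of every generated clone with
#'   `planted` / `shared` flags)`.
#' @export
simulate_clone_cohort <- function(n_samples, planted_spec = list(),
                                  artifact_spec = list(), seed = 1L) {
  ps <- utils::modifyList(list(count_range = c(300L, 900L), locus = "IGH"),
                          planted_spec)
  as_ <- utils::modifyList(list(n_per_sample = 20L, count_range = c(1L, 45L),
                                n_shared = 2L, shared_samples = 8L,
                                shared_rel_count = 0.4),
                           artifact_spec)
  as_$shared_samples <- min(as_$shared_samples, n_samples)
  set.seed(seed)
  loci <- c("IGH", "IGK", "IGL")
  sample_ids <- sprintf("S%02d", seq_len(n_samples))

  shared_seqs <- random_cdr3(as_$n_shared)
  shared_members <- lapply(seq_len(as_$n_shared), function(i) {
    sample(sample_ids, as_$shared_samples)
  })

  gene_pick <- function(locus, cls, k) {
    sprintf("%s%s%d-%d", locus, cls, sample(1:7, k, TRUE), sample(1:40, k, TRUE))
  }

  all_clones <- purrr::map_dfr(sample_ids, function(sid) {
    planted <- tibble(
      sample_id = sid, locus = ps$locus,
      v_gene = gene_pick(ps$locus, "V", 1L),
      d_gene = if (ps$locus == "IGH") gene_pick("IGH", "D", 1L) else "",
      j_gene = gene_pick(ps$locus, "J", 1L),
      cdr3_nt = random_cdr3(1L),
      clone_count = sample(ps$count_range[1]:ps$count_range[2], 1L),
      planted = TRUE, shared = FALSE)
    k <- as_$n_per_sample
    art_locus <- sample(loci, k, replace = TRUE)
    arts <- tibble(
      sample_id = sid, locus = art_locus,
      v_gene = gene_pick(art_locus, "V", k),
      d_gene = ifelse(art_locus == "IGH", gene_pick("IGH", "D", k), ""),
      j_gene = gene_pick(art_locus, "J", k),
      cdr3_nt = random_cdr3(k),
      clone_count = sample(as_$count_range[1]:as_$count_range[2], k, TRUE),
      planted = FALSE, shared = FALSE)
    shared_here <- vapply(shared_members, function(m) sid %in% m, logical(1))
    sh <- NULL
    if (any(shared_here)) {
      idx <- which(shared_here)
      igh_total <- sum(planted$clone_count[planted$locus == "IGH"],
                       arts$clone_count[arts$locus == "IGH"])
      sh <- tibble(
        sample_id = sid, locus = "IGH",
        v_gene = gene_pick("IGH", "V", length(idx)),
        d_gene = gene_pick("IGH", "D", length(idx)),
        j_gene = gene_pick("IGH", "J", length(idx)),
        cdr3_nt = shared_seqs[idx],
        clone_count = as.integer(round(as_$shared_rel_count * igh_total)),
        planted = FALSE, shared = TRUE)
    }
    bind_rows(planted, arts, sh)
  })

  all_clones <- all_clones |>
    group_by(.data$sample_id, .data$locus) |>
    mutate(clone_fraction = .data$clone_count / sum(.data$clone_count)) |>
    ungroup()

  tables <- lapply(sample_ids, function(sid) {
    d <- all_clones[all_clones$sample_id == sid, , drop = FALSE]
    tibble(
      cloneCount = d$clone_count,
      cloneFraction = d$clone_fraction,
      allVHitsWithScore = sprintf("%s*00(%d)", d$v_gene,
                                  sample(500:2500, nrow(d), TRUE)),
      allDHitsWithScore = ifelse(nzchar(d$d_gene),
                                 sprintf("%s*00(%d)", d$d_gene,
                                         sample(50:500, nrow(d), TRUE)), ""),
      allJHitsWithScore = sprintf("%s*00(%d)", d$j_gene,
                                  sample(200:900, nrow(d), TRUE)),
      nSeqCDR3 = d$cdr3_nt,
      aaSeqCDR3 = ""
    )
  })
  names(tables) <- sample_ids
  list(tables = tables, truth = all_clones)
}

#' @rdname simulate_clone_cohort
#' @param cohort Result of [simulate_clone_cohort()].
#' @param dir Output directory; one `<sample>.tsv` per sample.
#' @export
write_clone_tables <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (sid in names(cohort$tables)) {
    write.table(cohort$tables[[sid]], file.path(dir, paste0(sid, ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}
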