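# Shared fixture builders: everything is generated in code at test time.

# one aligned read row with sensible defaults, overridable per field
make_read <- function(qname = "r1", chrom = "chr1", pos = 1000L,
                      strand = "+", mapq = 60L, cigar = "150M",
                      seq = strrep("A", 150L), mean_baseq = 35,
                      mate_chrom = chrom, mate_pos = pos + 200L,
                      mate_strand = "-", insert_size = 350L,
                      is_first = TRUE, is_proper = TRUE,
                      is_duplicate = FALSE, nm = 0L,
                      clipped_prefix = "", clipped_suffix = "") {
  tibble::tibble(qname = qname, chrom = chrom, pos = as.integer(pos),
                 strand = strand, mapq = as.integer(mapq), cigar = cigar,
                 seq = seq, mean_baseq = mean_baseq,
                 mate_chrom = mate_chrom, mate_pos = as.integer(mate_pos),
                 mate_strand = mate_strand,
                 insert_size = as.integer(insert_size), is_first = is_first,
                 is_proper = is_proper, is_duplicate = is_duplicate,
                 nm = as.integer(nm), clipped_prefix = clipped_prefix,
                 clipped_suffix = clipped_suffix, read_len = nchar(seq))
}

# a mate pair as two rows; pair-level fields derived from the two anchors
make_pair <- function(qname, chromA, posA, chromB, posB, mapqA = 60L,
                      mapqB = 60L, dupA = FALSE, dupB = FALSE,
                      insert = if (chromA == chromB)
                        abs(posB - posA) + 150L else 0L) {
  dplyr::bind_rows(
    make_read(qname, chromA, posA, "+", mapqA, mate_chrom = chromB,
              mate_pos = posB, insert_size = insert, is_first = TRUE,
              is_proper = chromA == chromB && insert < 1000L,
              is_duplicate = dupA),
    make_read(qname, chromB, posB, "-", mapqB, mate_chrom = chromA,
              mate_pos = posA, mate_strand = "+", insert_size = insert,
              is_first = FALSE,
              is_proper = chromA == chromB && insert < 1000L,
              is_duplicate = dupB))
}

sort_reads <- function(reads, chrom_order = c("chr1", "chr2", "chr3")) {
  reads[order(match(reads$chrom, chrom_order), reads$pos), ]
}

random_seq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# toy segment FASTA in the simple header dialect
write_segment_fasta <- function(path, records) {
  lines <- unlist(lapply(records, function(r) {
    c(sprintf(">%s|%s|%s|%s", r$allele, r$class, r$locus,
              r$functionality %||% "functional"), r$seq)
  }))
  writeLines(lines, path)
  path
}

toy_sim_config <- function(seed = 1L, tumor_fraction = 0.1,
                           n_fragments = 20000L, ...) {
  sim_config(seed = seed,
             ref_spec = list(list(chrom = "chr1", length = 50000L),
                             list(chrom = "chr2", length = 50000L)),
             breakpoints = list(list(chromA = "chr1", posA = 25000L,
                                     chromB = "chr2", posB = 30000L)),
             tumor_fraction = tumor_fraction, n_fragments = n_fragments,
             ...)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# independent literal re-evaluation of the whole clonotype filtering
# pipeline: plain loops, no shared code with the package implementation
brute_force_candidates <- function(cohort, cfg, pseudogenes = character()) {
  staged <- list()
  for (sid in names(cohort)) {
    d <- as.data.frame(cohort[[sid]])
    d <- d[!(d$v_gene %in% pseudogenes | d$j_gene %in% pseudogenes), ]
    if (nrow(d) > 0) {
      frac <- numeric(nrow(d))
      for (i in seq_len(nrow(d))) {
        tot <- sum(d$clone_count[d$locus == d$locus[i]])
        frac[i] <- d$clone_count[i] / tot
      }
      d$clone_fraction <- frac
      d <- d[frac > cfg$min_fraction, ]
    }
    staged[[sid]] <- d
  }
  pool <- do.call(rbind, staged)
  out <- list()
  for (sid in names(cohort)) {
    d <- staged[[sid]]
    keep <- logical(nrow(d))
    for (i in seq_len(nrow(d))) {
      occ <- length(unique(pool$sample_id[pool$cdr3_nt == d$cdr3_nt[i]]))
      thr <- if (cfg$mode == "cell_line") cfg$min_count_cell_line else
        cfg$min_count_patient
      keep[i] <- occ <= cfg$max_cohort_occurrences && d$clone_count[i] > thr
    }
    d <- d[keep, ]
    out[[sid]] <- d[order(-d$clone_count, d$cdr3_nt), ]
  }
  out
}

evidence_from_config <- function(n_a, n_b, concordant, paired) {
  base <- strrep("ACGTA", 8)  # 40-mer shared consensus
  distinct <- c("AAGGTTCCAAGGTTCCAAGG", "CCAATTGGCCAATTGGCCAA",
                "GGTTAACCGGTTAACCGGTT", "TTCCGGAATTCCGGAATTCC",
                "ACACACACACACACACACAC", "GTGTGTGTGTGTGTGTGTGT")
  pick <- function(n, offset = 0L) {
    if (n == 0L) return(character())
    if (concordant == "yes") rep(base, n) else distinct[offset + seq_len(n)]
  }
  pa <- capig::partner_evidence(pick(n_a))
  pb <- capig::partner_evidence(pick(n_b))
  pev <- NULL
  if (paired != "absent") {
    k <- as.integer(paired)
    seqs_a <- if (concordant == "yes") rep(base, k) else
      rep("CATCATCATCATCATCATCA", k)
    seqs_b <- if (concordant == "yes") base else "TACTACTACTACTACTACTA"
    pev <- list(partnerA = capig::partner_evidence(seqs_a),
                partnerB = capig::partner_evidence(seqs_b))
  }
  list(partnerA = pa, partnerB = pb, paired = pev)
}
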