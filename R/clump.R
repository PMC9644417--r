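#' Extract discordant read pairs
#'
#' First stage of CluMP: scans a coordinate-sorted aligned-read table and
#' emits one canonicalized record per template whose mates map to different
#' chromosomes or whose insert size is at least `min_insert` bp
#' (inclusive). Both mates must reach `min_mapq` and neither may be a
#' flagged duplicate. Anchors are ordered so that
#' `(chromA, posA) <= (chromB, posB)` lexicographically.
#'
#' @param reads Aligned-read tibble (see [read_alignments()]), or a path to
#'   a SAM/BAM file.
#' @param cfg A [clump_config()].
#' @return Tibble of discordant pairs: `qname`, `chromA`, `posA`,
#'   `strandA`, `chromB`, `posB`, `strandB`, `min_pair_mapq`,
#'   `inter_chromosomal`. Templates with missing mate information are
#'   skipped; their number is attached as attribute `n_missing_mate`.
#' @export
extract_discordant <- function(reads, cfg = clump_config()) {
  reads <- as_read_tbl(reads)
  check_sorted(reads)
  empty <- tibble(qname = character(), chromA = character(),
                  posA = integer(), strandA = character(),
                  chromB = character(), posB = integer(),
                  strandB = character(), min_pair_mapq = integer(),
                  inter_chromosomal = logical())
  if (nrow(reads) == 0L) {
    attr(empty, "n_missing_mate") <- 0L
    return(empty)
  }
  has_mate <- !is.na(reads$mate_chrom) & reads$mate_chrom != "*" &
    !is.na(reads$mate_pos) & reads$mate_pos > 0L
  missing_tpl <- unique(reads$qname[!has_mate])
  reads <- reads[has_mate & !(reads$qname %in% missing_tpl), , drop = FALSE]

  counts <- table(reads$qname)
  paired_q <- names(counts)[counts == 2L]
  n_missing <- length(missing_tpl) + sum(counts != 2L)
  reads <- reads[reads$qname %in% paired_q, , drop = FALSE]
  if (nrow(reads) == 0L) {
    attr(empty, "n_missing_mate") <- n_missing
    return(empty)
  }
  reads <- reads[order(reads$qname, !reads$is_first), , drop = FALSE]
  i1 <- seq(1L, nrow(reads), by = 2L)
  i2 <- i1 + 1L
  m1 <- reads[i1, ]; m2 <- reads[i2, ]

  pass <- m1$mapq >= cfg$min_mapq & m2$mapq >= cfg$min_mapq &
    !m1$is_duplicate & !m2$is_duplicate &
    (m1$chrom != m2$chrom | pmax(m1$insert_size, m2$insert_size) >= cfg$min_insert)
  m1 <- m1[pass, ]; m2 <- m2[pass, ]
  swap <- m2$chrom < m1$chrom | (m2$chrom == m1$chrom & m2$pos < m1$pos)
  a <- m1; b <- m2
  a[swap, ] <- m2[swap, ]; b[swap, ] <- m1[swap, ]
  out <- tibble(qname = a$qname,
                chromA = a$chrom, posA = a$pos, strandA = a$strand,
                chromB = b$chrom, posB = b$pos, strandB = b$strand,
                min_pair_mapq = pmin(a$mapq, b$mapq),
                inter_chromosomal = a$chrom != b$chrom) |>
    arrange(.data$chromA, .data$posA, .data$chromB, .data$posB, .data$qname)
  attr(out, "n_missing_mate") <- n_missing
  out
}

as_read_tbl <- function(reads) {
  if (is.character(reads)) read_alignments(reads) else reads
}

check_sorted <- function(reads) {
  if (nrow(reads) < 2L) return(invisible(TRUE))
  ch <- reads$chrom
  new_block <- ch[-1L] != ch[-length(ch)]
  # chromosomes must form contiguous blocks, positions nondecreasing within
  blocks <- c(ch[1L], ch[-1L][new_block])
  stop_if(anyDuplicated(blocks) > 0L,
          "input reads are not coordinate-sorted (chromosome blocks repeat)")
  pos_ok <- new_block | diff(reads$pos) >= 0L
  stop_if(!all(pos_ok), "input reads are not coordinate-sorted")
  invisible(TRUE)
}

#' Cluster discordant pairs into candidate breakpoints
#'
#' Single-linkage clustering of discordant pairs within each
#' (chromA, chromB, orientation class) stratum: two pairs join the same
#' cluster when their A anchors are within `cluster_window` bp of each
#' other and their B anchors are too. Cluster windows are the min/max
#' anchor extents. Pairs are pre-sorted by anchors, so the result is
#' deterministic for a given input set.
#'
#' @param pairs Tibble from [extract_discordant()].
#' @param cfg A [clump_config()].
#' @return Tibble of clusters: `cluster_id`, `chromA`, `startA`, `endA`,
#'   `chromB`, `startB`, `endB`, `orientation`, `n_pairs`, and a `pairs`
#'   list-column holding the member pair rows.
#' @export
cluster_pairs <- function(pairs, cfg = clump_config()) {
  empty <- tibble(cluster_id = integer(), chromA = character(),
                  startA = integer(), endA = integer(), chromB = character(),
                  startB = integer(), endB = integer(),
                  orientation = character(), n_pairs = integer(),
                  pairs = list())
  if (nrow(pairs) == 0L) return(empty)
  pairs <- pairs |>
    mutate(orientation = paste0(ifelse(.data$strandA == "+", "F", "R"),
                                ifelse(.data$strandB == "+", "F", "R"))) |>
    arrange(.data$chromA, .data$chromB, .data$orientation, .data$posA,
            .data$posB, .data$qname)
  key <- paste(pairs$chromA, pairs$chromB, pairs$orientation, sep = "\r")
  groups <- split(seq_len(nrow(pairs)), key)

  out <- list()
  cid <- 0L
  for (g in groups[unique(key)]) {
    sub <- pairs[g, , drop = FALSE]
    n <- nrow(sub)
    parent <- seq_len(n)
    find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    w <- cfg$cluster_window
    for (i in seq_len(n)) {
      j <- i + 1L
      while (j <= n && sub$posA[j] - sub$posA[i] <= w) {
        if (abs(sub$posB[j] - sub$posB[i]) <= w) {
          ri <- find(i); rj <- find(j)
          if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
        }
        j <- j + 1L
      }
    }
    roots <- vapply(seq_len(n), find, integer(1))
    for (r in unique(roots)) {
      mem <- sub[roots == r, , drop = FALSE]
      cid <- cid + 1L
      out[[cid]] <- tibble(
        cluster_id = cid, chromA = mem$chromA[1],
        startA = min(mem$posA), endA = max(mem$posA),
        chromB = mem$chromB[1], startB = min(mem$posB),
        endB = max(mem$posB), orientation = mem$orientation[1],
        n_pairs = nrow(mem), pairs = list(mem))
    }
  }
  bind_rows(out)
}

#' Collect soft-clip evidence around a cluster window
#'
#' Extracts soft-clip evidence from reads overlapping one side of a
#' candidate breakpoint cluster (window padded by `breakpoint_pad`). A read
#' qualifies when its mapping quality reaches `min_mapq`, its mean base
#' quality reaches `min_baseq`, it is not a flagged duplicate, and the
#' fraction of bases not matching the reference — soft-clipped bases plus
#' aligned-base edit distance, over the full read length — is at least
#' `min_mismatch_frac`. PCR duplicates beyond the flag are collapsed by
#' identical (position, CIGAR). One evidence row is emitted per clip.
#'
#' @param reads Aligned-read tibble or SAM/BAM path.
#' @param chrom,start,end Window to query (1-based, closed).
#' @param cfg A [clump_config()].
#' @return Tibble of clip evidence: `qname`, `pos`, `cigar`, `side`
#'   (`left`/`right`), `clip_coord` (reference coordinate of the aligned
#'   base adjacent to the clip), `clipped_seq`, `mean_baseq`, `mapq`.
#' @export
collect_clip_support <- function(reads, chrom, start, end,
                                 cfg = clump_config()) {
  reads <- as_read_tbl(reads)
  lo <- start - cfg$breakpoint_pad
  hi <- end + cfg$breakpoint_pad
  ref_len <- cigar_ref_len(reads$cigar)
  ov <- reads$chrom == chrom & reads$pos <= hi &
    (reads$pos + ref_len - 1L) >= lo
  sub <- reads[ov, , drop = FALSE]
  sub_ref_len <- ref_len[ov]
  if (nrow(sub) == 0L) return(empty_clip_tbl())

  clip_len <- nchar(sub$clipped_prefix) + nchar(sub$clipped_suffix)
  mm_frac <- (clip_len + sub$nm) / sub$read_len
  keep <- sub$mapq >= cfg$min_mapq & sub$mean_baseq >= cfg$min_baseq &
    !sub$is_duplicate & mm_frac >= cfg$min_mismatch_frac & clip_len > 0L
  sub <- sub[keep, , drop = FALSE]
  sub_ref_len <- sub_ref_len[keep]
  if (nrow(sub) == 0L) return(empty_clip_tbl())
  # positional duplicate collapse: same (pos, cigar) == same template stack
  dup <- duplicated(paste(sub$pos, sub$cigar))
  sub <- sub[!dup, , drop = FALSE]
  sub_ref_len <- sub_ref_len[!dup]

  left <- sub[nzchar(sub$clipped_prefix), , drop = FALSE]
  right <- sub[nzchar(sub$clipped_suffix), , drop = FALSE]
  bind_rows(
    if (nrow(left)) tibble(qname = left$qname, pos = left$pos,
                           cigar = left$cigar, side = "left",
                           clip_coord = left$pos,
                           clipped_seq = left$clipped_prefix,
                           mean_baseq = left$mean_baseq, mapq = left$mapq),
    if (nrow(right)) tibble(qname = right$qname, pos = right$pos,
                            cigar = right$cigar, side = "right",
                            clip_coord = right$pos +
                              sub_ref_len[nzchar(sub$clipped_suffix)] - 1L,
                            clipped_seq = right$clipped_suffix,
                            mean_baseq = right$mean_baseq, mapq = right$mapq)
  ) |> arrange(.data$clip_coord, .data$qname)
}

empty_clip_tbl <- function() {
  tibble(qname = character(), pos = integer(), cigar = character(),
         side = character(), clip_coord = integer(),
         clipped_seq = character(), mean_baseq = numeric(),
         mapq = integer())
}

majority_consensus <- function(seqs) {
  if (length(seqs) == 0L) return("")
  mat <- stringr::str_split_fixed(seqs, "", max(nchar(seqs)))
  apply(mat, 2, function(col) {
    col <- col[nzchar(col)]
    if (length(col) == 0L) return("")
    tab <- table(col)
    names(tab)[which.max(tab)]  # ties: lexicographically smallest (table order)
  }) |> paste(collapse = "")
}

refine_side <- function(clips, win_start, win_end) {
  if (nrow(clips) == 0L) {
    return(list(pos = as.integer(floor((win_start + win_end) / 2)),
                n_clip = 0L, consensus = "", clip_seqs = character(),
                resolution = "window"))
  }
  tab <- table(clips$clip_coord)
  modal <- min(as.integer(names(tab)[tab == max(tab)]))
  at <- clips[clips$clip_coord == modal, , drop = FALSE]
  # consensus is built from the dominant clip side at the modal coordinate
  # (ties toward right clips, whose sequences already read away from the
  # junction)
  dominant <- if (sum(at$side == "right") >= sum(at$side == "left"))
    "right" else "left"
  use <- at[at$side == dominant, , drop = FALSE]
  oriented <- sort(junction_outward(use$clipped_seq, dominant))
  list(pos = modal, n_clip = nrow(at),
       consensus = majority_consensus(oriented),
       clip_seqs = oriented, resolution = "base_pair")
}

# junction-outward orientation: right clips read away from the junction
# already; left clips are reversed so position 1 abuts the junction
junction_outward <- function(seqs, side) {
  if (side == "right") seqs else stringi::stri_reverse(seqs)
}

#' Refine a cluster into a translocation call
#'
#' Turns one breakpoint cluster plus its per-side clip evidence into a
#' refined call. Per side, the breakpoint position is the modal clip
#' coordinate (ties broken toward the smallest coordinate) and the
#' consensus clip is the per-position majority base over the clipped
#' sequences aligned at the junction (ties toward the lexicographically
#' smallest base); with no clip evidence the side falls back to the window
#' midpoint. Clip sequences and consensus are reported junction-anchored,
#' reading away from the breakpoint.
#'
#' @param cluster One row of [cluster_pairs()] output.
#' @param clipsA,clipsB Clip-evidence tibbles for the two sides.
#' @return One-row call tibble: `chromA`, `posA`, `chromB`, `posB`,
#'   `n_pairs`, `n_clip_A`, `n_clip_B`, `consensus_clip_A/B`,
#'   `clip_seqs_A/B` (list-columns), `resolution`
#'   (`base_pair` when at least one side has clip evidence), `status`
#'   (`candidate`), `filter_reason`.
#' @export
refine_breakpoint <- function(cluster, clipsA = empty_clip_tbl(),
                              clipsB = empty_clip_tbl()) {
  a <- refine_side(clipsA, cluster$startA, cluster$endA)
  b <- refine_side(clipsB, cluster$startB, cluster$endB)
  tibble(
    chromA = cluster$chromA, posA = a$pos,
    chromB = cluster$chromB, posB = b$pos,
    n_pairs = cluster$n_pairs,
    n_clip_A = a$n_clip, n_clip_B = b$n_clip,
    consensus_clip_A = a$consensus, consensus_clip_B = b$consensus,
    clip_seqs_A = list(a$clip_seqs), clip_seqs_B = list(b$clip_seqs),
    resolution = if (a$resolution == "base_pair" ||
                     b$resolution == "base_pair") "base_pair" else "window",
    status = "candidate", filter_reason = ""
  )
}

#' Filter translocation calls by region and support
#'
#' Marks calls as `filtered` (status and reason only; nothing is deleted)
#' when either breakpoint falls inside a blacklist interval
#' (`"blacklist"`), when both breakpoints fall inside Ig-locus intervals
#' (`"ig_internal"`, these rearrangements are handled by the clonotype
#' arm of the pipeline instead), or when supporting pairs are fewer than
#' `min_pairs` with no clip evidence (`"min_support"`). Idempotent:
#' re-filtering a filtered set with the same intervals is a no-op, and a
#' call whose reason no longer applies reverts to `candidate`.
#'
#' @param calls Call tibble from [refine_breakpoint()] /
#'   [call_translocations()].
#' @param blacklist,ig_loci Interval tibbles `(chrom, start, end)` in
#'   0-based half-open coordinates (e.g. from [read_bed()]), or `NULL`.
#' @param cfg A [clump_config()].
#' @return The call tibble with `status` / `filter_reason` updated.
#' @export
filter_events <- function(calls, blacklist = NULL, ig_loci = NULL,
                          cfg = clump_config()) {
  if (nrow(calls) == 0L) return(calls)
  in_bed <- function(chrom, pos, bed) {
    if (is.null(bed) || nrow(bed) == 0L) return(rep(FALSE, length(pos)))
    lv <- union(unique(chrom), unique(bed$chrom))
    gr_bed <- GenomicRanges::GRanges(
      factor(bed$chrom, lv), IRanges::IRanges(bed$start + 1L, bed$end))
    gr_pos <- GenomicRanges::GRanges(factor(chrom, lv),
                                     IRanges::IRanges(pos, pos))
    IRanges::overlapsAny(gr_pos, gr_bed)
  }
  bl <- in_bed(calls$chromA, calls$posA, blacklist) |
    in_bed(calls$chromB, calls$posB, blacklist)
  ig <- in_bed(calls$chromA, calls$posA, ig_loci) &
    in_bed(calls$chromB, calls$posB, ig_loci)
  weak <- calls$n_pairs < cfg$min_pairs &
    calls$n_clip_A + calls$n_clip_B == 0L
  reason <- dplyr::case_when(bl ~ "blacklist",
                             ig ~ "ig_internal",
                             weak ~ "min_support",
                             TRUE ~ "")
  newly_filtered <- nzchar(reason)
  calls$filter_reason <- reason
  calls$status <- ifelse(newly_filtered, "filtered",
                         ifelse(calls$status == "filtered", "candidate",
                                calls$status))
  calls
}

#' Call translocations from aligned reads (CluMP)
#'
#' Full CluMP pipeline: discordant-pair extraction, single-linkage
#' clustering, per-side soft-clip collection, breakpoint refinement and
#' region filtering. Deterministic for a fixed input; output is
#' stable-ordered by `(chromA, posA, chromB, posB)`.
#'
#' @param reads Aligned-read tibble or SAM/BAM path.
#' @param cfg A [clump_config()].
#' @param blacklist,ig_loci Optional interval tibbles (0-based half-open).
#' @return Call tibble (see [refine_breakpoint()]).
#' @export
call_translocations <- function(reads, cfg = clump_config(),
                                blacklist = NULL, ig_loci = NULL) {
  reads <- as_read_tbl(reads)
  pairs <- extract_discordant(reads, cfg)
  clusters <- cluster_pairs(pairs, cfg)
  if (nrow(clusters) == 0L) return(empty_call_tbl())
  calls <- purrr::map_dfr(seq_len(nrow(clusters)), function(i) {
    cl <- clusters[i, ]
    clipsA <- collect_clip_support(reads, cl$chromA, cl$startA, cl$endA, cfg)
    clipsB <- collect_clip_support(reads, cl$chromB, cl$startB, cl$endB, cfg)
    refine_breakpoint(cl, clipsA, clipsB)
  })
  calls <- filter_events(calls, blacklist, ig_loci, cfg)
  arrange(calls, .data$chromA, .data$posA, .data$chromB, .data$posB)
}

empty_call_tbl <- function() {
  tibble(chromA = character(), posA = integer(), chromB = character(),
         posB = integer(), n_pairs = integer(), n_clip_A = integer(),
         n_clip_B = integer(), consensus_clip_A = character(),
         consensus_clip_B = character(), clip_seqs_A = list(),
         clip_seqs_B = list(), resolution = character(),
         status = character(), filter_reason = character())
}
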