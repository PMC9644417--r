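#' Parse an immunoglobulin segment reference FASTA
#'
#' Reads germline V/J/C gene segments from a FASTA file and returns one
#' record per parseable entry. Two header dialects are supported:
#'
#' * `"simple"` — `>gene|class|locus|functionality`, e.g.
#'   `>IGHV3-30*01|V|IGH|functional`. The canonical fixture format.
#' * `"imgt_header"` — pipe-delimited IMGT-style headers where field 2 is
#'   the allele name (e.g. `IGHV3-30*01`) and field 4 the functionality
#'   code (`F`, `P`, `ORF`, possibly parenthesised). Segment class and
#'   locus are derived from the allele name.
#'
#' Entries whose headers cannot be parsed under the chosen dialect are
#' skipped; the number skipped is attached as attribute `n_skipped` and
#' reported via a message.
#'
#' @param path Path to a FASTA file.
#' @param dialect Header dialect, `"simple"` or `"imgt_header"`.
#' @return A tibble of segment records with columns `gene_name`, `allele`,
#'   `segment_class` (V/J/C), `locus` (IGH/IGK/IGL), `functionality`,
#'   `sequence`, and optional genomic coordinates `chrom`, `start`, `end`,
#'   `strand` (NA when absent); attribute `n_skipped` counts rejected
#'   headers.
#' @export
parse_segment_fasta <- function(path, dialect = c("simple", "imgt_header")) {
  dialect <- match.arg(dialect)
  stop_if(!file.exists(path), "segment FASTA not found: %s", path)
  seqs <- Biostrings::readBStringSet(path)
  stop_if(length(seqs) == 0L, "segment FASTA is empty: %s", path)

  headers <- names(seqs)
  sequences <- unname(toupper(as.character(seqs)))
  bad <- grepl("[^ACGTN]", sequences)
  stop_if(any(bad), "non-nucleotide characters in record '%s'",
          headers[which(bad)[1]])

  parse_one <- if (dialect == "simple") parse_simple_header else parse_imgt_header
  parsed <- lapply(headers, parse_one)
  keep <- !vapply(parsed, is.null, logical(1))
  n_skipped <- sum(!keep)
  if (n_skipped > 0) {
    message(sprintf("parse_segment_fasta: skipped %d unparseable header(s)",
                    n_skipped))
  }
  recs <- bind_rows(parsed[keep])
  if (nrow(recs) > 0) {
    recs$sequence <- sequences[keep]
    empty <- !nzchar(recs$sequence)
    stop_if(any(empty), "empty sequence in record '%s'", headers[keep][which(empty)[1]])
    ok_locus <- substr(recs$gene_name, 1, 3) == recs$locus
    stop_if(any(!ok_locus), "locus inconsistent with gene name in record '%s'",
            recs$allele[which(!ok_locus)[1]])
  } else {
    recs <- empty_segment_tbl()
  }
  attr(recs, "n_skipped") <- n_skipped
  recs
}

empty_segment_tbl <- function() {
  tibble(gene_name = character(), allele = character(),
         segment_class = character(), locus = character(),
         functionality = character(), sequence = character(),
         chrom = character(), start = integer(), end = integer(),
         strand = character())
}

segment_class_from_gene <- function(gene) {
  ifelse(grepl("^IG[HKL]V", gene), "V",
         ifelse(grepl("^IG[HKL]J", gene), "J", "C"))
}

parse_simple_header <- function(h) {
  f <- strsplit(h, "|", fixed = TRUE)[[1]]
  if (length(f) != 4L) return(NULL)
  gene <- sub("\\*.*$", "", f[1])
  if (!grepl("^IG[HKL]", gene)) return(NULL)
  if (!f[2] %in% c("V", "J", "C")) return(NULL)
  if (!f[3] %in% c("IGH", "IGK", "IGL")) return(NULL)
  if (!f[4] %in% c("functional", "pseudogene", "ORF")) return(NULL)
  tibble(gene_name = gene, allele = f[1], segment_class = f[2],
         locus = f[3], functionality = f[4],
         chrom = NA_character_, start = NA_integer_, end = NA_integer_,
         strand = NA_character_)
}

parse_imgt_header <- function(h) {
  f <- strsplit(h, "|", fixed = TRUE)[[1]]
  if (length(f) < 4L) return(NULL)
  allele <- trimws(f[2])
  gene <- sub("\\*.*$", "", allele)
  if (!grepl("^IG[HKL]", gene)) return(NULL)
  func_raw <- gsub("[][()]", "", trimws(f[4]))
  func <- switch(func_raw,
                 "F" = "functional", "functional" = "functional",
                 "P" = "pseudogene", "pseudogene" = "pseudogene",
                 "ORF" = "ORF", NULL)
  if (is.null(func)) return(NULL)
  tibble(gene_name = gene, allele = allele,
         segment_class = segment_class_from_gene(gene),
         locus = substr(gene, 1, 3), functionality = func,
         chrom = NA_character_, start = NA_integer_, end = NA_integer_,
         strand = NA_character_)
}

#' Design capture probes from gene segments
#'
#' Derives single-stranded capture probes from parsed segments, in segment
#' (coding) orientation: V segments yield a probe over the last
#' `probe_len` bases (3' end, to capture fragments crossing the V(D)J
#' junction), J segments the first `probe_len` bases (5' end), and C
#' segments whole-exon probes (the full sequence when it fits in one probe,
#' otherwise `probe_len` tiles anchored at the 5' end; a final partial tile
#' is kept when at least `min_segment_len` long). Segments shorter than
#' `min_segment_len` are skipped with a warning; segments shorter than
#' `probe_len` yield a full-length probe. Probes identical in sequence are
#' deduplicated, keeping the lexicographically smallest `probe_id`.
#'
#' @param segments Tibble from [parse_segment_fasta()].
#' @param cfg A [probe_config()].
#' @return Tibble of probes: `probe_id`, `source` (allele), `anchored_end`
#'   (`three_prime`/`five_prime`/`exon`), `sequence`, `length`.
#' @export
design_probes <- function(segments, cfg = probe_config()) {
  if (nrow(segments) == 0L) return(empty_probe_tbl())
  short <- nchar(segments$sequence) < cfg$min_segment_len
  if (any(short)) {
    warning(sprintf("design_probes: skipped %d segment(s) shorter than %d nt",
                    sum(short), cfg$min_segment_len), call. = FALSE)
    segments <- segments[!short, , drop = FALSE]
  }
  if (nrow(segments) == 0L) return(empty_probe_tbl())

  rows <- purrr::pmap(
    list(segments$allele, segments$segment_class, segments$sequence),
    function(allele, cls, seq) {
      len <- nchar(seq)
      if (cls == "V") {
        p <- substr(seq, max(1L, len - cfg$probe_len + 1L), len)
        tibble(probe_id = paste0(allele, "_3p"), source = allele,
               anchored_end = "three_prime", sequence = p)
      } else if (cls == "J") {
        p <- substr(seq, 1L, min(cfg$probe_len, len))
        tibble(probe_id = paste0(allele, "_5p"), source = allele,
               anchored_end = "five_prime", sequence = p)
      } else {
        if (len <= cfg$probe_len) {
          tibble(probe_id = paste0(allele, "_ex1"), source = allele,
                 anchored_end = "exon", sequence = seq)
        } else {
          starts <- seq.int(1L, len, by = cfg$probe_len)
          tiles <- substring(seq, starts, pmin(starts + cfg$probe_len - 1L, len))
          keep <- nchar(tiles) >= cfg$min_segment_len
          tibble(probe_id = paste0(allele, "_ex", seq_along(starts))[keep],
                 source = allele, anchored_end = "exon",
                 sequence = tiles[keep])
        }
      }
    })
  probes <- bind_rows(rows)
  probes$length <- nchar(probes$sequence)
  probes |>
    arrange(.data$probe_id) |>
    group_by(.data$sequence) |>
    slice(1L) |>
    ungroup() |>
    arrange(.data$probe_id) |>
    select("probe_id", "source", "anchored_end", "sequence", "length")
}

empty_probe_tbl <- function() {
  tibble(probe_id = character(), source = character(),
         anchored_end = character(), sequence = character(),
         length = integer())
}

#' Screen probes for cross-hybridization promiscuity
#'
#' Flags probes predicted to hybridize promiscuously: a probe is flagged
#' when more than `promiscuity_max_hits` other probes share at least one
#' exact k-mer (`promiscuity_k`) with it. Deterministic;
#' `kept` and `flagged` partition the input.
#'
#' @param probes Tibble from [design_probes()].
#' @param cfg A [probe_config()].
#' @return `list(kept =, flagged =)` of probe tibbles.
#' @export
screen_promiscuity <- function(probes, cfg = probe_config()) {
  n <- nrow(probes)
  if (n == 0L || is.infinite(cfg$promiscuity_max_hits)) {
    return(list(kept = probes, flagged = probes[0, , drop = FALSE]))
  }
  k <- cfg$promiscuity_k
  kmer_sets <- lapply(probes$sequence, function(s) {
    len <- nchar(s)
    if (len < k) return(character(0))
    unique(substring(s, 1:(len - k + 1L), k:len))
  })
  # invert: k-mer -> probe indices
  idx <- rep.int(seq_len(n), lengths(kmer_sets))
  km <- unlist(kmer_sets, use.names = FALSE)
  by_kmer <- split(idx, km)
  hits <- lapply(seq_len(n), function(i) integer(0))
  for (grp in by_kmer) {
    if (length(grp) > 1L) {
      for (i in grp) hits[[i]] <- c(hits[[i]], setdiff(grp, i))
    }
  }
  n_hits <- vapply(hits, function(h) length(unique(h)), integer(1))
  flag <- n_hits > cfg$promiscuity_max_hits
  list(kept = probes[!flag, , drop = FALSE],
       flagged = probes[flag, , drop = FALSE])
}

#' Write and read probe FASTA
#'
#' Probes are written as `>probe_id|source|anchored_end` records so that a
#' probe panel round-trips through FASTA byte-identically.
#'
#' @param probes Tibble from [design_probes()].
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_probe_fasta <- function(probes, path) {
  x <- Biostrings::DNAStringSet(probes$sequence)
  names(x) <- paste(probes$probe_id, probes$source, probes$anchored_end,
                    sep = "|")
  Biostrings::writeXStringSet(x, path, width = 80L)
  invisible(path)
}

#' Probe genomic intervals as BED
#'
#' For probes whose source segment carries genomic coordinates, computes
#' the probe's genomic footprint (0-based half-open). Probes are emitted in
#' segment orientation, so a 3'-anchored probe on a `-`-strand gene maps to
#' the start of its genomic interval. Segments without coordinates are
#' skipped.
#'
#' @param probes Tibble from [design_probes()].
#' @param segments Tibble from [parse_segment_fasta()] with `chrom`,
#'   `start`, `end`, `strand` filled for at least some records (0-based
#'   half-open, like all BED in this package).
#' @return Tibble `chrom`, `start`, `end`, `name` suitable for BED export.
#' @export
probe_bed <- function(probes, segments) {
  d <- dplyr::left_join(probes, segments, by = c(source = "allele"))
  d <- d[!is.na(d$chrom), , drop = FALSE]
  if (nrow(d) == 0L) {
    return(tibble(chrom = character(), start = integer(), end = integer(),
                  name = character()))
  }
  at_three_prime <- (d$anchored_end == "three_prime") != (d$strand == "-")
  start <- ifelse(at_three_prime, d$end - d$length, d$start)
  tibble(chrom = d$chrom, start = as.integer(start),
         end = as.integer(start + d$length), name = d$probe_id) |>
    arrange(.data$chrom, .data$start)
}

#' @rdname write_probe_fasta
#' @export
parse_probe_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  f <- stringr::str_split_fixed(names(seqs), stringr::fixed("|"), 3)
  s <- unname(as.character(seqs))
  tibble(probe_id = f[, 1], source = f[, 2], anchored_end = f[, 3],
         sequence = s, length = nchar(s))
}
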