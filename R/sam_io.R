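#' Aligned-read I/O
#'
#' The package-internal representation of aligned paired-end reads is a
#' tibble with one row per primary alignment record, 1-based leftmost
#' positions (SAM convention), and soft-clipped prefix/suffix sequences
#' pre-extracted from the CIGAR. [read_alignments()] builds it from a SAM
#' or BAM file (SAM text is converted through `Rsamtools::asBam()`, which
#' also coordinate-sorts); [write_alignments()] writes it back out. All BED
#' output elsewhere in the package is 0-based half-open; conversions happen
#' only at the I/O boundary.
#'
#' @name sam-io
NULL

cigar_clip_lens <- function(cigar) {
  pre <- suppressWarnings(as.integer(stringr::str_match(cigar, "^(\\d+)S")[, 2]))
  suf <- suppressWarnings(as.integer(stringr::str_match(cigar, "(\\d+)S$")[, 2]))
  list(prefix = ifelse(is.na(pre), 0L, pre),
       suffix = ifelse(is.na(suf), 0L, suf))
}

cigar_ref_len <- function(cigar) {
  ops <- stringr::str_match_all(cigar, "(\\d+)([MIDNSHP=X])")
  vapply(ops, function(m) {
    if (nrow(m) == 0L) return(0L)
    sum(as.integer(m[, 2])[m[, 3] %in% c("M", "D", "N", "=", "X")])
  }, integer(1))
}

#' @describeIn sam-io Read a SAM or BAM file into the aligned-read tibble.
#' @param path Path to a `.sam` or `.bam` file (SAM is converted and sorted
#'   on the fly).
#' @return A tibble with columns `qname`, `chrom`, `pos`, `strand`, `mapq`,
#'   `cigar`, `seq`, `mean_baseq`, `mate_chrom`, `mate_pos`, `insert_size`,
#'   `is_first`, `is_proper`, `is_duplicate`, `nm`, `clipped_prefix`,
#'   `clipped_suffix`, `read_len`, coordinate-sorted.
#' @export
read_alignments <- function(path) {
  stop_if(!file.exists(path), "alignment file not found: %s", path)
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    bam <- Rsamtools::asBam(path, destination = dest, overwrite = TRUE,
                            indexDestination = TRUE)
  }
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "mapq", "cigar", "mrnm",
             "mpos", "isize", "seq", "qual"),
    tag = "NM")
  x <- Rsamtools::scanBam(bam, param = p)[[1]]
  n <- length(x$qname)
  if (n == 0L) return(empty_read_tbl())
  flag <- x$flag
  seqs <- as.character(x$seq)
  quals <- as(x$qual, "IntegerList")
  nm <- x$tag$NM %||% rep(0L, n)
  nm[is.na(nm)] <- 0L
  cl <- cigar_clip_lens(x$cigar)
  rl <- nchar(seqs)
  tibble(
    qname = x$qname,
    chrom = as.character(x$rname),
    pos = x$pos,
    strand = ifelse(bitwAnd(flag, 16L) > 0L, "-", "+"),
    mapq = as.integer(x$mapq),
    cigar = x$cigar,
    seq = seqs,
    mean_baseq = as.numeric(sum(quals)) / pmax(1L, lengths(quals)),
    mate_chrom = as.character(x$mrnm),
    mate_pos = x$mpos,
    mate_strand = ifelse(bitwAnd(flag, 32L) > 0L, "-", "+"),
    insert_size = abs(as.integer(x$isize)),
    is_first = bitwAnd(flag, 64L) > 0L,
    is_proper = bitwAnd(flag, 2L) > 0L,
    is_duplicate = bitwAnd(flag, 1024L) > 0L,
    nm = as.integer(nm),
    clipped_prefix = substr(seqs, 1L, cl$prefix),
    clipped_suffix = substr(seqs, rl - cl$suffix + 1L, rl),
    read_len = rl
  )
}

empty_read_tbl <- function() {
  tibble(qname = character(), chrom = character(), pos = integer(),
         strand = character(), mapq = integer(), cigar = character(),
         seq = character(), mean_baseq = numeric(),
         mate_chrom = character(), mate_pos = integer(),
         mate_strand = character(),
         insert_size = integer(), is_first = logical(),
         is_proper = logical(), is_duplicate = logical(), nm = integer(),
         clipped_prefix = character(), clipped_suffix = character(),
         read_len = integer())
}

#' @describeIn sam-io Write the aligned-read tibble to SAM (or BAM when
#'   `path` ends in `.bam`). Records are coordinate-sorted on output;
#'   a BAM destination is also indexed.
#' @param reads Aligned-read tibble.
#' @param ref_lengths Named integer vector of chromosome lengths for the
#'   `@SQ` header lines.
#' @export
write_alignments <- function(reads, ref_lengths, path) {
  want_bam <- grepl("\\.bam$", path, ignore.case = TRUE)
  sam_path <- if (want_bam) tempfile(fileext = ".sam") else path
  ord <- order(match(reads$chrom, names(ref_lengths)), reads$pos)
  reads <- reads[ord, , drop = FALSE]

  flag <- 1L +
    ifelse(reads$is_proper, 2L, 0L) +
    ifelse(reads$strand == "-", 16L, 0L) +
    ifelse(reads$mate_strand == "-", 32L, 0L) +
    ifelse(reads$is_first, 64L, 128L) +
    ifelse(reads$is_duplicate, 1024L, 0L)
  rnext <- ifelse(reads$mate_chrom == reads$chrom, "=", reads$mate_chrom)
  tlen <- ifelse(reads$chrom != reads$mate_chrom, 0L,
                 ifelse(reads$pos < reads$mate_pos |
                          (reads$pos == reads$mate_pos & reads$is_first),
                        reads$insert_size, -reads$insert_size))
  qual <- vapply(seq_len(nrow(reads)), function(i) {
    strrep(rawToChar(as.raw(33L + as.integer(round(reads$mean_baseq[i])))),
           reads$read_len[i])
  }, character(1))

  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           sprintf("@SQ\tSN:%s\tLN:%d", names(ref_lengths),
                   as.integer(ref_lengths)))
  rec <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t%s\t%d\t%d\t%s\t%s\tNM:i:%d",
                 reads$qname, flag, reads$chrom, reads$pos, reads$mapq,
                 reads$cigar, rnext, reads$mate_pos, tlen, reads$seq, qual,
                 reads$nm)
  writeLines(c(hdr, rec), sam_path)
  if (want_bam) {
    Rsamtools::asBam(sam_path, destination = sub("\\.bam$", "", path),
                     overwrite = TRUE, indexDestination = TRUE)
  }
  invisible(path)
}
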