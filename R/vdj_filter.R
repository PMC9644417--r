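#' Load a MiXCR-style clone table
#'
#' Reads a clone-export TSV into the package's clone-record representation.
#' Column names follow the MiXCR export convention by default and can be
#' remapped via `col_map`. The locus is inferred from the V-gene prefix
#' (IGH/IGK/IGL). Rows with unparsable counts are rejected with their row
#' numbers; the number rejected is attached as attribute `n_rejected`.
#'
#' @param path Path to a TSV file (or a data frame already read).
#' @param sample_id Sample identifier attached to every record (defaults to
#'   the file base name).
#' @param col_map Named list mapping the roles `count`, `fraction`, `v`,
#'   `d`, `j`, `cdr3_nt`, `cdr3_aa` to column names in the file.
#' @return Tibble of clone records: `sample_id`, `locus`, `v_gene`,
#'   `d_gene`, `j_gene`, `cdr3_nt`, `cdr3_aa`, `clone_count`,
#'   `clone_fraction`.
#' @export
load_clone_table <- function(path, sample_id = NULL, col_map = list()) {
  cm <- utils::modifyList(
    list(count = "cloneCount", fraction = "cloneFraction",
         v = "allVHitsWithScore", d = "allDHitsWithScore",
         j = "allJHitsWithScore", cdr3_nt = "nSeqCDR3",
         cdr3_aa = "aaSeqCDR3"),
    col_map)
  if (is.character(path)) {
    stop_if(!file.exists(path), "clone table not found: %s", path)
    if (is.null(sample_id)) {
      sample_id <- sub("\\.[^.]*$", "", basename(path))
    }
    d <- read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                    check.names = FALSE, colClasses = "character")
  } else {
    d <- as.data.frame(path, stringsAsFactors = FALSE)
    if (is.null(sample_id)) sample_id <- "sample"
  }
  for (role in c("count", "fraction", "v", "j", "cdr3_nt")) {
    stop_if(!(cm[[role]] %in% names(d)),
            "clone table is missing mandatory column '%s'", cm[[role]])
  }
  if (nrow(d) == 0L) {
    out <- empty_clone_tbl()
    attr(out, "n_rejected") <- 0L
    return(out)
  }
  cnt <- suppressWarnings(as.numeric(as.character(d[[cm$count]])))
  frac <- suppressWarnings(as.numeric(as.character(d[[cm$fraction]])))
  bad <- is.na(cnt) | cnt < 1
  if (any(bad)) {
    message(sprintf("load_clone_table: rejected rows with unparsable counts: %s",
                    paste(which(bad), collapse = ", ")))
  }
  strip_hit <- function(x) sub("\\*.*$", "", sub("\\(.*$", "", as.character(x)))
  v <- strip_hit(d[[cm$v]])
  locus <- substr(v, 1, 3)
  stop_if(any(!bad & !locus %in% c("IGH", "IGK", "IGL")),
          "cannot infer locus from V gene '%s'",
          v[which(!bad & !locus %in% c("IGH", "IGK", "IGL"))[1]])
  out <- tibble(
    sample_id = sample_id, locus = locus, v_gene = v,
    d_gene = if (cm$d %in% names(d)) strip_hit(d[[cm$d]]) else "",
    j_gene = strip_hit(d[[cm$j]]),
    cdr3_nt = toupper(as.character(d[[cm$cdr3_nt]])),
    cdr3_aa = if (cm$cdr3_aa %in% names(d)) as.character(d[[cm$cdr3_aa]]) else "",
    clone_count = as.integer(cnt), clone_fraction = frac
  )[!bad, , drop = FALSE]
  stop_if(any(!nzchar(out$cdr3_nt)), "empty CDR3 sequence in clone table")
  attr(out, "n_rejected") <- sum(bad)
  out
}

empty_clone_tbl <- function() {
  tibble(sample_id = character(), locus = character(), v_gene = character(),
         d_gene = character(), j_gene = character(), cdr3_nt = character(),
         cdr3_aa = character(), clone_count = integer(),
         clone_fraction = numeric())
}

#' V(D)J clonotype filters
#'
#' The candidate-filtering algorithm for MiXCR-style clone tables, applied
#' in a fixed order by [call_candidates()]:
#' pseudogene removal, per-locus fraction recomputation, clonal-fraction
#' filter (strict `> min_fraction`), cohort-specificity filter (keep when
#' the CDR3 sequence occurs in at most `max_cohort_occurrences` samples of
#' the cohort's candidate lists), and absolute-count filter (strict `>`,
#' 50 for cell lines / 10 for patient samples).
#'
#' @param clones Clone tibble (see [load_clone_table()]).
#' @param pseudogene_names Character vector of gene names treated as
#'   pseudogenes; clones whose V or J gene is in the set are dropped.
#' @param cfg A [filter_config()].
#' @param index Cohort index from [build_cohort_index()].
#' @name vdj-filters
NULL

#' @describeIn vdj-filters Drop clones whose V or J gene is a pseudogene.
#'   The number removed is attached as attribute `n_removed`.
#' @export
remove_pseudogenes <- function(clones, pseudogene_names = character()) {
  drop <- clones$v_gene %in% pseudogene_names |
    clones$j_gene %in% pseudogene_names
  out <- clones[!drop, , drop = FALSE]
  attr(out, "n_removed") <- sum(drop)
  out
}

#' @describeIn vdj-filters Recompute `clone_fraction` as the clone's share
#'   of total clone counts at the same (sample, locus); per-group fractions
#'   sum to 1.
#' @export
recompute_locus_fractions <- function(clones) {
  if (nrow(clones) == 0L) return(clones)
  clones |>
    group_by(.data$sample_id, .data$locus) |>
    mutate(clone_fraction = .data$clone_count / sum(.data$clone_count)) |>
    ungroup()
}

#' @describeIn vdj-filters Keep clones with `clone_fraction > min_fraction`
#'   (strict).
#' @export
filter_by_fraction <- function(clones, cfg = filter_config()) {
  clones[clones$clone_fraction > cfg$min_fraction, , drop = FALSE]
}

#' @describeIn vdj-filters Build the cohort occurrence index over
#'   per-sample candidate lists: exact CDR3 nucleotide identity, occurrence
#'   = number of distinct samples carrying the sequence (replicate samples
#'   from one donor are not collapsed).
#' @param candidate_lists List of per-sample clone tibbles (or one combined
#'   tibble with a `sample_id` column).
#' @export
build_cohort_index <- function(candidate_lists) {
  combined <- if (is.data.frame(candidate_lists)) candidate_lists
  else bind_rows(candidate_lists)
  if (nrow(combined) == 0L) {
    return(tibble(cdr3_nt = character(), occurrence = integer()))
  }
  combined |>
    distinct(.data$cdr3_nt, .data$sample_id) |>
    dplyr::count(.data$cdr3_nt, name = "occurrence") |>
    arrange(.data$cdr3_nt)
}

#' @describeIn vdj-filters Keep clones whose cohort occurrence is at most
#'   `max_cohort_occurrences` (inclusive). Sequences absent from the index
#'   count as occurrence 0.
#' @export
filter_by_specificity <- function(clones, index, cfg = filter_config()) {
  if (nrow(clones) == 0L) return(clones)
  occ <- index$occurrence[match(clones$cdr3_nt, index$cdr3_nt)]
  occ[is.na(occ)] <- 0L
  clones[occ <= cfg$max_cohort_occurrences, , drop = FALSE]
}

#' @describeIn vdj-filters Keep clones with `clone_count` strictly above
#'   the mode's threshold (cell_line: 50; patient: 10).
#' @export
filter_by_count <- function(clones, cfg = filter_config()) {
  clones[clones$clone_count > min_count_threshold(cfg), , drop = FALSE]
}

#' Run the full clonotype filtering pipeline over a cohort
#'
#' Applies the filters in fixed order: pseudogene removal, per-locus
#' fraction recomputation, clonal-fraction filter, cohort index +
#' specificity filter (occurrences counted among the post-fraction-filter
#' candidates), and absolute-count filter. Output per sample is
#' stable-sorted by decreasing count then CDR3 sequence, so the result is
#' invariant to input row order.
#'
#' @param cohort Named list of per-sample clone tibbles.
#' @param cfg A [filter_config()].
#' @param pseudogene_names Pseudogene name set (possibly empty).
#' @return `list(candidates = named list of surviving clone tibbles,
#'   audit = tibble of per-sample, per-stage drop counts)`.
#' @export
call_candidates <- function(cohort, cfg = filter_config(),
                            pseudogene_names = character()) {
  if (is.null(names(cohort))) {
    names(cohort) <- sprintf("sample%02d", seq_along(cohort))
  }
  stage1 <- lapply(cohort, function(cl) {
    cl |>
      remove_pseudogenes(pseudogene_names) |>
      recompute_locus_fractions() |>
      filter_by_fraction(cfg)
  })
  index <- build_cohort_index(stage1)
  candidates <- lapply(stage1, function(cl) {
    cl |>
      filter_by_specificity(index, cfg) |>
      filter_by_count(cfg) |>
      arrange(dplyr::desc(.data$clone_count), .data$cdr3_nt)
  })
  audit <- purrr::map_dfr(names(cohort), function(sid) {
    n0 <- nrow(cohort[[sid]])
    after_pseudo <- remove_pseudogenes(cohort[[sid]], pseudogene_names)
    n1 <- nrow(after_pseudo)
    n2 <- nrow(stage1[[sid]])
    after_spec <- filter_by_specificity(stage1[[sid]], index, cfg)
    n3 <- nrow(after_spec)
    n4 <- nrow(candidates[[sid]])
    tibble(sample_id = as.character(sid), n_input = n0,
           dropped_pseudogene = n0 - n1, dropped_fraction = n1 - n2,
           dropped_specificity = n2 - n3, dropped_count = n3 - n4,
           n_candidates = n4)
  })
  list(candidates = candidates, audit = audit)
}
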