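#' Clip-sequence concordance
#'
#' Two junction-anchored clipped sequences are concordant when they agree
#' exactly over their overlapping prefix (both sequences are read away from
#' the junction, so the overlap is anchored at the junction) and that
#' overlap is at least `min_overlap` nt. No mismatches are tolerated.
#'
#' @param a,b Clipped sequences (junction-anchored).
#' @param min_overlap Minimum overlap length (default 10 nt).
#' @return Logical flag.
#' @export
seqs_concordant <- function(a, b, min_overlap = 10L) {
  n <- min(nchar(a), nchar(b))
  n >= min_overlap && substr(a, 1L, n) == substr(b, 1L, n)
}

# size of the largest mutually concordant clip group
concordant_count <- function(seqs, min_overlap = 10L) {
  k <- length(seqs)
  if (k == 0L) return(0L)
  best <- 1L
  for (i in seq_len(k)) {
    grp <- 1L
    for (j in seq_len(k)) {
      if (j != i && seqs_concordant(seqs[i], seqs[j], min_overlap)) {
        grp <- grp + 1L
      }
    }
    best <- max(best, grp)
  }
  best
}

any_concordant_with <- function(seqs, ref_seqs, min_overlap = 10L) {
  for (a in seqs) for (b in ref_seqs) {
    if (seqs_concordant(a, b, min_overlap)) return(TRUE)
  }
  FALSE
}

#' Assemble partner evidence
#'
#' @param clip_seqs Character vector of non-duplicate, junction-anchored
#'   clipped sequences observed at one rearrangement partner.
#' @param coverage_drop Optional heuristic flag; reported but not used in
#'   the confirmation logic.
#' @return A `partner_evidence` list.
#' @export
partner_evidence <- function(clip_seqs = character(),
                             coverage_drop = NA) {
  structure(list(clip_seqs = as.character(clip_seqs),
                 n_nondup_clips = length(clip_seqs),
                 coverage_drop = coverage_drop),
            class = "partner_evidence")
}

#' Classify a candidate rearrangement by the manual-review rules
#'
#' Deterministic encoding of the confirmation rules used in manual review
#' of candidate rearrangements:
#'
#' 1. `confirmed` when there are at least two mutually concordant
#'    non-duplicate clipped reads at *both* rearrangement partners.
#' 2. Otherwise `confirmed` when a paired sample (matched targeted or WGS
#'    run) is available, each partner has at least one clip concordant
#'    with the paired sample's clips at that partner, and the paired
#'    sample has at least five non-duplicate clipped reads at one partner.
#' 3. Otherwise `equivocal` when there is any clip evidence anywhere
#'    (single reads are suggestive but not definitive on their own).
#' 4. Otherwise `absent`.
#'
#' @param partnerA,partnerB [partner_evidence()] for the two partners.
#' @param paired Optional `list(partnerA =, partnerB =)` of
#'   [partner_evidence()] from a matched sample.
#' @param min_overlap Concordance overlap (default 10 nt).
#' @return `list(status = "confirmed"|"equivocal"|"absent", rule_fired =)`.
#' @export
verify_event <- function(partnerA, partnerB, paired = NULL,
                         min_overlap = 10L) {
  ccA <- concordant_count(partnerA$clip_seqs, min_overlap)
  ccB <- concordant_count(partnerB$clip_seqs, min_overlap)
  if (ccA >= 2L && ccB >= 2L) {
    return(list(status = "confirmed", rule_fired = "two_concordant_both_partners"))
  }
  if (!is.null(paired)) {
    paired_max <- max(paired$partnerA$n_nondup_clips,
                      paired$partnerB$n_nondup_clips)
    if (partnerA$n_nondup_clips >= 1L && partnerB$n_nondup_clips >= 1L &&
        paired_max >= 5L &&
        any_concordant_with(partnerA$clip_seqs, paired$partnerA$clip_seqs,
                            min_overlap) &&
        any_concordant_with(partnerB$clip_seqs, paired$partnerB$clip_seqs,
                            min_overlap)) {
      return(list(status = "confirmed", rule_fired = "paired_sample_support"))
    }
  }
  if (partnerA$n_nondup_clips + partnerB$n_nondup_clips >= 1L) {
    return(list(status = "equivocal", rule_fired = "single_read_not_definitive"))
  }
  list(status = "absent", rule_fired = "no_evidence")
}

#' Verify a batch of translocation calls
#'
#' Applies [verify_event()] to every non-filtered call, using the stored
#' junction-anchored clip sequences as partner evidence. When a paired
#' call set is supplied, each call is matched to a paired call by
#' breakpoint proximity (both breakpoints within `tol` bp) and the paired
#' sample's clips feed the second confirmation rule. Filtered calls keep
#' their status.
#'
#' @param calls Call tibble from [call_translocations()].
#' @param paired Optional call tibble from a matched sample.
#' @param tol Breakpoint match tolerance in bp (default 10).
#' @param min_overlap Concordance overlap (default 10 nt).
#' @return The call tibble with `status` / `filter_reason` updated and a
#'   `summary` attribute counting confirmed / equivocal / absent calls.
#' @export
verify_batch <- function(calls, paired = NULL, tol = 10L, min_overlap = 10L) {
  if (nrow(calls) == 0L) {
    attr(calls, "summary") <- c(confirmed = 0L, equivocal = 0L, absent = 0L)
    return(calls)
  }
  for (i in seq_len(nrow(calls))) {
    if (calls$status[i] == "filtered") next
    pa <- partner_evidence(calls$clip_seqs_A[[i]])
    pb <- partner_evidence(calls$clip_seqs_B[[i]])
    pev <- NULL
    if (!is.null(paired) && nrow(paired) > 0L) {
      hit <- which(paired$chromA == calls$chromA[i] &
                     paired$chromB == calls$chromB[i] &
                     abs(paired$posA - calls$posA[i]) <= tol &
                     abs(paired$posB - calls$posB[i]) <= tol)
      if (length(hit) > 0L) {
        h <- hit[1L]
        pev <- list(partnerA = partner_evidence(paired$clip_seqs_A[[h]]),
                    partnerB = partner_evidence(paired$clip_seqs_B[[h]]))
      }
    }
    res <- verify_event(pa, pb, pev, min_overlap)
    calls$status[i] <- res$status
    calls$filter_reason[i] <- res$rule_fired
  }
  attr(calls, "summary") <- c(
    confirmed = sum(calls$status == "confirmed"),
    equivocal = sum(calls$status == "equivocal"),
    absent = sum(calls$status == "absent"))
  calls
}
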