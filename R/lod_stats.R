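#' Sensitivity with a Wald confidence interval
#'
#' Detection sensitivity reported the way the assay's validation tables
#' print it: the point estimate is `detected / total` rounded to two
#' decimals, the margin is the Wald normal approximation
#' `z * sqrt(p(1 - p) / total)` computed from the rounded point estimate,
#' and the bounds are rounded to two decimals but *not* truncated to
#' \[0, 1\] (small denominators can print bounds like -0.19 or 1.19).
#'
#' @param detected Number of positives detected.
#' @param total Number of known positives assayed (>= 1).
#' @param z Normal quantile (default 1.96 for 95%).
#' @return A one-row tibble: `detected`, `total`, `point`, `ci_low`,
#'   `ci_high`, `z`.
#' @export
sensitivity_ci <- function(detected, total, z = 1.96) {
  stop_if(length(total) != 1L || is.na(total) || total < 1,
          "total must be a positive count")
  stop_if(detected < 0 || detected > total,
          "detected must lie in [0, total]")
  p <- round(detected / total, 2)
  margin <- z * sqrt(p * (1 - p) / total)
  tibble(detected = as.integer(detected), total = as.integer(total),
         point = p, ci_low = round(p - margin, 2),
         ci_high = round(p + margin, 2), z = z)
}

#' Aggregate detection rate over marker families
#'
#' Pools per-family (detected, total) counts into one overall detection
#' fraction, `sum(detected) / sum(total)`; invariant to family order and
#' to splitting or merging families with the same totals.
#'
#' @param family_counts List of `c(detected, total)` pairs (or a 2-column
#'   matrix / data frame).
#' @return The pooled detection fraction.
#' @export
aggregate_detection <- function(family_counts) {
  if (is.data.frame(family_counts) || is.matrix(family_counts)) {
    m <- as.matrix(family_counts)
  } else {
    m <- do.call(rbind, family_counts)
  }
  stop_if(ncol(m) != 2L, "family_counts must be (detected, total) pairs")
  sum(m[, 1]) / sum(m[, 2])
}

match_breakpoint <- function(calls, chromA, posA, chromB, posB, tol = 10L,
                             statuses = c("confirmed", "equivocal")) {
  if (is.null(calls) || nrow(calls) == 0L) return(FALSE)
  ok <- calls$status %in% statuses &
    ((calls$chromA == chromA & calls$chromB == chromB &
        abs(calls$posA - posA) <= tol & abs(calls$posB - posB) <= tol) |
       (calls$chromA == chromB & calls$chromB == chromA &
          abs(calls$posA - posB) <= tol & abs(calls$posB - posA) <= tol))
  any(ok)
}

#' Build a marker-by-condition detection matrix
#'
#' Scores a set of tracked markers (translocation breakpoints and/or V(D)J
#' clonotypes) against the verified outputs of several conditions
#' (dilutions or timepoints). A translocation marker is detected in a
#' condition when a verified call (status in `statuses`) matches both
#' breakpoints within `tol` bp; a clonotype marker when a candidate clone
#' has the identical CDR3 nucleotide sequence. A marker is `not_assayed`
#' in conditions lacking the relevant input.
#'
#' @param calls_by_condition Named list; each element is
#'   `list(calls = call tibble or NULL, clones = candidate clone tibble or
#'   NULL)`.
#' @param markers Tibble with `marker_id`, `class`
#'   (`"translocation"`/`"vdj"`), and either `chromA`, `posA`, `chromB`,
#'   `posB` or `cdr3_nt`.
#' @param tol Breakpoint tolerance in bp (default 10).
#' @param statuses Call statuses that count as detected (default confirmed
#'   and equivocal).
#' @return Tibble with one row per marker and one `detected`/
#'   `not_detected`/`not_assayed` column per condition, ordered by marker
#'   then condition.
#' @export
detection_matrix <- function(calls_by_condition, markers, tol = 10L,
                             statuses = c("confirmed", "equivocal")) {
  conds <- names(calls_by_condition)
  out <- markers["marker_id"]
  for (cond in conds) {
    inp <- calls_by_condition[[cond]]
    out[[cond]] <- vapply(seq_len(nrow(markers)), function(i) {
      m <- markers[i, ]
      if (m$class == "translocation") {
        if (is.null(inp$calls)) return("not_assayed")
        det <- match_breakpoint(inp$calls, m$chromA, m$posA, m$chromB,
                                m$posB, tol, statuses)
      } else {
        if (is.null(inp$clones)) return("not_assayed")
        det <- nrow(inp$clones) > 0L && m$cdr3_nt %in% inp$clones$cdr3_nt
      }
      if (det) "detected" else "not_detected"
    }, character(1))
  }
  arrange(out, .data$marker_id)
}

#' Most dilute condition with a detection
#'
#' @param row_statuses Character vector of cell statuses for one marker,
#'   named by condition.
#' @param dilution_order Condition labels ordered from least to most
#'   dilute. Gaps are allowed: the most dilute `detected` condition is
#'   returned regardless of contiguity.
#' @return The most dilute detected condition label, or `NA` if never
#'   detected.
#' @export
lowest_detected_dilution <- function(row_statuses, dilution_order) {
  det <- dilution_order[row_statuses[dilution_order] == "detected"]
  if (length(det) == 0L) NA_character_ else det[length(det)]
}
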