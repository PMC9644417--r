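mm1s_cdr3 <- paste0("GCGAGAGATTTGAGAGGTTAGGGTGAAAGGTTCCTTGTTTGTAGTAGTA",
                    "CCAGCTGCTACGAGGACTCCTACTACTACGATATGGACGTC")

test_that("MiXCR-style clone tables load with locus inference", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    paste("cloneCount", "cloneFraction", "allVHitsWithScore",
          "allDHitsWithScore", "allJHitsWithScore", "nSeqCDR3", "aaSeqCDR3",
          sep = "\t"),
    paste("880", "0.8802", "IGHV3-30*00(2431)", "IGHD2-2*00(80)",
          "IGHJ6*00(310)", mm1s_cdr3, "", sep = "\t"),
    paste("40", "0.04", "IGKV3-15*00(900)", "", "IGKJ5*00(200)",
          "TGTCAGCAGTATAATAACTGGCCTCC", "", sep = "\t")), f)
  clones <- load_clone_table(f, sample_id = "MM1S")
  expect_equal(nrow(clones), 2L)
  expect_equal(clones$v_gene, c("IGHV3-30", "IGKV3-15"))
  expect_equal(clones$d_gene[1], "IGHD2-2")
  expect_equal(clones$j_gene, c("IGHJ6", "IGKJ5"))
  expect_equal(clones$locus, c("IGH", "IGK"))
  expect_equal(clones$clone_fraction[1], 0.8802)
  expect_equal(clones$cdr3_nt[1], mm1s_cdr3)
})

test_that("missing columns and unparsable counts are reported", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("cloneCount\tcloneFraction\tallVHitsWithScore",
               "10\t0.5\tIGHV1-1*00(100)"), f)
  expect_error(load_clone_table(f), "allJHitsWithScore")

  f2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    paste("cloneCount", "cloneFraction", "allVHitsWithScore",
          "allJHitsWithScore", "nSeqCDR3", sep = "\t"),
    paste("oops", "0.5", "IGHV1-1*00(1)", "IGHJ1*00(1)", "ACGT", sep = "\t"),
    paste("25", "0.5", "IGHV1-2*00(1)", "IGHJ1*00(1)", "ACGTA", sep = "\t")),
    f2)
  clones <- suppressMessages(load_clone_table(f2))
  expect_equal(nrow(clones), 1L)
  expect_equal(attr(clones, "n_rejected"), 1L)

  f3 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(paste("cloneCount", "cloneFraction", "allVHitsWithScore",
                   "allJHitsWithScore", "nSeqCDR3", sep = "\t"), f3)
  expect_equal(nrow(load_clone_table(f3)), 0L)
})

mk_clone <- function(sample_id = "S1", locus = "IGH", v = "IGHV1-1",
                     j = "IGHJ1", cdr3 = "ACGTACGTACGTACGTACGTACGT",
                     count = 100L, fraction = NA_real_) {
  tibble::tibble(sample_id = sample_id, locus = locus, v_gene = v,
                 d_gene = "", j_gene = j, cdr3_nt = cdr3, cdr3_aa = "",
                 clone_count = as.integer(count), clone_fraction = fraction)
}

test_that("pseudogene removal drops V or J hits in the name set", {
  clones <- dplyr::bind_rows(
    mk_clone(v = "IGHV1-1"), mk_clone(v = "IGHV3-52"),
    mk_clone(j = "IGHJ9P"), mk_clone(v = "IGHV2-2"), mk_clone(v = "IGHV4-4"))
  out <- remove_pseudogenes(clones, c("IGHV3-52", "IGHJ9P"))
  expect_equal(nrow(out), 3L)
  expect_equal(attr(out, "n_removed"), 2L)
  expect_equal(remove_pseudogenes(clones, character())$v_gene, clones$v_gene)
})

test_that("locus fractions renormalize within sample and locus", {
  clones <- dplyr::bind_rows(
    mk_clone(count = 90L, cdr3 = "AAAAAAAAAAAA"),
    mk_clone(count = 10L, cdr3 = "CCCCCCCCCCCC"),
    mk_clone(locus = "IGK", v = "IGKV1-1", count = 30L, cdr3 = "GGGGGGGGGGGG"),
    mk_clone(locus = "IGK", v = "IGKV1-2", count = 70L, cdr3 = "TTTTTTTTTTTT"))
  out <- recompute_locus_fractions(clones)
  expect_equal(out$clone_fraction[out$locus == "IGH"], c(0.9, 0.1))
  sums <- tapply(out$clone_fraction, paste(out$sample_id, out$locus), sum)
  expect_true(all(abs(sums - 1) < 1e-9))
  # invariant under row reordering
  perm <- recompute_locus_fractions(clones[c(3, 1, 4, 2), ])
  expect_equal(dplyr::arrange(perm, cdr3_nt)$clone_fraction,
               dplyr::arrange(out, cdr3_nt)$clone_fraction)
  single <- recompute_locus_fractions(mk_clone(count = 5L))
  expect_equal(single$clone_fraction, 1.0)
})

test_that("the clonal-fraction threshold is strictly greater-than", {
  clones <- dplyr::bind_rows(
    mk_clone(cdr3 = "AAAAAAAAAAAA", fraction = 0.10),
    mk_clone(cdr3 = "CCCCCCCCCCCC", fraction = 0.8802),
    mk_clone(cdr3 = "GGGGGGGGGGGG", fraction = 0.101))
  out <- filter_by_fraction(clones, filter_config())
  expect_setequal(out$cdr3_nt, c("CCCCCCCCCCCC", "GGGGGGGGGGGG"))
  expect_equal(nrow(filter_by_fraction(clones[0, ], filter_config())), 0L)
})

test_that("cohort occurrences count distinct samples with exact CDR3 identity", {
  shared <- "TGTGCAAGAGGGG"
  lists <- lapply(sprintf("S%d", 1:10), function(sid) {
    dplyr::bind_rows(
      mk_clone(sample_id = sid, cdr3 = paste0("UNIQ", sid, "AAAAAA")),
      if (sid %in% sprintf("S%d", 1:6)) mk_clone(sample_id = sid,
                                                 cdr3 = shared))
  })
  idx <- build_cohort_index(lists)
  expect_equal(idx$occurrence[idx$cdr3_nt == shared], 6L)
  expect_true(all(idx$occurrence[idx$cdr3_nt != shared] == 1L))
  # donor replicates are not collapsed: two samples, same CDR3 -> 2
  reps <- list(mk_clone(sample_id = "D1a", cdr3 = shared),
               mk_clone(sample_id = "D1b", cdr3 = shared))
  expect_equal(build_cohort_index(reps)$occurrence, 2L)

  cfg <- filter_config()
  at5 <- mk_clone(sample_id = "S99", cdr3 = shared)
  idx5 <- build_cohort_index(lists[1:5])
  idx6 <- build_cohort_index(lists[1:6])
  expect_equal(nrow(filter_by_specificity(at5, idx5, cfg)), 1L)  # occurrence 5
  expect_equal(nrow(filter_by_specificity(at5, idx6, cfg)), 0L)  # occurrence 6
  # cohort of one sample: everything kept
  expect_equal(nrow(filter_by_specificity(lists[[1]],
                                          build_cohort_index(lists[1]),
                                          cfg)), nrow(lists[[1]]))
})

test_that("clone-count thresholds are strict and mode-dependent", {
  cfg_cl <- filter_config(mode = "cell_line")
  cfg_pt <- filter_config(mode = "patient")
  clones <- dplyr::bind_rows(
    mk_clone(cdr3 = "AAAAAAAAAAAA", count = 50L),
    mk_clone(cdr3 = "CCCCCCCCCCCC", count = 51L),
    mk_clone(cdr3 = "GGGGGGGGGGGG", count = 11L))
  expect_equal(filter_by_count(clones, cfg_cl)$cdr3_nt, "CCCCCCCCCCCC")
  expect_setequal(filter_by_count(clones, cfg_pt)$cdr3_nt,
                  c("AAAAAAAAAAAA", "CCCCCCCCCCCC", "GGGGGGGGGGGG"))
  expect_equal(nrow(filter_by_count(mk_clone(count = 10L), cfg_pt)), 0L)
})

test_that("the pipeline equals brute-force predicate evaluation", {
  for (s in c(101L, 202L)) {
    cohort <- simulate_clone_cohort(8L, seed = s)
    tables <- purrr::imap(cohort$tables, function(tb, sid) {
      load_clone_table(tb, sample_id = sid)
    })
    cfg <- filter_config()
    res <- call_candidates(tables, cfg)
    oracle <- brute_force_candidates(tables, cfg)
    for (sid in names(tables)) {
      got <- res$candidates[[sid]]
      want <- oracle[[sid]]
      expect_equal(got$cdr3_nt, want$cdr3_nt, info = sid)
      expect_equal(got$clone_count, want$clone_count, info = sid)
      expect_equal(got$clone_fraction, want$clone_fraction, info = sid,
                   tolerance = 1e-12)
    }
  }
})

test_that("the pipeline is invariant to input row order and audits drops", {
  cohort <- simulate_clone_cohort(6L, seed = 77)
  tables <- purrr::imap(cohort$tables, function(tb, sid) {
    load_clone_table(tb, sample_id = sid)
  })
  res <- call_candidates(tables, filter_config())
  shuffled <- lapply(tables, function(d) d[sample(nrow(d)), ])
  res2 <- call_candidates(shuffled, filter_config())
  for (sid in names(tables)) {
    expect_equal(res2$candidates[[sid]]$cdr3_nt, res$candidates[[sid]]$cdr3_nt)
  }
  a <- res$audit
  expect_equal(a$n_input - a$dropped_pseudogene - a$dropped_fraction -
                 a$dropped_specificity - a$dropped_count, a$n_candidates)
})

test_that("planted clones survive and threshold-violating artifacts never do", {
  cohort <- simulate_clone_cohort(10L, seed = 123)
  tables <- purrr::imap(cohort$tables, function(tb, sid) {
    load_clone_table(tb, sample_id = sid)
  })
  res <- call_candidates(tables, filter_config())
  surv <- dplyr::bind_rows(res$candidates)
  truth <- cohort$truth
  planted <- truth[truth$planted, ]
  for (i in seq_len(nrow(planted))) {
    expect_true(planted$cdr3_nt[i] %in%
                  surv$cdr3_nt[surv$sample_id == planted$sample_id[i]])
  }
  # shared artifacts recur in 8 > 5 samples: never survive anywhere
  expect_false(any(truth$cdr3_nt[truth$shared] %in% surv$cdr3_nt))
  # low-count artifacts (<= 50) never survive in cell-line mode
  low <- truth[!truth$planted & !truth$shared & truth$clone_count <= 50L, ]
  expect_false(any(paste(low$sample_id, low$cdr3_nt) %in%
                     paste(surv$sample_id, surv$cdr3_nt)))
})

test_that("an all-artifact sample yields an empty candidate list", {
  arts <- lapply(sprintf("P%d", 1:3), function(sid) {
    dplyr::bind_rows(lapply(1:10, function(i) {
      mk_clone(sample_id = sid, cdr3 = random_seq(30), count = 8L)
    }))
  })
  names(arts) <- sprintf("P%d", 1:3)
  res <- call_candidates(arts, filter_config(mode = "patient"))
  # every artifact count (8) fails the patient threshold (> 10)
  expect_true(all(vapply(res$candidates, nrow, integer(1)) == 0L))
  one <- list(S1 = mk_clone(count = 500L))
  expect_equal(nrow(call_candidates(one, filter_config())$candidates$S1), 1L)
})
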