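test_that("discordant-pair extraction applies the gates literally", {
  reads <- sort_reads(dplyr::bind_rows(
    make_pair("proper", "chr1", 1000L, "chr1", 1200L, insert = 350L),
    make_pair("boundary", "chr1", 2000L, "chr1", 7000L, insert = 5000L),
    make_pair("below", "chr1", 3000L, "chr1", 7500L, insert = 4999L),
    make_pair("inter1", "chr1", 4000L, "chr2", 9000L),
    make_pair("inter2", "chr1", 4100L, "chr2", 9100L),
    make_pair("lowmapq", "chr1", 4200L, "chr2", 9200L, mapqB = 10L),
    make_pair("dup", "chr1", 4300L, "chr2", 9300L, dupA = TRUE)))
  pairs <- extract_discordant(reads, clump_config())
  # proper 350-bp insert: no; 5000 inclusive boundary: yes; 4999: no;
  # inter-chromosomal: yes unless one mate fails MAPQ or is a duplicate
  expect_setequal(pairs$qname, c("boundary", "inter1", "inter2"))
  expect_true(all(pairs$chromA <= pairs$chromB))
})

test_that("extraction equals a brute-force scan of the predicate", {
  cfg <- clump_config()
  sim <- simulate_translocation_reads(
    toy_sim_config(seed = 17, tumor_fraction = 0.2, n_fragments = 2000L))
  got <- extract_discordant(sim$reads, cfg)

  # independent literal evaluation over every template
  reads <- sim$reads
  expected <- character()
  for (q in unique(reads$qname)) {
    m <- reads[reads$qname == q, ]
    if (nrow(m) != 2L) next
    if (all(m$mapq >= cfg$min_mapq) && !any(m$is_duplicate) &&
        (m$chrom[1] != m$chrom[2] ||
           max(m$insert_size) >= cfg$min_insert)) {
      expected <- c(expected, q)
    }
  }
  expect_setequal(got$qname, expected)
})

test_that("unsorted input and missing mates are handled", {
  reads <- dplyr::bind_rows(
    make_pair("a", "chr1", 5000L, "chr2", 1000L),
    make_pair("b", "chr1", 1000L, "chr2", 2000L))
  expect_error(extract_discordant(reads, clump_config()), "sorted")

  orphan <- make_read("orphan", "chr1", 100L, mate_chrom = "*",
                      mate_pos = 0L)
  ok <- sort_reads(dplyr::bind_rows(
    orphan, make_pair("c", "chr1", 1000L, "chr2", 2000L)))
  pairs <- extract_discordant(ok, clump_config())
  expect_equal(pairs$qname, "c")
  expect_equal(attr(pairs, "n_missing_mate"), 1L)
})

test_that("single-linkage clustering joins anchors within the window", {
  mk_pairs <- function(posA, posB) {
    reads <- sort_reads(dplyr::bind_rows(purrr::map2(
      posA, posB, function(a, b) {
        make_pair(sprintf("q%d_%d", a, b), "chr1", as.integer(a),
                  "chr2", as.integer(b))
      })))
    extract_discordant(reads, clump_config())
  }
  one <- cluster_pairs(mk_pairs(1000L, 2000L), clump_config())
  expect_equal(nrow(one), 1L)
  expect_equal(one$n_pairs, 1L)

  close2 <- cluster_pairs(mk_pairs(c(1000L, 1200L), c(2000L, 2200L)),
                          clump_config())
  expect_equal(nrow(close2), 1L)
  expect_equal(close2$n_pairs, 2L)

  farA <- cluster_pairs(mk_pairs(c(1000L, 6000L), c(2000L, 2200L)),
                        clump_config())
  expect_equal(nrow(farA), 2L)
})

test_that("clustering matches an independent connected-components oracle", {
  set.seed(23)
  cfg <- clump_config()
  for (rep in 1:5) {
    n <- 40L
    posA <- sample(seq(1000L, 30000L, by = 250L), n, replace = TRUE)
    posB <- sample(seq(1000L, 30000L, by = 250L), n, replace = TRUE)
    pairs <- tibble::tibble(
      qname = sprintf("q%02d", seq_len(n)),
      chromA = "chr1", posA = posA, strandA = "+",
      chromB = "chr2", posB = posB, strandB = "-",
      min_pair_mapq = 60L, inter_chromosomal = TRUE)
    clusters <- cluster_pairs(pairs, cfg)
    # oracle: graph with edges where both anchor gaps fit the window
    adj <- outer(posA, posA, function(x, y) abs(x - y) <= cfg$cluster_window) &
      outer(posB, posB, function(x, y) abs(x - y) <= cfg$cluster_window)
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
    comp <- igraph::components(g)$membership
    got <- integer(n)
    for (i in seq_len(nrow(clusters))) {
      got[match(clusters$pairs[[i]]$qname, pairs$qname)] <- i
    }
    # same partition: cluster labels must be a relabelling of components
    expect_equal(length(unique(comp)), nrow(clusters))
    expect_true(all(tapply(got, comp, function(x) length(unique(x))) == 1L))
  }
})

test_that("clip collection applies the mismatch-fraction arithmetic", {
  cfg <- clump_config()
  reads <- sort_reads(dplyr::bind_rows(
    make_read("big", "chr1", 9926L, cigar = "75M75S",
              seq = random_seq(150), clipped_suffix = strrep("C", 75)),
    make_read("small", "chr1", 9990L, cigar = "10S140M", nm = 2L,
              seq = random_seq(150), clipped_prefix = strrep("G", 10)),
    make_read("dup", "chr1", 9926L, cigar = "75M75S", is_duplicate = TRUE,
              seq = random_seq(150), clipped_suffix = strrep("C", 75)),
    make_read("lowq", "chr1", 9930L, cigar = "75M75S", mean_baseq = 10,
              seq = random_seq(150), clipped_suffix = strrep("C", 75))))
  clips <- collect_clip_support(reads, "chr1", 9500L, 10500L, cfg)
  # (75 + 0)/150 = 0.5 >= 0.33 kept; (10 + 2)/150 = 0.08 excluded;
  # duplicate flag excluded; mean base quality 10 < 20 excluded
  expect_equal(clips$qname, "big")
  expect_equal(clips$side, "right")
  expect_equal(clips$clip_coord, 9926L + 75L - 1L)
})

test_that("positional duplicate stacks collapse to one clip", {
  cfg <- clump_config()
  stack <- dplyr::bind_rows(lapply(1:4, function(i) {
    make_read(sprintf("s%d", i), "chr1", 10000L, cigar = "75M75S",
              seq = random_seq(150), clipped_suffix = strrep("C", 75))
  }))
  staggered <- make_read("t1", "chr1", 10005L, cigar = "70M80S",
                         seq = random_seq(150),
                         clipped_suffix = strrep("C", 80))
  clips <- collect_clip_support(sort_reads(dplyr::bind_rows(stack, staggered)),
                                "chr1", 9500L, 10500L, cfg)
  expect_equal(nrow(clips), 2L)  # identical (pos, cigar) stack collapses
})

test_that("breakpoint refinement takes the modal coordinate and majority base", {
  cluster <- tibble::tibble(cluster_id = 1L, chromA = "chr1",
                            startA = 9000L, endA = 11000L, chromB = "chr2",
                            startB = 19000L, endB = 21000L,
                            orientation = "FR", n_pairs = 5L,
                            pairs = list(NULL))
  clip_row <- function(q, coord, seq, side = "right") {
    tibble::tibble(qname = q, pos = coord - 74L, cigar = "75M75S",
                   side = side, clip_coord = as.integer(coord),
                   clipped_seq = seq, mean_baseq = 35, mapq = 60L)
  }
  seq40 <- random_seq(40)
  clipsA <- dplyr::bind_rows(lapply(1:5, function(i) {
    clip_row(sprintf("c%d", i), 10000L, seq40)
  }))
  call <- refine_breakpoint(cluster[1, ], clipsA)
  expect_equal(call$posA, 10000L)
  expect_equal(call$consensus_clip_A, seq40)
  expect_equal(call$n_clip_A, 5L)
  expect_equal(call$resolution, "base_pair")
  # no clips on B: window midpoint
  expect_equal(call$posB, 20000L)

  tie <- dplyr::bind_rows(
    lapply(1:3, function(i) clip_row(sprintf("x%d", i), 10000L, seq40)),
    lapply(1:3, function(i) clip_row(sprintf("y%d", i), 10002L, seq40)))
  call2 <- refine_breakpoint(cluster[1, ], tie)
  expect_equal(call2$posA, 10000L)  # ties break to the smaller coordinate

  none <- refine_breakpoint(cluster[1, ])
  expect_equal(none$resolution, "window")
  expect_equal(none$posA, 10000L)
})

test_that("region filters mark calls without deleting them", {
  calls <- dplyr::bind_rows(
    tibble::tibble(chromA = "chr1", posA = 500L, chromB = "chr2",
                   posB = 5000L, n_pairs = 5L, n_clip_A = 2L, n_clip_B = 2L,
                   consensus_clip_A = "A", consensus_clip_B = "A",
                   clip_seqs_A = list("A"), clip_seqs_B = list("A"),
                   resolution = "base_pair", status = "candidate",
                   filter_reason = ""),
    tibble::tibble(chromA = "chr1", posA = 2000L, chromB = "chr2",
                   posB = 7000L, n_pairs = 5L, n_clip_A = 2L, n_clip_B = 2L,
                   consensus_clip_A = "A", consensus_clip_B = "A",
                   clip_seqs_A = list("A"), clip_seqs_B = list("A"),
                   resolution = "base_pair", status = "candidate",
                   filter_reason = ""),
    tibble::tibble(chromA = "chr1", posA = 9000L, chromB = "chr2",
                   posB = 9500L, n_pairs = 1L, n_clip_A = 0L, n_clip_B = 0L,
                   consensus_clip_A = "", consensus_clip_B = "",
                   clip_seqs_A = list(character()),
                   clip_seqs_B = list(character()),
                   resolution = "window", status = "candidate",
                   filter_reason = ""))
  blacklist <- tibble::tibble(chrom = "chr1", start = 400L, end = 600L)
  ig <- tibble::tibble(chrom = c("chr1", "chr2"),
                       start = c(1500L, 6500L), end = c(2500L, 7500L))
  out <- filter_events(calls, blacklist, ig, clump_config())
  expect_equal(out$status, rep("filtered", 3))
  expect_equal(out$filter_reason, c("blacklist", "ig_internal", "min_support"))
  # idempotent
  expect_equal(filter_events(out, blacklist, ig, clump_config()), out)
  # with no intervals, region reasons clear but weak support still filters
  clean <- filter_events(calls, NULL, NULL, clump_config())
  expect_equal(clean$status, c("candidate", "candidate", "filtered"))
})

test_that("malformed BED lines fail hard with their line number", {
  f <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t100\t200", "chr1\tnot_a_number\t300"), f)
  expect_error(read_bed(f), "line 2")
  writeLines(c("chr1\t100\t200", "chr2\t5\t50\tname"), f)
  bed <- read_bed(f)
  expect_equal(bed$start, c(100L, 5L))
  expect_equal(bed$name, c(NA, "name"))
})

test_that("the full caller recovers a planted junction and is deterministic", {
  cfg <- toy_sim_config(seed = 101, tumor_fraction = 0.1,
                        n_fragments = 20000L)
  sim <- simulate_translocation_reads(cfg)
  calls <- call_translocations(sim$reads)
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$posA, sim$truth$breakpoints$posA)
  expect_equal(calls$posB, sim$truth$breakpoints$posB)
  expect_equal(calls$resolution, "base_pair")

  # byte-identical TSV across two runs
  f1 <- withr::local_tempfile(fileext = ".tsv")
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_calls_tsv(call_translocations(sim$reads), f1)
  write_calls_tsv(call_translocations(sim$reads), f2)
  expect_identical(readLines(f1), readLines(f2))

  # no tumor fragments -> no candidates
  none <- simulate_translocation_reads(toy_sim_config(tumor_fraction = 0,
                                                      n_fragments = 2000L))
  expect_equal(nrow(call_translocations(none$reads)), 0L)
})
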