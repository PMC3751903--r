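# Breakpoint search regions and read support (Stage 2).

test_that("breakpoint regions follow the overlap/extension rules", {
  # split alignments overlapping contig [50,60)
  a <- mk_aln("c", 120, blocks = list(c(0, 1000, 60)))
  b <- mk_aln("c", 120, "chr2", blocks = list(c(50, 9000, 70)))
  sel <- list(case = "III", sets = list(list(a, b)), multimapping = FALSE,
              groups = NULL, gaps = list())
  cand <- make_candidates(list(id = "c", length = 120), sel)[[1]]
  expect_equal(breakpoint_region(cand), c(49, 61))

  # abutting alignments at contig position 80
  a2 <- mk_aln("c", 160, blocks = list(c(0, 1000, 80)))
  b2 <- mk_aln("c", 160, "chr2", blocks = list(c(80, 9000, 80)))
  sel$sets <- list(list(a2, b2))
  cand2 <- make_candidates(list(id = "c", length = 160), sel)[[1]]
  expect_equal(breakpoint_region(cand2), c(79, 81))

  # gap duplication with inserted bases between the copies: the region
  # starts at the first copy's end and ends at the second copy's start
  # (chance homology at the insert boundary may shrink it, never grow it)
  fx <- mk_gap_candidate(pre = 300, dup = 60, post = 300, insert = 6)
  P <- breakpoint_region(fx$candidate)
  expect_equal(P[1], 360)
  expect_lte(P[2], 366)
  expect_gt(P[2], P[1])

  # without an insert the copies abut: the two junction-flanking bases
  fx2 <- mk_gap_candidate(pre = 300, dup = 60, post = 300, insert = 0)
  expect_equal(diff(breakpoint_region(fx2$candidate)), 2)
})

test_that("read support equals the worst position and honours flanks", {
  fx <- mk_gap_candidate()
  P <- breakpoint_region(fx$candidate)
  # 7 mismatch-free reads spanning P with >= 5 nt flanks on both sides
  reads <- mk_reads("ctgG", rep(P[1] - 40, 7), rep(P[2] + 40, 7))
  rs <- read_support(fx$candidate, reads)
  expect_equal(rs$total_support, 7L)
  expect_equal(rs$strong_support, 7L)

  # a read with mismatches does not count
  reads2 <- rbind(reads, mk_reads("ctgG", P[1] - 40, P[2] + 40,
                                  has_mismatch = TRUE, ids = "rX"))
  expect_equal(read_support(fx$candidate, reads2)$total_support, 7L)

  # an uneven depth profile is summarized by its minimum
  cand <- mk_split_candidate()  # junction at 100, P = [99,101)
  deep <- mk_reads("ctgS", c(rep(50, 10), rep(96, 2)), c(rep(145, 10), rep(171, 2)))
  # drop the 10 spanning reads' right flank at position 100 by ending at 104:
  shallow <- mk_reads("ctgS", rep(60, 10), rep(104, 10), ids = sprintf("s%d", 1:10))
  rs2 <- read_support(cand, rbind(deep, shallow))
  # at p=99: spanning 10+2(+10 with flank 5: 104-99=5 ok) ; at p=100: shallow lose flank
  expect_equal(rs2$total_support,
               brute_read_support(c(99, 101), rbind(deep, shallow)))
})

test_that("read support equals brute force on 500 random layouts", {
  set.seed(404)
  cand <- mk_split_candidate()
  P <- breakpoint_region(cand)
  for (i in 1:500) {
    n <- sample(0:25, 1)
    starts <- sample(0:150, n, replace = TRUE)
    lens <- sample(20:75, max(n, 1), replace = TRUE)[seq_len(n)]
    reads <- mk_reads("ctgS", starts, pmin(200, starts + lens),
                      has_mismatch = sample(c(TRUE, FALSE), n, replace = TRUE))
    rs <- read_support(cand, reads)
    expect_equal(rs$total_support, brute_read_support(P, reads))
  }
})

test_that("support guarantee: every position in P has at least the reported depth", {
  set.seed(405)
  cand <- mk_split_candidate()
  P <- breakpoint_region(cand)
  for (i in 1:50) {
    n <- sample(5:30, 1)
    starts <- sample(60:120, n, replace = TRUE)
    reads <- mk_reads("ctgS", starts, starts + 75)
    rs <- read_support(cand, reads)
    for (p in seq.int(P[1], P[2] - 1)) {
      depth_p <- sum(p - reads$target_start >= 4 & reads$target_end - p >= 5)
      expect_gte(depth_p, rs$total_support)
    }
  }
})

test_that("support score splits strong and weak multi-mapping reads", {
  expect_equal(support_score("c1", "c1"), list(score = 1.0, strong = TRUE))
  expect_equal(support_score(c("c1", "c2"), "c1"),
               list(score = 0.5, strong = TRUE))
  s <- support_score(c("c1", "c2", "c3"), "c1")
  expect_equal(s$score, 1 / 3)
  expect_false(s$strong)
  expect_error(support_score(character(0), "c1"), "no contig")
})

test_that("weakly supporting reads count toward total but not strong support", {
  cand <- mk_split_candidate()
  P <- breakpoint_region(cand)
  span <- mk_reads("ctgS", rep(P[1] - 40, 6), rep(P[2] + 40, 6))
  # three of the reads also map to two unrelated contigs
  extra <- data.frame(read_id = rep(c("r001", "r002", "r003"), each = 2),
                      target_id = rep(c("other1", "other2"), 3),
                      target_start = 0, target_end = 75,
                      has_mismatch = FALSE, perfect = TRUE, mate = 1L)
  rs <- read_support(cand, rbind(span, extra))
  expect_equal(rs$total_support, 6L)
  expect_equal(rs$strong_support, 3L)  # score 1/3 for the multi-mapped reads
})

test_that("support is monotone in min_flank and under adding reads", {
  set.seed(406)
  cand <- mk_split_candidate()
  starts <- sample(40:140, 30, replace = TRUE)
  reads <- mk_reads("ctgS", starts, starts + 60)
  totals <- vapply(c(1, 3, 5, 10, 20), function(q)
    read_support(cand, reads, min_flank = q)$total_support, integer(1))
  expect_true(all(diff(totals) <= 0))

  base <- read_support(cand, reads)
  more <- rbind(reads, mk_reads("ctgS", 60, 135, ids = "extra"))
  grown <- read_support(cand, more)
  expect_gte(grown$total_support, base$total_support)
  expect_gte(grown$strong_support, base$strong_support)
})
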