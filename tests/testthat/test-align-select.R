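# Alignment-set metrics, selection cases, query gaps, topology labels and
# gap realignment.

test_that("alignment-set metrics match forced arithmetic on stated cases", {
  full <- mk_aln("c1", 100, blocks = list(c(0, 1000, 100)))
  m <- alignment_set_metrics(list(full), 100)
  expect_equal(m$quality, 1.0)
  expect_equal(m$inclusion, 1.0)
  expect_equal(m$overlap, 0.0)
  expect_equal(m$size, 1)
  expect_equal(m$score, 1.0)

  # two quality-0.9 alignments covering [0,60) and [40,100)
  a <- mk_aln("c1", 100, blocks = list(c(0, 1000, 60)), mismatches = 3)
  b <- mk_aln("c1", 100, blocks = list(c(40, 2000, 60)), mismatches = 3)
  expect_equal(a$quality, 0.9)
  m2 <- alignment_set_metrics(list(a, b), 100)
  expect_equal(m2$quality, 1.8)
  expect_equal(m2$inclusion, 1.0)
  expect_equal(m2$overlap, 0.2)
  expect_equal(m2$size, 2)
  expect_equal(m2$score, 0.6)

  expect_error(alignment_set_metrics(list(), 100), "empty")
})

test_that("metrics equal the per-position brute-force tally on random sets", {
  set.seed(101)
  for (i in 1:200) {
    rs <- random_alignment_set()
    m <- alignment_set_metrics(rs$alignments, rs$contig_length)
    o <- brute_metrics(rs$alignments, rs$contig_length)
    expect_equal(m, o)
    expect_true(m$overlap <= m$inclusion)
    expect_true(m$overlap >= 0 && m$inclusion <= 1)
  }
})

test_that("query gaps cover interior, edge and absent cases", {
  a <- mk_aln("c1", 100, blocks = list(c(0, 1000, 40), c(60, 2000, 40)))
  gaps <- find_query_gaps(a, 100)
  expect_length(gaps, 1)
  expect_equal(gaps[[1]]$start, 40)
  expect_equal(gaps[[1]]$end, 59)

  edge <- mk_aln("c1", 100, blocks = list(c(10, 1000, 90)))
  g2 <- find_query_gaps(edge, 100)
  expect_length(g2, 1)
  expect_equal(c(g2[[1]]$start, g2[[1]]$end), c(0, 9))

  expect_length(find_query_gaps(mk_aln("c1", 100), 100), 0)
})

test_that("selection distinguishes Cases I-IV", {
  # Case I: one gap-free alignment with inclusion 0.99
  sel <- select_alignment_sets(list(mk_aln("c", 100,
                                           blocks = list(c(0, 1000, 99)))), 100)
  expect_equal(sel$case, "I")
  expect_length(sel$sets, 0)

  # Case III: among five partial alignments, the high-quality, low-overlap
  # pair jointly covering the contig is selected
  good1 <- mk_aln("c", 100, blocks = list(c(0, 1000, 55)))
  good2 <- mk_aln("c", 100, "chr2", blocks = list(c(55, 9000, 45)))
  noise <- lapply(1:3, function(i)
    mk_aln("c", 100, blocks = list(c(5 * i, 3000 + 500 * i, 35)),
           mismatches = 7))
  sel3 <- select_alignment_sets(c(list(good1, good2), noise), 100)
  expect_equal(sel3$case, "III")
  prim <- sel3$sets[[1]]
  expect_setequal(vapply(prim, function(a) a$blocks[1, "genome_start"],
                         numeric(1)), c(1000, 9000))

  # Case IV: three mutually disjoint pieces
  thirds <- lapply(0:2, function(i)
    mk_aln("c", 90, paste0("chr", i + 1), blocks = list(c(30 * i, 1000, 30))))
  expect_equal(select_alignment_sets(thirds, 90)$case, "IV")

  # Case II: single gapped alignment (gap >= min length) is not Case I
  gapped <- mk_aln("c", 100, blocks = list(c(0, 1000, 48), c(52, 1048, 48)))
  sel2 <- select_alignment_sets(list(gapped), 100)
  expect_equal(sel2$case, "II")
  expect_length(sel2$gaps, 1)
})

test_that("chosen subset score matches exhaustive enumeration over the partition", {
  set.seed(202)
  for (i in 1:60) {
    rs <- random_alignment_set(6, 200)
    params <- align_params(case1_inclusion_min = 1.01)  # force grouping path
    sel <- select_alignment_sets(rs$alignments, rs$contig_length, params)
    if (length(sel$sets) == 0) next
    chosen <- alignment_set_metrics(sel$sets[[1]], rs$contig_length)$score
    groups <- chimdetect:::overlap_groups(rs$alignments, rs$contig_length,
                                          params$overlap_group_min)
    # every subset taking at most one member per overlap group
    choice_sets <- lapply(groups, function(idx) c(NA, idx))
    grid <- do.call(expand.grid, choice_sets)
    best <- -Inf
    for (r in seq_len(nrow(grid))) {
      idx <- na.omit(as.numeric(grid[r, ]))
      if (length(idx) == 0) next
      s <- alignment_set_metrics(rs$alignments[idx], rs$contig_length)$score
      best <- max(best, s)
    }
    expect_equal(chosen, best, tolerance = 1e-9)
  }
})

test_that("multi-mapping alternates within the quality window are flagged", {
  a <- mk_aln("c", 100, blocks = list(c(0, 1000, 60)))
  a_alt <- mk_aln("c", 100, blocks = list(c(0, 7000, 60)), mismatches = 1)
  b <- mk_aln("c", 100, "chr2", blocks = list(c(60, 9000, 40)))
  sel <- select_alignment_sets(list(a, a_alt, b), 100)
  expect_equal(sel$case, "III")
  expect_true(all(sel$multimapping))
  expect_length(sel$sets, 2)  # primary plus the alternate substitution
})

test_that("topology labels partition ordered pairs", {
  base <- function(chrom, strand, gstart)
    mk_aln("c", 100, chrom, strand, list(c(0, gstart, 50)))
  second <- function(chrom, strand, gstart)
    mk_aln("c", 100, chrom, strand, list(c(50, gstart, 50)))
  cases <- list(
    list(base("chr1", "+", 1000), second("chr2", "+", 1000), "interchromosomal"),
    list(base("chr1", "+", 1000), second("chr1", "-", 2000), "inversion"),
    list(base("chr1", "+", 5000), second("chr1", "+", 4800), "eversion"),
    list(base("chr1", "+", 5000), second("chr1", "+", 5000), "duplication"),
    list(base("chr1", "+", 1000), second("chr1", "+", 8000), "read_through"))
  labels <- c("interchromosomal", "inversion", "eversion", "duplication",
              "read_through")
  for (cs in cases) {
    got <- classify_topology(cs[[1]], cs[[2]])
    expect_equal(got, cs[[3]])
    expect_equal(sum(labels == got), 1L)  # exactly one label
  }
})

test_that("gap realignment detects constructed duplications and inversions", {
  fx <- mk_gap_candidate(pre = 60, dup = 30, post = 60)
  expect_equal(fx$realignment$kind, "duplication")
  expect_equal(fx$realignment$identity, 100)
  expect_gte(fx$realignment$aligned_fraction, 0.9)
  # the duplication realignment maps onto the first copy, not the gap
  expect_equal(unname(fx$realignment$target_interval), c(60, 90))
  expect_equal(fx$realignment$gap_aligned_seq,
               substr(fx$contig, 61, 90))

  # inversion: gap equals the reverse complement of the flanked window
  set.seed(5)
  chrom <- chimdetect:::random_dna(400)
  left <- substr(chrom, 101, 160)
  right <- substr(chrom, 201, 260)
  win_rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(substr(chrom, 161, 200))))
  contig <- paste0(left, win_rc, right)
  host <- contig_alignment("ci", nchar(contig), "chr1", "+",
                           rbind(c(0, 100, 60), c(100, 200, 60)))
  gap <- list(contig_id = "ci", start = 60, end = 99, gap_sequence = win_rc)
  re <- realign_gap(contig, gap, host, make_genome_fetcher(c(chr1 = chrom)))
  expect_equal(re$kind, "inversion")
  expect_equal(re$identity, 100)
  expect_equal(unname(re$target_interval), c(160, 200))

  # a random gap matching nothing returns NULL
  set.seed(6)
  P <- chimdetect:::random_dna(60); S <- chimdetect:::random_dna(60)
  junk <- paste(rep(c("A", "C"), 15), collapse = "")
  contig2 <- paste0(P, junk, S)
  host2 <- contig_alignment("cx", nchar(contig2), "chr1", "+",
                            rbind(c(0, 100, 60), c(90, 300, 60)))
  gap2 <- list(contig_id = "cx", start = 60, end = 89, gap_sequence = junk)
  fetch2 <- make_genome_fetcher(c(chr1 = chimdetect:::random_dna(600)))
  expect_null(realign_gap(contig2, gap2, host2, fetch2))

  expect_error(realign_gap("ACGT", list(start = 2, end = 10), host), "outside")
})

test_that("candidate creation enforces thresholds and drops mitochondria", {
  a <- mk_aln("c", 200, blocks = list(c(0, 1000, 100)))
  b <- mk_aln("c", 200, "chr2", blocks = list(c(100, 9000, 92)))
  sel <- list(case = "III", sets = list(list(a, b)), multimapping = FALSE,
              groups = NULL, gaps = list())
  cands <- make_candidates(list(id = "c", length = 200), sel)
  expect_length(cands, 1)  # inclusion 0.96 > 0.9
  expect_equal(cands[[1]]$kind, "split")

  short_b <- mk_aln("c", 200, "chr2", blocks = list(c(100, 9000, 70)))
  sel$sets <- list(list(a, short_b))
  expect_length(make_candidates(list(id = "c", length = 200), sel), 0)

  mito <- mk_aln("c", 200, "chrM", blocks = list(c(100, 50, 100)))
  sel$sets <- list(list(a, mito))
  expect_length(make_candidates(list(id = "c", length = 200), sel), 0)
  keep <- make_candidates(list(id = "c", length = 200), sel,
                          params = align_params(drop_mito = FALSE))
  expect_length(keep, 1)
})

test_that("gap candidates carry duplication topology and genomic segment", {
  fx <- mk_gap_candidate(pre = 200, dup = 40, post = 200)
  cand <- fx$candidate
  expect_equal(cand$kind, "gap")
  expect_equal(cand$topology, "duplication")
  # existing copy sits at contig [200,240) -> genome [2200, 2240)
  expect_equal(cand$dup_segment$start, 2200)
  expect_equal(cand$dup_segment$end, 2240)
  expect_equal(cand$breakpoints$pos, c(2200, 2239))
})
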