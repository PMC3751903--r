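# Flank regions, depth partitioning and relative coverage (Stage 5).

test_that("flank regions are cut to two read lengths from the junction", {
  # one 400 nt block per side, read length 75 -> 150 nt kept per side,
  # adjacent to the breakpoint
  a <- mk_aln("ctgF", 800, "chr1", "+", list(c(0, 1000, 400)))
  b <- mk_aln("ctgF", 800, "chr2", "+", list(c(400, 5000, 400)))
  sel <- list(case = "III", sets = list(list(a, b)), multimapping = FALSE,
              groups = NULL, gaps = list())
  cand <- make_candidates(list(id = "ctgF", length = 800), sel)[[1]]
  fl <- flanking_regions(cand, 75)
  expect_equal(fl$A$total_length, 150)
  expect_equal(fl$B$total_length, 150)
  expect_equal(unname(fl$A$blocks), matrix(c(1250, 1400), 1))
  expect_equal(unname(fl$B$blocks), matrix(c(5000, 5150), 1))
  expect_false(fl$A$truncated)
})

test_that("short junction-proximal blocks borrow from the next block", {
  # side A: 100 + 30 nt exon blocks; keeps the 30 nt block plus 120 nt
  a <- mk_aln("ctgF", 600, "chr1", "+",
              list(c(0, 1000, 100), c(100, 2000, 30)))
  b <- mk_aln("ctgF", 600, "chr2", "+", list(c(130, 5000, 470)))
  sel <- list(case = "III", sets = list(list(a, b)), multimapping = FALSE,
              groups = NULL, gaps = list())
  cand <- make_candidates(list(id = "ctgF", length = 600), sel)[[1]]
  gm <- list(gene_model("GA", "TA", "chr1", "+",
                        cbind(c(950, 2000), c(1100, 2030))))
  fl <- flanking_regions(cand, 75, gm)
  expect_equal(fl$A$total_length, 150)
  covered <- sort(unlist(apply(fl$A$blocks, 1, function(b) b[1]:(b[2] - 1))))
  expect_equal(covered, sort(c(2000:2029, 980:1099)))
  # without gene models the region truncates at the aligned blocks
  fl0 <- flanking_regions(cand, 75)
  expect_equal(fl0$A$total_length, 130)
  expect_true(fl0$A$truncated)
})

test_that("a terminal exon with no neighbor truncates and is flagged", {
  a <- mk_aln("ctgF", 300, "chr1", "+", list(c(0, 1000, 80)))
  b <- mk_aln("ctgF", 300, "chr2", "+", list(c(80, 5000, 220)))
  sel <- list(case = "III", sets = list(list(a, b)), multimapping = FALSE,
              groups = NULL, gaps = list())
  cand <- make_candidates(list(id = "ctgF", length = 300), sel)[[1]]
  # gene model offers no neighboring exon to extend into
  gm <- list(gene_model("GA", "TA", "chr1", "+", cbind(1000, 1080)))
  fl <- flanking_regions(cand, 75, gm)
  expect_equal(fl$A$total_length, 80)
  expect_true(fl$A$truncated)
})

test_that("extension walks the annotated transcript structure", {
  a <- mk_aln("ctgF", 300, "chr1", "+", list(c(0, 2000, 80)))
  b <- mk_aln("ctgF", 300, "chr2", "+", list(c(80, 5000, 220)))
  sel <- list(case = "III", sets = list(list(a, b)), multimapping = FALSE,
              groups = NULL, gaps = list())
  cand <- make_candidates(list(id = "ctgF", length = 300), sel)[[1]]
  gm <- list(gene_model("GA", "TA", "chr1", "+",
                        cbind(c(1500, 2000), c(1700, 2100))))
  fl <- flanking_regions(cand, 75, gm)
  expect_equal(fl$A$total_length, 150)
  expect_false(fl$A$truncated)
  # 80 nt of the aligned exon + 70 nt borrowed from the upstream exon
  expect_equal(unname(fl$A$blocks), rbind(c(2000, 2080), c(1630, 1700)))
})

mk_partition <- function(DW, T1, T2, n = 20) {
  p <- data.frame(pos = seq_len(n), DW = DW, T1 = T1, T2 = T2)
  p$T <- p$DW + p$T1 + p$T2
  p
}

test_that("relative coverage matches the closed-form cases exactly", {
  # C=5; DW=0, T1=15, T2=0 everywhere -> W(*)=10, T(*)=15
  rc <- relative_coverage(5, mk_partition(0, 15, 0), mk_partition(0, 15, 0))
  expect_equal(rc$W_star, 10)
  expect_equal(rc$T_star, 15)
  expect_equal(unname(rc$ratios["C_W_star"]), 0.5)
  expect_equal(unname(rc$ratios["C_T_star"]), 1 / 3)

  # a duplicated-segment position with T2=20 -> W = 20 - 2*5 = 10
  rc2 <- relative_coverage(5, mk_partition(0, 0, 20), mk_partition(0, 0, 20))
  expect_equal(rc2$W_A, 10)
  expect_equal(rc2$T_A, 20)

  # W equals T when the chimeric terms are absent
  rc3 <- relative_coverage(5, mk_partition(12, 0, 0), mk_partition(12, 0, 0))
  expect_equal(rc3$W_A, rc3$T_A)
})

test_that("negative intermediate W is clamped and zero W gives Inf sentinel", {
  rc <- relative_coverage(30, mk_partition(0, 15, 0), mk_partition(0, 15, 0))
  expect_true(rc$clamped)
  expect_equal(rc$W_star, 0)
  expect_equal(unname(rc$ratios["C_W_star"]), Inf)
  expect_false(is.na(rc$ratios["C_T_star"]))
})

test_that("T(r) is taken among positions attaining the W maximum", {
  pa <- mk_partition(0, c(rep(15, 10), rep(10, 10)), 0)
  pa$T[3] <- 18  # higher total at a W-max position
  pa$T1[3] <- 18
  # position 3 now has W = 18 - 5 = 13, the unique max; T must follow it
  rc <- relative_coverage(5, pa, pa)
  expect_equal(rc$W_A, 13)
  expect_equal(rc$T_A, 18)
})

test_that("depth partition classifies uniform wild-type coverage as T1", {
  region <- structure(list(label = "A", chrom = "chr1",
                           blocks = cbind(start = 1000, end = 1100),
                           total_length = 100, truncated = FALSE),
                      class = "FlankRegion")
  event <- structure(list(event_type = "PTD",
                          dup_segment = list(chrom = "chr1", start = 5000,
                                             end = 5200),
                          breakpoints = data.frame(chrom = "chr1",
                                                   pos = c(5000, 5199))),
                     class = "EventPrediction")
  starts <- seq(900, 1100, by = 5)
  r2g <- data.frame(read_id = sprintf("r%d", seq_along(starts)),
                    target_id = "chr1", target_start = starts,
                    target_end = starts + 75, has_mismatch = FALSE,
                    perfect = TRUE, mate = 1L)
  r2g$blocks <- lapply(starts, function(s)
    cbind(start = s, end = s + 75))
  dp <- depth_partition(region, event, r2g, q = 5)
  expect_true(all(dp$DW == 0))
  expect_true(all(dp$T2 == 0))
  expect_true(all(dp$T == dp$T1))
  # interior positions carry the full qualifying depth
  interior <- dp$pos > 1010 & dp$pos < 1090
  expect_true(all(dp$T1[interior] > 0))

  # positions inside the duplicated segment accrue T2 instead
  region2 <- structure(list(label = "B", chrom = "chr1",
                            blocks = cbind(start = 5050, end = 5120),
                            total_length = 70, truncated = FALSE),
                       class = "FlankRegion")
  starts2 <- seq(4980, 5120, by = 4)
  r2g2 <- data.frame(read_id = sprintf("q%d", seq_along(starts2)),
                     target_id = "chr1", target_start = starts2,
                     target_end = starts2 + 75, has_mismatch = FALSE,
                     perfect = TRUE, mate = 1L)
  r2g2$blocks <- lapply(starts2, function(s) cbind(start = s, end = s + 75))
  dp2 <- depth_partition(region2, event, r2g2, q = 5)
  expect_true(all(dp2$T1 == 0))
  expect_true(all(dp2$T == dp2$T2))
})

test_that("fusion reads spanning the breakpoint are classified wild-type-only", {
  region <- structure(list(label = "A", chrom = "chr1",
                           blocks = cbind(start = 1000, end = 1100),
                           total_length = 100, truncated = FALSE),
                      class = "FlankRegion")
  event <- structure(list(event_type = "fusion", dup_segment = NULL,
                          breakpoints = data.frame(
                            chrom = c("chr1", "chr2"), pos = c(1099, 5000))),
                     class = "EventPrediction")
  # one read stops at the breakpoint (chimeric-compatible), one crosses it
  r2g <- data.frame(read_id = c("stop", "cross"), target_id = "chr1",
                    target_start = c(1025, 1060), target_end = c(1100, 1135),
                    has_mismatch = FALSE, perfect = TRUE, mate = 1L)
  r2g$blocks <- list(cbind(start = 1025, end = 1100),
                     cbind(start = 1060, end = 1135))
  dp <- depth_partition(region, event, r2g, q = 5)
  at <- function(p) dp[dp$pos == p, ]
  expect_equal(at(1080)$DW, 1)  # the crossing read
  expect_equal(at(1080)$T1, 1)  # the stopping read
  expect_equal(at(1040)$T1, 1)  # only the stopping read qualifies here
  expect_equal(at(1040)$DW, 0)
})
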