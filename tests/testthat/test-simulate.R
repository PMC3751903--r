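# Synthetic genome / event / read generation and the ideal-alignment
# synthesizer.

test_that("genome simulation is seed-deterministic and writes valid files", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  g1 <- simulate_genome(seed = 7, out_dir = d1)
  g2 <- simulate_genome(seed = 7, out_dir = d2)
  expect_identical(g1$seqs, g2$seqs)
  expect_identical(readBin(file.path(d1, "genome.fa"), "raw", 1e6),
                   readBin(file.path(d2, "genome.fa"), "raw", 1e6))
  back <- read_annotations(file.path(d1, "genes.genepred"), "genepredext")
  expect_length(back, length(g1$genes))
  expect_equal(back[[3]]$exons, g1$genes[[3]]$exons)

  empty <- simulate_genome(n_genes = 0, seed = 1)
  expect_length(empty$genes, 0)
  expect_true(all(nchar(empty$seqs) > 0))
})

test_that("gene models stay within chromosome bounds across seeds", {
  for (s in 1:50) {
    g <- simulate_genome(seed = s, n_genes = 8)
    for (gm in g$genes) {
      expect_gte(min(gm$exons), 0)
      expect_lte(max(gm$exons), nchar(g$seqs[[gm$chrom]]))
    }
  }
})

test_that("simulated events obey their defining constraints", {
  g <- simulate_genome(seed = 21, n_genes = 20)
  ev <- simulate_events(g, c(fusion = 5, ptd = 5, itd = 5), seed = 22)
  expect_lte(length(ev), 15)
  expect_true(all(vapply(ev, function(e) nchar(e$transcript_seq), 0) >= 200))

  boundaries <- lapply(g$genes, gene_exon_boundaries)
  names(boundaries) <- vapply(g$genes, `[[`, "", "gene_id")
  for (e in ev) {
    if (e$event_type == "ptd") {
      b <- boundaries[[e$genes]]
      expect_true(all(e$breakpoints$pos %in% b))
    }
    if (e$event_type == "itd") {
      b <- boundaries[[e$genes]]
      expect_false(any(e$breakpoints$pos %in% b))
      # chimeric sequence equals wild type with the segment duplicated
      gene <- Filter(function(x) x$gene_id == e$genes, g$genes)[[1]]
      wt <- chimdetect:::gene_transcript_seq(g, gene)
      seg <- substr(g$seqs[[gene$chrom]], e$dup_segment$start + 1,
                    e$dup_segment$end)
      expect_equal(nchar(e$transcript_seq),
                   nchar(wt) + nchar(seg) + e$inserted_bases)
      # removing the second copy (and insert) restores the wild type
      gap <- e$gap
      restored <- paste0(substr(e$transcript_seq, 1, gap[1]),
                         substr(e$transcript_seq, gap[2] + 1,
                                nchar(e$transcript_seq)))
      expect_equal(restored, wt)
    }
    if (e$event_type == "fusion") {
      expect_length(e$genes, 2)
      expect_false(e$genes[1] == e$genes[2])
    }
  }
})

test_that("read counts track coverage and reads are seed-deterministic", {
  tx <- setNames(chimdetect:::random_dna(300), "t1")
  rd <- simulate_reads(tx, coverage_model(constant = 10), read_length = 75,
                       seed = 5)
  # expectation: cov * len / read_len single reads = 40
  expect_gt(nrow(rd$reads), 25)
  expect_lt(nrow(rd$reads), 55)
  rd2 <- simulate_reads(tx, coverage_model(constant = 10), read_length = 75,
                        seed = 5)
  expect_identical(rd$reads, rd2$reads)

  f1 <- withr::local_tempfile(fileext = ".fq")
  f2 <- withr::local_tempfile(fileext = ".fq")
  write_fastq(rd$reads, f1, f2)
  expect_equal(length(readLines(f1)), 4 * sum(rd$reads$mate == 1))

  # mates are reverse complements drawn from one fragment
  r1 <- rd$reads[rd$reads$mate == 1, ][1, ]
  r2 <- rd$reads[rd$reads$read_id == r1$read_id & rd$reads$mate == 2, ]
  expect_equal(as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(r2$seq))),
    substr(tx[[1]], r2$t_start + 1, r2$t_end))
})

test_that("coverage draws are positive and match the mixture distribution", {
  set.seed(9)
  cov <- sample_coverage(10000, coverage_model())
  expect_true(all(cov > 0))
  m <- coverage_model()
  mix_cdf <- function(x) {
    m$weight * plnorm(x, m$meanlog1, m$sdlog1) +
      (1 - m$weight) * plnorm(x, m$meanlog2, m$sdlog2)
  }
  ks <- suppressWarnings(ks.test(cov[1:2000], mix_cdf))
  expect_gt(ks$p.value, 0.01)
  # median near the 30x design point
  expect_gt(median(cov), 20)
  expect_lt(median(cov), 50)
})

test_that("ideal alignments are structurally faithful to their events", {
  fx <- build_simulation(counts = c(fusion = 3, ptd = 3, itd = 3),
                         seed_genome = 31, seed_events = 32, seed_reads = 33)
  alns <- fx$syn$contig_alignments
  by_ctg <- split(alns, vapply(alns, `[[`, "", "contig_id"))
  for (e in fx$events) {
    mine <- by_ctg[[e$contig_id]]
    if (e$event_type == "itd") {
      expect_length(mine, 1)  # one gapped alignment
      gaps <- find_query_gaps(mine[[1]], nchar(e$contig_seq))
      expect_length(gaps, 1)
    } else {
      expect_length(mine, 2)
      if (e$event_type == "ptd") {
        # overlapping genomic intervals on one chromosome: duplication class
        ord <- order(vapply(mine, function(a)
          chimdetect:::aln_contig_span(a)[1], numeric(1)))
        topo <- classify_topology(mine[[ord[1]]], mine[[ord[2]]])
        expect_true(topo %in% c("duplication", "eversion"))
      }
    }
  }
  # read-to-contig records are perfect single runs inside the contig
  r2c <- fx$syn$read_to_contig
  expect_true(all(!r2c$has_mismatch))
  expect_true(all(grepl("^[0-9]+M$", r2c$cigar)))

  # SAM round trip through the real reader preserves the records
  tmp <- withr::local_tempfile(fileext = ".sam")
  lens <- setNames(vapply(fx$syn$contigs, nchar, 0), names(fx$syn$contigs))
  sub <- r2c[seq_len(min(200, nrow(r2c))), ]
  write_sam(sub, lens, tmp)
  back <- read_read_alignments(tmp, "read_to_contig")
  expect_equal(nrow(back), nrow(sub))
  key <- function(d) sort(paste(d$read_id, d$target_id, d$target_start,
                                d$target_end))
  expect_equal(key(back), key(sub))
})
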