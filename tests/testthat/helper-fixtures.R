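# Shared fixture builders and brute-force oracles.

# shorthand alignment constructor: blocks as list of c(qstart, tstart, len)
mk_aln <- function(id = "c1", len = 100, chrom = "chr1", strand = "+",
                   blocks = list(c(0, 100, len)), mismatches = 0) {
  contig_alignment(id, len, chrom, strand, do.call(rbind, blocks),
                   mismatches = mismatches)
}

# brute-force per-position tally of alignment-set metrics
brute_metrics <- function(alignments, contig_length) {
  cov <- integer(contig_length)
  for (a in alignments) {
    for (k in seq_len(nrow(a$blocks))) {
      b <- a$blocks[k, ]
      idx <- seq.int(b["contig_start"] + 1, b["contig_start"] + b["length"])
      cov[idx] <- cov[idx] + 1L
    }
  }
  quality <- sum(vapply(alignments, `[[`, numeric(1), "quality"))
  list(quality = quality,
       inclusion = mean(cov >= 1),
       overlap = mean(cov >= 2),
       size = length(alignments),
       score = quality + mean(cov >= 1) - mean(cov >= 2) - length(alignments))
}

# random alignment set on a random contig, for the metric/selection oracles
random_alignment_set <- function(max_alns = 5, max_len = 200) {
  len <- sample(50:max_len, 1)
  n <- sample.int(max_alns, 1)
  alns <- lapply(seq_len(n), function(i) {
    w <- sample(10:max(11, len - 1), 1)
    w <- min(w, len)
    s <- sample.int(len - w + 1, 1) - 1
    mm <- sample(0:min(5, w - 1), 1)
    nb <- sample.int(min(3, max(1, w %/% 10)), 1)
    # split [s, s+w) into nb disjoint blocks with 1nt spacers
    if (nb > 1 && w > 2 * nb) {
      cuts <- sort(sample.int(w - 1, nb - 1))
      bounds <- cbind(c(0, cuts), c(cuts, w))
      keep <- bounds[, 2] - bounds[, 1] >= 2
      bounds <- bounds[keep, , drop = FALSE]
      blocks <- cbind(s + bounds[, 1], 1000 + s + bounds[, 1] * 2,
                      bounds[, 2] - bounds[, 1] - 1)
      blocks[nrow(blocks), 3] <- blocks[nrow(blocks), 3] + 1
    } else {
      blocks <- cbind(s, 1000 + s, w)
    }
    blocks <- blocks[blocks[, 3] > 0, , drop = FALSE]
    total <- sum(blocks[, 3])
    contig_alignment(sprintf("rc%d", i), len, sample(c("chr1", "chr2"), 1),
                     sample(c("+", "-"), 1), blocks,
                     mismatches = min(mm, total - 1))
  })
  list(alignments = alns, contig_length = len)
}

# brute-force per-position read support: min over P of flank-qualified depth
brute_read_support <- function(P, reads, min_flank = 5) {
  positions <- seq.int(P[1], P[2] - 1)
  min(vapply(positions, function(p) {
    sum(!reads$has_mismatch &
          p - reads$target_start >= min_flank - 1 &
          reads$target_end - p >= min_flank)
  }, numeric(1)))
}

# read-to-contig alignment table from (start, end) pairs on one contig
mk_reads <- function(contig, starts, ends, has_mismatch = FALSE,
                     ids = sprintf("r%03d", seq_along(starts))) {
  data.frame(read_id = ids, target_id = rep(contig, length(starts)),
             target_start = starts, target_end = ends,
             has_mismatch = rep(has_mismatch, length.out = length(starts)),
             perfect = !rep(has_mismatch, length.out = length(starts)),
             mate = rep(1L, length(starts)))
}

# canonical clean split candidate: two genes, two chromosomes
mk_split_candidate <- function(contig_len = 200, seq = NULL,
                               chrom_b = "chr2", strand_b = "+",
                               gstart_b = 5000, split_at = 100) {
  a <- mk_aln("ctgS", contig_len, "chr1", "+", list(c(0, 1000, split_at)))
  b <- mk_aln("ctgS", contig_len, chrom_b, strand_b,
              list(c(split_at, gstart_b, contig_len - split_at)))
  sel <- list(case = "III", sets = list(list(a, b)), multimapping = FALSE,
              groups = NULL, gaps = list())
  make_candidates(list(id = "ctgS", length = contig_len, seq = seq), sel)[[1]]
}

# clean gap-duplication candidate built from an explicit repeat contig
mk_gap_candidate <- function(pre = 150, dup = 30, post = 150, insert = 0,
                             seed = 99, dup_seq = NULL) {
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  rnd <- function(n) paste(sample(bases, n, replace = TRUE), collapse = "")
  P <- rnd(pre); D <- if (is.null(dup_seq)) rnd(dup) else dup_seq
  dup <- nchar(D)
  S <- rnd(post); I <- if (insert > 0) rnd(insert) else ""
  contig <- paste0(P, D, I, D, S)
  L <- nchar(contig)
  gap_start <- pre + dup
  gap_end <- pre + dup + insert + dup - 1
  host <- contig_alignment("ctgG", L, "chr1", "+",
                           rbind(c(0, 2000, gap_start),
                                 c(gap_end + 1, 2000 + gap_start, post)))
  gap <- list(contig_id = "ctgG", start = gap_start, end = gap_end,
              gap_sequence = substr(contig, gap_start + 1, gap_end + 1))
  re <- realign_gap(contig, gap, host)
  sel <- list(case = "II", sets = list(list(host)), multimapping = FALSE,
              groups = NULL, gaps = list(gap))
  cands <- make_candidates(list(id = "ctgG", length = L, seq = contig),
                           sel, list(re))
  list(candidate = if (length(cands)) cands[[1]] else NULL,
       realignment = re, contig = contig, host = host, gap = gap)
}

# full synthetic study fixture: genome, events, reads, ideal alignments
build_simulation <- function(counts = c(fusion = 10, ptd = 10, itd = 10),
                             n_genes = 20, seed_genome = 7, seed_events = 11,
                             seed_reads = 13,
                             model = coverage_model(constant = 30),
                             distinct_genes = FALSE, genome_reads = FALSE) {
  g <- simulate_genome(seed = seed_genome, n_genes = n_genes)
  ev <- simulate_events(g, counts, seed = seed_events,
                        distinct_genes = distinct_genes)
  txs <- setNames(vapply(ev, `[[`, "", "transcript_seq"),
                  vapply(ev, `[[`, "", "event_id"))
  wt <- setNames(vapply(g$genes, function(x)
    chimdetect:::gene_transcript_seq(g, x), character(1)),
    vapply(g$genes, `[[`, "", "transcript_id"))
  wt_genes <- setNames(vapply(g$genes, `[[`, "", "gene_id"), names(wt))
  rd <- simulate_reads(c(txs, wt), model, seed = seed_reads)
  syn <- synthesize_alignments(ev, g, rd$reads, wildtype = wt,
                               wildtype_genes = wt_genes,
                               genome_reads = genome_reads)
  list(genome = g, events = ev, reads = rd, syn = syn, wildtype = wt,
       wildtype_genes = wt_genes)
}

# match pipeline predictions against simulated truth (10 nt tolerance)
match_truth <- function(tab, events, tol = 10) {
  type_map <- c(fusion = "fusion", ptd = "PTD", itd = "ITD")
  hit_one <- function(e, r) {
    type_map[[e$event_type]] == r$event_type &&
      r$chrom_a == e$breakpoints$chrom[1] &&
      abs(r$breakpoint_a - 1 - e$breakpoints$pos[1]) <= tol &&
      r$chrom_b == e$breakpoints$chrom[2] &&
      abs(r$breakpoint_b - 1 - e$breakpoints$pos[2]) <= tol
  }
  recovered <- vapply(events, function(e) {
    any(vapply(seq_len(nrow(tab)), function(i) hit_one(e, tab[i, ]),
               logical(1)))
  }, logical(1))
  false_pos <- if (nrow(tab) == 0) 0L else
    sum(!vapply(seq_len(nrow(tab)), function(i) {
      any(vapply(events, function(e) hit_one(e, tab[i, ]), logical(1)))
    }, logical(1)))
  list(recovered = recovered, false_positives = false_pos)
}

run_sim_pipeline <- function(fx, config = filter_config(), relcov = FALSE) {
  run_pipeline(contigs = fx$syn$contigs,
               contig_alignments = fx$syn$contig_alignments,
               read_to_contig = fx$syn$read_to_contig,
               gene_models = fx$genome$genes,
               wildtype_transcripts = fx$wildtype,
               read_to_genome = if (relcov) fx$syn$read_to_genome else NULL,
               genome_seqs = fx$genome$seqs,
               config = config)
}
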