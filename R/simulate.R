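# Synthetic data: a small multi-gene genome, simulated fusion/PTD/ITD
# transcripts, paired-end reads with a two-component log-normal coverage
# mixture, and the ideal alignments a perfect aligner would produce.

with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  code
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# uniform draw from lo:hi that is safe when lo == hi
sample_range <- function(lo, hi) {
  if (hi <= lo) return(lo)
  lo + sample.int(hi - lo + 1L, 1L) - 1L
}

#' Simulate a small multi-gene genome
#'
#' Generates random chromosome sequences and non-overlapping multi-exon
#' gene models placed sequentially (round-robin over chromosomes, plus
#' strand). Reproducible under a fixed seed.
#'
#' @param n_chroms number of chromosomes.
#' @param n_genes number of genes.
#' @param exons_per_gene range of exon counts per gene.
#' @param exon_length_range,intron_length_range exon/intron length ranges
#'   (nt).
#' @param intergenic_range spacing between genes (nt).
#' @param seed optional RNG seed.
#' @param out_dir optional directory: writes `genome.fa` and
#'   `genes.genepred` there.
#' @return list of class `SyntheticGenome`: `seqs` (named character),
#'   `genes` (list of `GeneModel`), `seed`.
#' @export
simulate_genome <- function(n_chroms = 2, n_genes = 20,
                            exons_per_gene = c(3, 6),
                            exon_length_range = c(150, 400),
                            intron_length_range = c(200, 600),
                            intergenic_range = c(400, 800),
                            seed = NULL, out_dir = NULL) {
  stopifnot(n_chroms >= 1, n_genes >= 0)
  with_seed(seed, {
    chrom_names <- paste0("chr", seq_len(n_chroms))
    genes <- list()
    cursor <- setNames(rep(0, n_chroms), chrom_names)
    for (g in seq_len(n_genes)) {
      chrom <- chrom_names[((g - 1) %% n_chroms) + 1]
      start <- cursor[[chrom]] + sample_range(intergenic_range[1], intergenic_range[2])
      n_ex <- sample_range(exons_per_gene[1], exons_per_gene[2])
      pos <- start
      exons <- matrix(0, n_ex, 2)
      for (e in seq_len(n_ex)) {
        len <- sample_range(exon_length_range[1], exon_length_range[2])
        exons[e, ] <- c(pos, pos + len)
        pos <- pos + len +
          if (e < n_ex) sample_range(intron_length_range[1], intron_length_range[2]) else 0
      }
      cursor[[chrom]] <- pos
      genes[[g]] <- gene_model(sprintf("GENE%03d", g), sprintf("TX%03d", g),
                               chrom, "+", exons)
    }
    chrom_len <- pmax(cursor + 500, 1000)
    seqs <- setNames(vapply(chrom_len, random_dna, character(1)), chrom_names)
    genome <- structure(list(seqs = seqs, genes = genes, seed = seed),
                        class = "SyntheticGenome")
    if (!is.null(out_dir)) {
      dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
      Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs),
                                  file.path(out_dir, "genome.fa"))
      write_genepredext(genes, file.path(out_dir, "genes.genepred"))
    }
    genome
  })
}

#' Wild-type transcript sequences of a synthetic genome
#'
#' @param genome a `SyntheticGenome`.
#' @return named character vector of spliced transcript sequences keyed by
#'   transcript id, with a `genes` attribute mapping transcript ids to gene
#'   ids (as [synthesize_alignments()] expects).
#' @export
wildtype_transcript_seqs <- function(genome) {
  out <- setNames(vapply(genome$genes, function(g)
    gene_transcript_seq(genome, g), character(1)),
    vapply(genome$genes, `[[`, "", "transcript_id"))
  attr(out, "genes") <- setNames(
    vapply(genome$genes, `[[`, "", "gene_id"), names(out))
  out
}

# spliced (wild-type) transcript sequence of a gene
gene_transcript_seq <- function(genome, gene) {
  chrom <- genome$seqs[[gene$chrom]]
  paste(vapply(seq_len(nrow(gene$exons)), function(k)
    substr(chrom, gene$exons[k, "start"] + 1, gene$exons[k, "end"]),
    character(1)), collapse = "")
}

# map a transcript interval [a, b) onto genome blocks via an exon chain
# (matrix of genome intervals in transcript order); returns a matrix with
# columns contig_start (t_offset-shifted), genome_start, length
chain_map <- function(chain, a, b, t_offset = 0) {
  lens <- chain[, 2] - chain[, 1]
  cum <- c(0, cumsum(lens))
  out <- NULL
  for (k in seq_len(nrow(chain))) {
    lo <- max(a, cum[k]); hi <- min(b, cum[k + 1])
    if (hi > lo)
      out <- rbind(out, c(t_offset + lo, chain[k, 1] + (lo - cum[k]), hi - lo))
  }
  if (is.null(out)) out <- matrix(numeric(0), ncol = 3)
  colnames(out) <- c("contig_start", "genome_start", "length")
  out
}

#' Simulate fusion, PTD and ITD transcripts
#'
#' Fusions join the 5' exons of one gene to the 3' exons of another gene
#' (on another chromosome when available). PTDs duplicate a whole exon run,
#' so both duplicated-segment edges fall on annotated exon boundaries; the
#' emitted contig is a short junction contig spanning the non-canonical
#' exon junction. ITDs duplicate a sub-exonic segment in place, optionally
#' with a few inserted bases between the copies, and are emitted as
#' full-length contigs with the second copy left as a query gap by an
#' ideal aligner. Simulated transcripts shorter than `min_transcript_length`
#' are discarded.
#'
#' @param genome a `SyntheticGenome`.
#' @param counts named vector `c(fusion=, ptd=, itd=)`.
#' @param seed optional RNG seed.
#' @param itd_length_range duplicated-segment length range for ITDs.
#' @param itd_insert_max maximum inserted bases between ITD copies (the
#'   insert is kept below a tenth of the segment so the gap realignment can
#'   succeed, as in real FLT3-style inserts which are short relative to the
#'   duplication).
#' @param min_transcript_length discard shorter products (default 200).
#' @param junction_read_length half-width of PTD junction contigs (default
#'   75, one read length each side of the junction).
#' @param distinct_genes sample source genes without replacement, so no
#'   two events share a gene (default FALSE).
#' @return list of `SimulatedEvent` records: `event_id`, `event_type`,
#'   `genes`, `transcript_seq`, `contig_id`, `contig_seq`, `contig_offset`
#'   (offset of the contig within the transcript), `breakpoints`,
#'   `dup_segment`, `inserted_bases`, `pieces` (transcript-to-genome
#'   mapping).
#' @export
simulate_events <- function(genome, counts = c(fusion = 5, ptd = 5, itd = 5),
                            seed = NULL,
                            itd_length_range = c(15, 45),
                            itd_insert_max = 3,
                            min_transcript_length = 200,
                            junction_read_length = 75,
                            distinct_genes = FALSE) {
  genes <- genome$genes
  stopifnot(length(genes) >= 2)
  with_seed(seed, {
    available <- seq_along(genes)
    take_gene <- function(n = 1L, prefer_other_chrom_than = NULL) {
      pool <- if (distinct_genes) available else seq_along(genes)
      if (!is.null(prefer_other_chrom_than)) {
        alt <- pool[vapply(genes[pool], function(g)
          g$chrom != prefer_other_chrom_than, logical(1))]
        if (length(alt) > 0) pool <- alt
      }
      if (length(pool) == 0L) stop("not enough genes for distinct events")
      i <- if (length(pool) == 1L) pool else sample(pool, 1)
      if (distinct_genes) available <<- setdiff(available, i)
      i
    }
    events <- list()
    eid <- 0L
    add_event <- function(ev) {
      if (nchar(ev$transcript_seq) < min_transcript_length) return()
      eid <<- eid + 1L
      ev$event_id <- sprintf("ev%03d", eid)
      ev$contig_id <- sprintf("ctg_%s_%s", ev$event_type, ev$event_id)
      events[[length(events) + 1L]] <<- ev
    }
    n_genes <- length(genes)
    # fusions: 5' exons of A + 3' exons of B
    for (k in seq_len(counts[["fusion"]] %||% 0)) {
      i <- take_gene()
      j <- take_gene(prefer_other_chrom_than = genes[[i]]$chrom)
      A <- genes[[i]]; B <- genes[[j]]
      nA <- nrow(A$exons); nB <- nrow(B$exons)
      kA <- sample.int(nA - 1, 1)
      mB <- sample.int(nB - 1, 1)
      chainA <- A$exons[seq_len(kA), , drop = FALSE]
      chainB <- B$exons[seq.int(nB - mB + 1, nB), , drop = FALSE]
      lenA <- sum(chainA[, 2] - chainA[, 1])
      lenB <- sum(chainB[, 2] - chainB[, 1])
      chrA <- genome$seqs[[A$chrom]]; chrB <- genome$seqs[[B$chrom]]
      seqA <- paste(substring(chrA, chainA[, 1] + 1, chainA[, 2]), collapse = "")
      seqB <- paste(substring(chrB, chainB[, 1] + 1, chainB[, 2]), collapse = "")
      add_event(list(
        event_type = "fusion", genes = c(A$gene_id, B$gene_id),
        transcript_seq = paste0(seqA, seqB),
        contig_offset = 0,
        breakpoints = data.frame(
          chrom = c(A$chrom, B$chrom),
          pos = c(chainA[kA, 2] - 1, chainB[1, 1]),
          strand = "+"),
        dup_segment = NULL, inserted_bases = NA_integer_,
        pieces = list(
          list(t_start = 0, t_end = lenA, chrom = A$chrom, chain = chainA),
          list(t_start = lenA, t_end = lenA + lenB, chrom = B$chrom,
               chain = chainB))))
    }
    # PTDs: duplicate a whole exon run; junction contig around the NCEJ
    for (k in seq_len(counts[["ptd"]] %||% 0)) {
      g <- genes[[take_gene()]]
      n_ex <- nrow(g$exons)
      e1 <- sample.int(n_ex, 1)
      e2 <- sample_range(e1, n_ex)
      chain1 <- g$exons[seq_len(e2), , drop = FALSE]
      chain2 <- g$exons[seq.int(e1, n_ex), , drop = FALSE]
      len1 <- sum(chain1[, 2] - chain1[, 1])
      len2 <- sum(chain2[, 2] - chain2[, 1])
      chr <- genome$seqs[[g$chrom]]
      seq1 <- paste(substring(chr, chain1[, 1] + 1, chain1[, 2]), collapse = "")
      seq2 <- paste(substring(chr, chain2[, 1] + 1, chain2[, 2]), collapse = "")
      tx <- paste0(seq1, seq2)
      L <- junction_read_length
      off <- max(0, len1 - L)
      contig_end <- min(len1 + len2, len1 + L)
      add_event(list(
        event_type = "ptd", genes = g$gene_id,
        transcript_seq = tx,
        contig_offset = off,
        contig_end = contig_end,
        breakpoints = data.frame(
          chrom = g$chrom,
          pos = c(g$exons[e1, "start"], g$exons[e2, "end"] - 1),
          strand = "+"),
        dup_segment = list(chrom = g$chrom, start = g$exons[e1, "start"],
                           end = g$exons[e2, "end"]),
        inserted_bases = 0L,
        pieces = list(
          list(t_start = 0, t_end = len1, chrom = g$chrom, chain = chain1),
          list(t_start = len1, t_end = len1 + len2, chrom = g$chrom,
               chain = chain2))))
    }
    # ITDs: duplicate a sub-exonic segment in place
    for (k in seq_len(counts[["itd"]] %||% 0)) {
      g <- genes[[take_gene()]]
      widths <- g$exons[, 2] - g$exons[, 1]
      ok <- which(widths >= itd_length_range[2] + 10)
      if (length(ok) == 0L) ok <- which.max(widths)
      ex <- if (length(ok) == 1L) ok else sample(ok, 1)
      seg_len <- sample_range(itd_length_range[1], itd_length_range[2])
      seg_len <- min(seg_len, widths[ex] - 10)
      ins_len <- sample_range(0L, min(itd_insert_max, seg_len %/% 10))
      seg_start <- g$exons[ex, 1] +
        sample_range(3, widths[ex] - seg_len - 3)
      seg_end <- seg_start + seg_len
      chr <- genome$seqs[[g$chrom]]
      wild_chain <- g$exons
      wild_tx <- gene_transcript_seq(genome, g)
      cum <- c(0, cumsum(widths))
      t_seg_end <- cum[ex] + (seg_end - g$exons[ex, 1])
      seg_seq <- substr(chr, seg_start + 1, seg_end)
      ins_seq <- if (ins_len > 0) random_dna(ins_len) else ""
      tx <- paste0(substr(wild_tx, 1, t_seg_end), ins_seq, seg_seq,
                   substr(wild_tx, t_seg_end + 1, nchar(wild_tx)))
      # split the containing exon at the segment bounds so both pieces'
      # chains end/start exactly at the duplicated segment
      chain1 <- rbind(
        wild_chain[seq_len(ex - 1), , drop = FALSE],
        c(g$exons[ex, 1], seg_end))
      chain2 <- if (ex == nrow(wild_chain)) {
        matrix(c(seg_start, g$exons[ex, 2]), ncol = 2)
      } else {
        rbind(c(seg_start, g$exons[ex, 2]),
              wild_chain[seq.int(ex + 1, nrow(wild_chain)), , drop = FALSE])
      }
      len1 <- t_seg_end
      add_event(list(
        event_type = "itd", genes = g$gene_id,
        transcript_seq = tx,
        contig_offset = 0,
        breakpoints = data.frame(chrom = g$chrom,
                                 pos = c(seg_start, seg_end - 1),
                                 strand = "+"),
        dup_segment = list(chrom = g$chrom, start = seg_start, end = seg_end),
        inserted_bases = as.integer(ins_len),
        gap = c(t_seg_end, t_seg_end + ins_len + seg_len),
        pieces = list(
          list(t_start = 0, t_end = len1, chrom = g$chrom, chain = chain1),
          list(t_start = len1 + ins_len, t_end = nchar(tx),
               chrom = g$chrom, chain = chain2))))
    }
    # finalize contig sequences
    for (k in seq_along(events)) {
      ev <- events[[k]]
      if (ev$event_type == "ptd") {
        events[[k]]$contig_seq <- substr(ev$transcript_seq,
                                         ev$contig_offset + 1, ev$contig_end)
      } else {
        events[[k]]$contig_seq <- ev$transcript_seq
      }
    }
    events
  })
}

#' Two-component log-normal coverage model
#'
#' Defaults give a long-tailed mixture with median coverage around 30x,
#' emulating bulk transcriptome expression.
#'
#' @param meanlog1,sdlog1,meanlog2,sdlog2 component parameters.
#' @param weight mixing weight of component 1.
#' @param constant if non-NULL, every transcript gets exactly this
#'   coverage (a degenerate model useful for controlled fixtures).
#' @return list of class `CoverageModel`.
#' @export
coverage_model <- function(meanlog1 = log(12), sdlog1 = 0.7,
                           meanlog2 = log(65), sdlog2 = 1.0,
                           weight = 0.45, constant = NULL) {
  structure(list(meanlog1 = meanlog1, sdlog1 = sdlog1, meanlog2 = meanlog2,
                 sdlog2 = sdlog2, weight = weight, constant = constant),
            class = "CoverageModel")
}

#' Sample per-transcript coverages from a coverage model
#'
#' @param n number of draws.
#' @param model a [coverage_model()].
#' @return numeric vector of positive coverages.
#' @export
sample_coverage <- function(n, model = coverage_model()) {
  if (!is.null(model$constant)) return(rep(model$constant, n))
  comp1 <- runif(n) < model$weight
  ifelse(comp1,
         rlnorm(n, model$meanlog1, model$sdlog1),
         rlnorm(n, model$meanlog2, model$sdlog2))
}

#' Simulate error-free paired-end reads from transcripts
#'
#' Per-transcript coverage is drawn from the coverage model; fragments are
#' placed uniformly, with fragment length drawn from a normal distribution
#' (clamped between the read length and the transcript length), so mates
#' overlap when the mean fragment is shorter than twice the read length.
#'
#' @param transcripts named character vector of transcript sequences.
#' @param model a [coverage_model()].
#' @param read_length read length (default 75).
#' @param mean_fragment,sd_fragment fragment length distribution (defaults
#'   114 and 10: overlapping pairs).
#' @param seed optional RNG seed.
#' @return list with `reads` (data.frame: `read_id`, `transcript_id`,
#'   `mate`, `t_start`, `t_end` (0-based fragment-derived read interval on
#'   the transcript), `seq`) and `coverage` (named per-transcript
#'   coverage).
#' @export
simulate_reads <- function(transcripts, model = coverage_model(),
                           read_length = 75, mean_fragment = 114,
                           sd_fragment = 10, seed = NULL) {
  stopifnot(length(names(transcripts)) == length(transcripts))
  with_seed(seed, {
    cov <- setNames(sample_coverage(length(transcripts), model),
                    names(transcripts))
    out <- vector("list", length(transcripts))
    for (k in seq_along(transcripts)) {
      id <- names(transcripts)[k]
      seq <- transcripts[[k]]
      len <- nchar(seq)
      if (len < read_length) next
      n_pairs <- max(0L, round(cov[[k]] * len / (2 * read_length)))
      if (n_pairs == 0L) next
      flen <- pmin(len, pmax(read_length,
                             round(rnorm(n_pairs, mean_fragment, sd_fragment))))
      fstart <- floor(runif(n_pairs, 0, len - flen + 1))
      r1 <- substring(seq, fstart + 1, fstart + read_length)
      r2s <- substring(seq, fstart + flen - read_length + 1, fstart + flen)
      r2 <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAStringSet(r2s)))
      ids <- sprintf("%s_p%05d", id, seq_len(n_pairs))
      out[[k]] <- data.frame(
        read_id = rep(ids, 2L),
        transcript_id = id,
        mate = rep(c(1L, 2L), each = n_pairs),
        t_start = c(fstart, fstart + flen - read_length),
        t_end = c(fstart + read_length, fstart + flen),
        seq = c(r1, r2))
    }
    reads <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
    if (is.null(reads))
      reads <- data.frame(read_id = character(), transcript_id = character(),
                          mate = integer(), t_start = numeric(),
                          t_end = numeric(), seq = character())
    list(reads = reads, coverage = cov)
  })
}

#' Write paired reads as FASTQ
#'
#' @param reads data.frame from [simulate_reads()].
#' @param path1,path2 output FASTQ paths for mates 1 and 2.
#' @export
write_fastq <- function(reads, path1, path2) {
  emit <- function(df, path) {
    writeLines(as.vector(rbind(paste0("@", df$read_id, "/", df$mate),
                               df$seq, "+",
                               strrep("I", nchar(df$seq)))), path)
  }
  emit(reads[reads$mate == 1L, ], path1)
  emit(reads[reads$mate == 2L, ], path2)
  invisible(c(path1, path2))
}
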