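# Ideal alignments: the PSL and SAM records a perfect aligner would
# produce for simulated contigs and reads, so the pipeline can be run
# without BLAT/BWA.

# genome blocks of a transcript interval [a, b) under an event's piecewise
# mapping; returns per-piece block matrices (contig_start, genome_start,
# length) with contig coordinates shifted by -contig_offset
event_piece_blocks <- function(event, a, b, contig_offset = 0) {
  lapply(event$pieces, function(p) {
    lo <- max(a, p$t_start); hi <- min(b, p$t_end)
    if (hi <= lo)
      return(matrix(numeric(0), ncol = 3,
                    dimnames = list(NULL, c("contig_start", "genome_start", "length"))))
    chain_map(p$chain, lo - p$t_start, hi - p$t_start,
              t_offset = p$t_start - contig_offset)
  })
}

#' Synthesize ideal contig and read alignments for simulated events
#'
#' Emits, for each simulated event, the contig-to-genome alignment(s) a
#' perfect aligner would report (a split pair for fusions and PTD junction
#' contigs; a single gapped alignment for ITDs, whose second copy is left
#' as a query gap), plus read-to-contig records (reads wholly inside a
#' contig, mismatch-free) and spliced read-to-genome records (reads
#' spanning a chimeric junction align their longer side, with the rest
#' soft-clipped). Wild-type transcripts can contribute collinear contigs
#' of their own, exercising the non-chimeric path.
#'
#' @param events list from [simulate_events()].
#' @param genome the `SyntheticGenome`.
#' @param reads data.frame from [simulate_reads()] (event and/or wild-type
#'   transcript reads; `transcript_id` must name an event's
#'   `contig_id`-bearing transcript or a wild-type transcript).
#' @param wildtype optional named character vector of wild-type transcript
#'   sequences, keyed by transcript id, with a parallel `wildtype_genes`
#'   naming the source gene of each.
#' @param wildtype_genes named character vector mapping wild-type
#'   transcript ids to gene ids (for genome mapping of their reads).
#' @param include_wildtype_contigs also emit one collinear contig (and its
#'   single alignment) per wild-type transcript.
#' @param min_genome_side minimum aligned side (nt) for a junction-spanning
#'   read's genome record (default 20; shorter sides are dropped, as an
#'   aligner would fail to place them).
#' @return list with `contig_alignments` (list of `ContigAlignment`),
#'   `contigs` (named character sequences), `read_to_contig` and
#'   `read_to_genome` (data.frames in the [read_read_alignments()] layout,
#'   with `pos`/`cigar`/`nm`/`seq` columns so [write_sam()] applies).
#' @export
synthesize_alignments <- function(events, genome, reads,
                                  wildtype = NULL, wildtype_genes = NULL,
                                  include_wildtype_contigs = TRUE,
                                  genome_reads = TRUE,
                                  min_genome_side = 20) {
  contigs <- character(0)
  alns <- list()
  gene_by_id <- setNames(genome$genes,
                         vapply(genome$genes, `[[`, "", "gene_id"))

  for (ev in events) {
    contigs[[ev$contig_id]] <- ev$contig_seq
    clen <- nchar(ev$contig_seq)
    off <- ev$contig_offset
    if (ev$event_type == "itd") {
      # one gapped alignment: everything but the second copy (+ insert)
      blocks <- rbind(
        event_piece_blocks(ev, 0, ev$gap[1], off)[[1]],
        event_piece_blocks(ev, ev$gap[2], nchar(ev$transcript_seq), off)[[2]])
      alns[[length(alns) + 1L]] <- contig_alignment(
        ev$contig_id, clen, ev$pieces[[1]]$chrom, "+", blocks)
    } else {
      pb <- event_piece_blocks(ev, off, off + clen, off)
      for (k in 1:2) {
        if (nrow(pb[[k]]) == 0L) next
        alns[[length(alns) + 1L]] <- contig_alignment(
          ev$contig_id, clen, ev$pieces[[k]]$chrom, "+", pb[[k]])
      }
    }
  }
  if (include_wildtype_contigs && !is.null(wildtype)) {
    for (tx in names(wildtype)) {
      cid <- paste0("ctg_wt_", tx)
      contigs[[cid]] <- wildtype[[tx]]
      g <- gene_by_id[[wildtype_genes[[tx]]]]
      alns[[length(alns) + 1L]] <- contig_alignment(
        cid, nchar(wildtype[[tx]]), g$chrom, "+",
        chain_map(g$exons, 0, gene_model_length(g)))
    }
  }

  # --- read-to-contig: reads wholly inside a contig window, perfect
  ev_of_read <- match(reads$transcript_id,
                      vapply(events, `[[`, "", "event_id"))
  ei <- which(!is.na(ev_of_read))
  offs <- vapply(events, `[[`, numeric(1), "contig_offset")
  clens <- vapply(events, function(e) nchar(e$contig_seq), numeric(1))
  cids <- vapply(events, `[[`, "", "contig_id")
  s <- reads$t_start[ei] - offs[ev_of_read[ei]]
  e <- reads$t_end[ei] - offs[ev_of_read[ei]]
  keep <- s >= 0 & e <= clens[ev_of_read[ei]]
  ei <- ei[keep]; s <- s[keep]; e <- e[keep]
  r2c <- data.frame(
    read_id = reads$read_id[ei], target_id = cids[ev_of_read[ei]],
    target_start = s, target_end = e,
    has_mismatch = rep(FALSE, length(ei)), perfect = rep(TRUE, length(ei)),
    mate = reads$mate[ei], pos = s, cigar = sprintf("%dM", as.integer(e - s)),
    nm = rep(0L, length(ei)), seq = reads$seq[ei])
  r2c$blocks <- mapply(function(s, e)
    matrix(c(s, e), ncol = 2, dimnames = list(NULL, c("start", "end"))),
    r2c$target_start, r2c$target_end, SIMPLIFY = FALSE)
  attr(r2c, "mode") <- "read_to_contig"

  # --- read-to-genome: spliced records; junction reads keep their longer
  # mappable side
  n_reads <- if (genome_reads) nrow(reads) else 0L
  acc <- list(read_id = character(n_reads), target_id = character(n_reads),
              target_start = numeric(n_reads), target_end = numeric(n_reads),
              has_mismatch = logical(n_reads), perfect = logical(n_reads),
              mate = integer(n_reads), pos = numeric(n_reads),
              cigar = character(n_reads), seq = character(n_reads),
              blocks = vector("list", n_reads))
  n_out <- 0L
  add_genome_row <- function(i, blocks, chrom, read_len) {
    bl <- cbind(blocks[, "genome_start"],
                blocks[, "genome_start"] + blocks[, "length"])
    if (sum(bl[, 2] - bl[, 1]) < min_genome_side) return()
    nb <- nrow(blocks)
    clip_left <- blocks[1, "contig_start"]
    clip_right <- read_len - (blocks[nb, "contig_start"] +
                                blocks[nb, "length"])
    cig <- character(0)
    if (clip_left > 0) cig <- sprintf("%dS", as.integer(clip_left))
    for (k in seq_len(nb)) {
      if (k > 1) {
        gap <- blocks[k, "genome_start"] -
          (blocks[k - 1, "genome_start"] + blocks[k - 1, "length"])
        cig <- c(cig, sprintf("%dN", as.integer(gap)))
      }
      cig <- c(cig, sprintf("%dM", as.integer(blocks[k, "length"])))
    }
    if (clip_right > 0) cig <- c(cig, sprintf("%dS", as.integer(clip_right)))
    n_out <<- n_out + 1L
    acc$read_id[n_out] <<- reads$read_id[i]
    acc$target_id[n_out] <<- chrom
    acc$target_start[n_out] <<- bl[1, 1]
    acc$target_end[n_out] <<- bl[nrow(bl), 2]
    acc$has_mismatch[n_out] <<- clip_left > 0 || clip_right > 0
    acc$perfect[n_out] <<- clip_left == 0 && clip_right == 0 && nrow(bl) == 1L
    acc$mate[n_out] <<- reads$mate[i]
    acc$pos[n_out] <<- bl[1, 1]
    acc$cigar[n_out] <<- paste(cig, collapse = "")
    acc$seq[n_out] <<- reads$seq[i]
    acc$blocks[[n_out]] <<- `colnames<-`(bl, c("start", "end"))
  }
  wt_chain <- list()
  if (!is.null(wildtype_genes)) {
    for (tx in names(wildtype_genes)) {
      g <- gene_by_id[[wildtype_genes[[tx]]]]
      wt_chain[[tx]] <- list(chain = g$exons, chrom = g$chrom)
    }
  }
  for (i in seq_len(n_reads)) {
    tx <- reads$transcript_id[i]
    read_len <- reads$t_end[i] - reads$t_start[i]
    if (!is.na(ev_of_read[i])) {
      ev <- events[[ev_of_read[i]]]
      pb <- event_piece_blocks(ev, reads$t_start[i], reads$t_end[i],
                               contig_offset = reads$t_start[i])
      sizes <- vapply(pb, function(m) sum(m[, "length"]), numeric(1))
      k <- which.max(sizes)
      if (sizes[k] == 0) next
      add_genome_row(i, pb[[k]], ev$pieces[[k]]$chrom, read_len)
    } else {
      wc <- wt_chain[[tx]]
      if (is.null(wc)) next
      add_genome_row(i, chain_map(wc$chain, reads$t_start[i], reads$t_end[i]),
                     wc$chrom, read_len)
    }
  }
  r2g <- data.frame(read_id = acc$read_id[seq_len(n_out)],
                    target_id = acc$target_id[seq_len(n_out)],
                    target_start = acc$target_start[seq_len(n_out)],
                    target_end = acc$target_end[seq_len(n_out)],
                    has_mismatch = acc$has_mismatch[seq_len(n_out)],
                    perfect = acc$perfect[seq_len(n_out)],
                    mate = acc$mate[seq_len(n_out)],
                    pos = acc$pos[seq_len(n_out)],
                    cigar = acc$cigar[seq_len(n_out)],
                    nm = rep(0L, n_out),
                    seq = acc$seq[seq_len(n_out)])
  r2g$blocks <- acc$blocks[seq_len(n_out)]
  attr(r2g, "mode") <- "read_to_genome"

  list(contig_alignments = alns, contigs = contigs,
       read_to_contig = r2c, read_to_genome = r2g)
}
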