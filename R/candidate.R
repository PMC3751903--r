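# Candidate construction from selected alignment sets and successful gap
# realignments.

candidate_counter <- local({
  i <- 0L
  function(reset = FALSE) {
    if (reset) i <<- 0L else i <<- i + 1L
    i
  }
})

new_candidate <- function(...) {
  structure(list(...), class = "Candidate")
}

#' @export
print.Candidate <- function(x, ...) {
  cat(sprintf("<Candidate %s> %s %s/%s %s:%d | %s:%d%s\n",
              x$id, x$contig_id, x$kind, x$topology,
              x$breakpoints$chrom[1], as.integer(x$breakpoints$pos[1]),
              x$breakpoints$chrom[2], as.integer(x$breakpoints$pos[2]),
              if (isTRUE(x$multimapping)) " [multimap]" else ""))
  invisible(x)
}

# genome blocks (start,end matrix) of an alignment
aln_genome_blocks <- function(aln) {
  cbind(start = aln$blocks[, "genome_start"],
        end = aln$blocks[, "genome_start"] + aln$blocks[, "length"])
}

# contig-coordinate overlap (nt) of two alignments, counted per position
pair_contig_overlap <- function(a, b) {
  length(intersect(aln_contig_positions(a), aln_contig_positions(b)))
}

split_candidate <- function(contig, aln_a, aln_b, multimapping, contig_length) {
  # order by contig coordinate
  if (aln_contig_span(aln_b)[1] < aln_contig_span(aln_a)[1]) {
    tmp <- aln_a; aln_a <- aln_b; aln_b <- tmp
  }
  topo <- classify_topology(aln_a, aln_b)
  dup_segment <- NULL
  if (topo %in% c("duplication", "eversion")) {
    # the duplicated segment spans the union of the two genomic intervals;
    # breakpoints are its first and last genomic positions
    ga <- aln_genome_span(aln_a); gb <- aln_genome_span(aln_b)
    seg <- c(min(ga[1], gb[1]), max(ga[2], gb[2]))
    dup_segment <- list(chrom = aln_a$chrom, start = seg[1], end = seg[2])
    bps <- data.frame(chrom = aln_a$chrom, pos = c(seg[1], seg[2] - 1),
                      strand = aln_a$strand)
  } else {
    bps <- data.frame(
      chrom = c(aln_a$chrom, aln_b$chrom),
      pos = c(aln_junction_breakpoint(aln_a, "left"),
              aln_junction_breakpoint(aln_b, "right")),
      strand = c(aln_a$strand, aln_b$strand))
  }
  m <- alignment_set_metrics(list(aln_a, aln_b), contig_length)
  new_candidate(
    id = sprintf("cand%05d", candidate_counter()),
    contig_id = contig$id, contig_length = contig_length,
    contig_seq = contig$seq %||% NULL,
    kind = "split", topology = topo,
    aln_a = aln_a, aln_b = aln_b,
    contig_span_a = aln_contig_span(aln_a),
    contig_span_b = aln_contig_span(aln_b),
    chrom_a = aln_a$chrom, chrom_b = aln_b$chrom,
    strand_a = aln_a$strand, strand_b = aln_b$strand,
    genome_blocks_a = aln_genome_blocks(aln_a),
    genome_blocks_b = aln_genome_blocks(aln_b),
    breakpoints = bps,
    dup_segment = dup_segment,
    multimapping = multimapping,
    contig_overlap_nt = pair_contig_overlap(aln_a, aln_b),
    inclusion = m$inclusion,
    identity_a = aln_a$percent_identity,
    identity_b = aln_b$percent_identity,
    gap = NULL)
}

gap_candidate <- function(contig, host, gap, realignment, multimapping,
                          contig_length) {
  topo <- realignment$kind
  i <- gap$start; j <- gap$end
  if (topo == "duplication") {
    # genomic coordinates of the existing copy, via the host alignment
    ts <- realignment$target_interval[1]
    te <- realignment$target_interval[2]
    g1 <- aln_genome_mate(host, ts)
    g2 <- aln_genome_mate(host, te - 1)
    if (is.na(g1)) g1 <- aln_genome_mate(host, max(0, i - 1))
    if (is.na(g2)) g2 <- aln_genome_mate(host, min(contig_length - 1, j + 1))
    seg <- c(min(g1, g2), max(g1, g2) + 1)
    dup_segment <- list(chrom = host$chrom, start = seg[1], end = seg[2])
    bps <- data.frame(chrom = host$chrom, pos = c(seg[1], seg[2] - 1),
                      strand = host$strand)
    blocks_b <- matrix(seg, ncol = 2, dimnames = list(NULL, c("start", "end")))
    span_b <- c(ts, te)
  } else {
    intv <- realignment$target_interval
    dup_segment <- NULL
    bps <- data.frame(chrom = host$chrom, pos = c(intv[1], intv[2] - 1),
                      strand = c(host$strand,
                                 if (host$strand == "+") "-" else "+"))
    blocks_b <- matrix(intv, ncol = 2, dimnames = list(NULL, c("start", "end")))
    span_b <- c(i, j + 1)
  }
  host_inc <- alignment_set_metrics(list(host), contig_length)$inclusion
  inclusion <- min(1, host_inc + realignment$aligned_fraction *
                     (j - i + 1) / contig_length)
  new_candidate(
    id = sprintf("cand%05d", candidate_counter()),
    contig_id = contig$id, contig_length = contig_length,
    contig_seq = contig$seq %||% NULL,
    kind = "gap", topology = topo,
    aln_a = host, aln_b = realignment,
    contig_span_a = aln_contig_span(host),
    contig_span_b = span_b,
    chrom_a = host$chrom, chrom_b = host$chrom,
    strand_a = host$strand,
    strand_b = bps$strand[2],
    genome_blocks_a = aln_genome_blocks(host),
    genome_blocks_b = blocks_b,
    breakpoints = bps,
    dup_segment = dup_segment,
    multimapping = multimapping,
    contig_overlap_nt = 0L,
    inclusion = inclusion,
    identity_a = host$percent_identity,
    identity_b = realignment$identity,
    gap = list(start = i, end = j,
               gap_sequence = gap$gap_sequence,
               aligned_seq = realignment$gap_aligned_seq,
               realign_conflict = isTRUE(realignment$conflict)))
}

#' Create gap- and split-candidates for one contig
#'
#' Case III sets with joint inclusion above `split_inclusion_min` become
#' split-candidates; Case II gaps with a successful realignment become
#' gap-candidates (the host alignment must meet `gap_quality_min` /
#' `gap_inclusion_min`). Sets touching mitochondrial sequence are dropped
#' when `drop_mito` is set. A candidate inherits the multi-mapping flag of
#' its alignment set.
#'
#' @param contig list with `id`, `length` and optionally `seq`.
#' @param selection result of [select_alignment_sets()].
#' @param realignments for Case II: list of `GapRealignment` (or NULL)
#'   parallel to `selection$gaps`, from [realign_gap()].
#' @param params an [align_params()] object.
#' @return list of `Candidate` objects (possibly empty).
#' @export
make_candidates <- function(contig, selection, realignments = list(),
                            params = align_params()) {
  out <- list()
  is_mito <- function(a) a$chrom %in% params$mito_names
  if (selection$case == "III") {
    for (k in seq_along(selection$sets)) {
      pair <- selection$sets[[k]]
      if (params$drop_mito && any(vapply(pair, is_mito, logical(1)))) next
      m <- alignment_set_metrics(pair, contig$length)
      if (m$inclusion <= params$split_inclusion_min) next
      out[[length(out) + 1L]] <- split_candidate(
        contig, pair[[1]], pair[[2]],
        multimapping = selection$multimapping[k],
        contig_length = contig$length)
    }
  } else if (selection$case == "II") {
    host <- selection$sets[[1]][[1]]
    if (params$drop_mito && is_mito(host)) return(out)
    host_m <- alignment_set_metrics(list(host), contig$length)
    if (host$quality < params$gap_quality_min ||
        host_m$inclusion < params$gap_inclusion_min) return(out)
    for (k in seq_along(selection$gaps)) {
      re <- if (k <= length(realignments)) realignments[[k]] else NULL
      if (is.null(re)) next
      out[[length(out) + 1L]] <- gap_candidate(
        contig, host, selection$gaps[[k]], re,
        multimapping = isTRUE(selection$multimapping[1]),
        contig_length = contig$length)
    }
  }
  out
}
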